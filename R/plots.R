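#' Plot a priming histogram
#'
#' Bars of tract-3'-end offsets along the read; vertical guides mark the
#' read body. Internal priming shows as mass piled near the 3' end.
#'
#' @param object A `priming_histogram`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.priming_histogram <- function(object, ...) {
  read_len <- attr(object, "read_len")
  df <- as_tibble(object)
  df$mid <- (df$bin_start + df$bin_end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = df$bin_end[1] - df$bin_start[1],
                      fill = "grey30") +
    ggplot2::geom_vline(xintercept = c(0, read_len), linetype = "dashed") +
    ggplot2::labs(x = "polyA tract 3' end offset from read 5' end (bp)",
                  y = "tract-read intersections") +
    ggplot2::theme_minimal()
}

#' Plot per-cell detection gain from intron inclusion
#'
#' @param object A `detection_gain` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.detection_gain <- function(object, ...) {
  finite <- filter(as_tibble(object), is.finite(.data$gain))
  ggplot2::ggplot(finite, ggplot2::aes(x = .data$gain)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::geom_vline(xintercept = mean(finite$gain), colour = "red") +
    ggplot2::labs(x = "genes detected, exon+intron / exon-only",
                  y = "cells") +
    ggplot2::theme_minimal()
}

#' Heatmap of a correlation profile, optionally bi-clustered
#'
#' @param object A `correlation_profile`.
#' @param cluster Reorder rows/columns by [bicluster()] (default `TRUE`).
#' @param ... Passed to [bicluster()].
#' @return A ggplot object.
#' @export
autoplot.correlation_profile <- function(object, cluster = TRUE, ...) {
  m <- unclass(object)
  attr(m, "gene_set") <- NULL
  if (cluster && nrow(m) > 1 && ncol(m) > 1) {
    bc <- bicluster(object, ...)
    m <- m[bc$row_order, bc$col_order, drop = FALSE]
  }
  long <- as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE))
  names(long) <- c("query", "reference", "r")
  long$query <- factor(long$query, levels = rownames(m))
  long$reference <- factor(long$reference, levels = colnames(m))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$reference, y = .data$query,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar chart of read fractions across genomic regions
#'
#' @param fractions Tibble from [region_fractions()].
#' @return A ggplot object.
#' @export
plot_region_fractions <- function(fractions) {
  fractions$region <- factor(fractions$region,
                             levels = c("exonic", "intronic", "intergenic",
                                        "ambiguous"))
  ggplot2::ggplot(fractions, ggplot2::aes(x = .data$region,
                                          y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' Bar chart of the top genes' share of counts
#'
#' @param top Tibble from [top_gene_fractions()].
#' @return A ggplot object.
#' @export
plot_top_genes <- function(top) {
  top$gene_id <- factor(top$gene_id, levels = rev(top$gene_id))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$fraction, y = .data$gene_id)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.1f%%",
                                                             100 * x)) +
    ggplot2::labs(x = "share of total counts", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
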