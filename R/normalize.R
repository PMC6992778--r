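#' Normalize a UMI count matrix
#'
#' The three-rung normalization ladder used throughout the package:
#'
#' 1. `tp10k` — each cell's counts divided by the cell's total UMIs and
#'    scaled to 10^4 (transcripts per 10k). Columns of nonempty cells sum to
#'    10^4 exactly.
#' 2. `log1p_tp10k` — natural log of TP10k plus a pseudo-count of 1.
#' 3. `standardized` — per-gene mean-centering and scaling to unit variance
#'    of the log values. Genes constant across cells cannot be scaled and
#'    become all-zero rows, recorded in the `constant_genes` attribute.
#'
#' Each rung is explicit: `to` selects how far up the ladder to go.
#'
#' @param x A `umi_counts` object, or a genes x cells matrix.
#' @param to Target rung: `"tp10k"`, `"log1p_tp10k"`, or `"standardized"`.
#' @return A dense genes x cells matrix with attribute `ladder` set to `to`.
#' @export
normalize_counts <- function(x, to = c("log1p_tp10k", "tp10k",
                                       "standardized")) {
  to <- match.arg(to)
  m <- if (inherits(x, "umi_counts")) x$counts else x
  m <- as.matrix(m)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf(
      "%d cell(s) have zero counts; run filter_matrix() before normalizing",
      sum(totals == 0)
    ))
  }
  out <- sweep(m, 2, totals, "/") * 1e4
  constant <- character()
  if (to %in% c("log1p_tp10k", "standardized")) out <- log1p(out)
  if (to == "standardized") {
    mu <- rowMeans(out)
    sdv <- apply(out, 1, sd)
    constant <- rownames(out)[sdv == 0]
    sdv[sdv == 0] <- 1
    out <- (out - mu) / sdv
  }
  structure(out, ladder = to, constant_genes = constant)
}

#' Select highly variable genes by binned dispersion
#'
#' Per gene, dispersion is variance over mean of the exponentiated
#' (TP10k-scale) expression; dispersions are z-standardized within
#' equal-frequency bins of mean expression so that highly expressed genes do
#' not dominate. A gene is selected when its standardized dispersion reaches
#' `dispersion_min` and its log-scale mean expression reaches `mean_min`
#' (defaults 1.5 and 0.15).
#'
#' @param log_x A `log1p_tp10k` matrix from [normalize_counts()].
#' @param dispersion_min Threshold on the binned dispersion z-score.
#' @param mean_min Threshold on `log1p(mean TP10k)`.
#' @param n_bins Number of equal-frequency mean bins (default 20; reduced
#'   with a warning when there are fewer genes than bins).
#' @return Tibble with `gene_id`, `mean_log`, `dispersion`, `dispersion_z`,
#'   `selected`.
#' @export
select_hvg <- function(log_x, dispersion_min = 1.5, mean_min = 0.15,
                       n_bins = 20L) {
  stopifnot(is.matrix(log_x))
  expd <- expm1(log_x)
  mu <- rowMeans(expd)
  v <- apply(expd, 1, var)
  dispersion <- ifelse(mu > 0, v / mu, 0)
  mean_log <- log1p(mu)

  n_genes <- nrow(log_x)
  if (n_genes < n_bins) {
    warn(sprintf("only %d genes; reducing mean bins from %d to %d",
                 n_genes, n_bins, max(1L, n_genes)))
    n_bins <- max(1L, n_genes)
  }
  bin <- ggplot2::cut_number(rank(mean_log, ties.method = "first"),
                             n = n_bins, labels = FALSE)
  z <- stats::ave(dispersion, bin, FUN = function(d) {
    s <- sd(d)
    if (is.na(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
  })
  tibble(
    gene_id = rownames(log_x),
    mean_log = unname(mean_log),
    dispersion = unname(dispersion),
    dispersion_z = unname(z),
    selected = unname(z >= dispersion_min & mean_log >= mean_min)
  )
}

#' Aggregate cells into pseudo-bulk expression profiles
#'
#' Raw counts are summed over each group's cells, then the group's summed
#' counts are converted to `log(TP10k + 1)` — the same ladder as single
#' cells, applied to the aggregate. This is the profile used to compare
#' droplet libraries against bulk RNA-seq.
#'
#' @param x A `umi_counts` object.
#' @param groups Tibble with `barcode` and `label`, or a named character
#'   vector `barcode -> label` covering every cell in `x`.
#' @return A genes x labels matrix of log1p-TP10k values.
#' @export
pseudobulk_profiles <- function(x, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$label), groups$barcode)
  }
  cells <- colnames(x$counts)
  missing <- setdiff(cells, names(groups))
  if (length(missing) > 0) {
    abort(sprintf("%d barcode(s) have no group label (first: %s)",
                  length(missing), missing[1]))
  }
  labels <- sort(unique(unname(groups[cells])))
  prof <- vapply(labels, function(L) {
    sub <- x$counts[, cells[groups[cells] == L], drop = FALSE]
    if (ncol(sub) == 0) abort(sprintf("group '%s' contains no cells", L))
    sums <- Matrix::rowSums(sub)
    total <- sum(sums)
    if (total == 0) abort(sprintf("group '%s' has zero total counts", L))
    log1p(1e4 * sums / total)
  }, numeric(nrow(x$counts)))
  prof <- matrix(prof, nrow = nrow(x$counts),
                 dimnames = list(rownames(x$counts), labels))
  prof
}

#' Pearson correlation profiles between query and reference expression
#'
#' Computes the Pearson correlation of every query profile (columns of
#' `queries`) against every reference profile over a common gene set —
#' e.g. per-nucleus or pseudo-bulk profiles against a panel of bulk RNA-seq
#' samples, giving each query its "correlation profile".
#'
#' @param queries,references Numeric matrices, genes in rows (rownames
#'   required), profiles in columns.
#' @param gene_set Genes to correlate over; default the intersection of the
#'   two rowname sets. At least 3 genes are required.
#' @return A `correlation_profile`: queries x references matrix of Pearson
#'   r with attribute `gene_set`. A zero-variance profile over the gene set
#'   yields `NA` for its pairs (with a warning).
#' @export
correlate_profiles <- function(queries, references, gene_set = NULL) {
  gene_set <- gene_set %||% intersect(rownames(queries), rownames(references))
  if (length(gene_set) < 3) {
    abort(sprintf("gene set has %d genes; need at least 3", length(gene_set)))
  }
  if (!all(gene_set %in% rownames(queries)) ||
      !all(gene_set %in% rownames(references))) {
    abort("gene_set contains genes absent from queries or references")
  }
  q <- queries[gene_set, , drop = FALSE]
  r <- references[gene_set, , drop = FALSE]
  flat_q <- apply(q, 2, sd) == 0
  flat_r <- apply(r, 2, sd) == 0
  if (any(flat_q) || any(flat_r)) {
    warn(sprintf(
      "%d profile(s) have zero variance over the gene set; their correlations are NA",
      sum(flat_q) + sum(flat_r)
    ))
  }
  cc <- suppressWarnings(cor(q, r))
  structure(cc, gene_set = gene_set, class = c("correlation_profile",
                                               class(cc)))
}

#' @export
tidy.correlation_profile <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(unclass(x), stringsAsFactors = FALSE))
  names(long) <- c("query", "reference", "r")
  as_tibble(long)
}

#' Pick a correlation gene set
#'
#' Genes detected (nonzero mean) on both sides, optionally capped to the
#' `top_n` by mean expression across both matrices.
#'
#' @param queries,references Expression matrices with rownames.
#' @param top_n Optional cap on the gene-set size.
#' @return Character vector of gene ids.
#' @export
select_correlation_genes <- function(queries, references, top_n = NULL) {
  common <- intersect(rownames(queries), rownames(references))
  det <- common[rowMeans(queries[common, , drop = FALSE]) > 0 &
                rowMeans(references[common, , drop = FALSE]) > 0]
  if (!is.null(top_n) && length(det) > top_n) {
    score <- rowMeans(queries[det, , drop = FALSE]) +
      rowMeans(references[det, , drop = FALSE])
    det <- det[order(-score)][seq_len(top_n)]
  }
  sort(det)
}

#' Bi-cluster a correlation matrix
#'
#' Hierarchical agglomerative clustering applied independently to the rows
#' and the columns, as a correlation heatmap does. Default complete linkage
#' on Euclidean distance; alternatively average linkage on the correlation
#' distance `1 - r`. Missing values are imputed by row mean (with a
#' warning). Fewer than two rows or columns yields the identity order.
#'
#' @param corr A `correlation_profile` or numeric matrix.
#' @param linkage `"complete"` or `"average"`.
#' @param distance `"euclidean"` or `"correlation"`.
#' @return A `bicluster` list: `row_order`, `col_order` (integer leaf
#'   orders), and the two `hclust` objects (`NULL` when degenerate).
#' @export
bicluster <- function(corr, linkage = c("complete", "average"),
                      distance = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  m <- unclass(corr)
  attr(m, "gene_set") <- NULL
  if (anyNA(m)) {
    warn("NA correlations imputed by row mean for clustering")
    for (i in seq_len(nrow(m))) {
      m[i, is.na(m[i, ])] <- mean(m[i, ], na.rm = TRUE)
    }
  }
  dfun <- function(mat) {
    if (distance == "euclidean") dist(mat) else stats::as.dist(1 - cor(t(mat)))
  }
  cl <- function(mat) {
    if (nrow(mat) < 2) return(NULL)
    hclust(dfun(mat), method = linkage)
  }
  rc <- cl(m)
  cc <- cl(t(m))
  structure(list(
    row_order = if (is.null(rc)) seq_len(nrow(m)) else rc$order,
    col_order = if (is.null(cc)) seq_len(ncol(m)) else cc$order,
    row_hclust = rc,
    col_hclust = cc
  ), class = "bicluster")
}
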