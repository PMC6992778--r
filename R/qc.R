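#' QC thresholds for cell and gene filtering
#'
#' Defaults follow the comparison study's rules: whole cells need at least
#' 400 detected genes, nuclei at least 300 (nuclear libraries carry less
#' RNA), a gene must be detected in at least 10 surviving cells, and a gene
#' counts as detected in a cell at 1 UMI or more.
#'
#' @param min_genes_cell,min_genes_nucleus Minimum detected genes for a
#'   cell / nucleus to be kept (strictly-less-than removal).
#' @param min_cells_per_gene Minimum number of surviving cells a gene must
#'   be detected in.
#' @param detection_min_umi UMIs needed for a gene to count as detected.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_genes_cell = 400L, min_genes_nucleus = 300L,
                      min_cells_per_gene = 10L, detection_min_umi = 1L) {
  stopifnot(min_genes_cell >= 0, min_genes_nucleus >= 0,
            min_cells_per_gene >= 0, detection_min_umi >= 0)
  structure(
    list(
      min_genes_cell = as.integer(min_genes_cell),
      min_genes_nucleus = as.integer(min_genes_nucleus),
      min_cells_per_gene = as.integer(min_cells_per_gene),
      detection_min_umi = as.integer(detection_min_umi)
    ),
    class = "qc_config"
  )
}

genes_detected_per_cell <- function(x, detection_min_umi = 1L) {
  Matrix::colSums(x$counts >= detection_min_umi)
}

#' Per-cell summary statistics
#'
#' @param x A `umi_counts` object.
#' @param assignments Optional assignment tibble from [assign_reads()]; when
#'   given, each cell's intronic read fraction (intronic reads over all of
#'   that barcode's reads) is added.
#' @param detection_min_umi UMIs needed for a gene to count as detected.
#' @return Tibble with `barcode`, `genes_detected`, `total_umi`, and
#'   `intronic_fraction` when assignments are supplied.
#' @export
per_cell_summary <- function(x, assignments = NULL, detection_min_umi = 1L) {
  out <- tibble(
    barcode = colnames(x$counts),
    genes_detected = as.integer(genes_detected_per_cell(x, detection_min_umi)),
    total_umi = as.integer(Matrix::colSums(x$counts))
  )
  if (!is.null(assignments)) {
    fr <- assignments |>
      group_by(barcode = .data$cell_barcode) |>
      summarise(
        intronic_fraction = mean(.data$region == "intronic"),
        .groups = "drop"
      )
    out <- left_join(out, fr, by = "barcode")
  }
  out
}

#' Apply the cell-then-gene QC filter
#'
#' Cells (or nuclei) with fewer than the mode's minimum number of detected
#' genes are removed first; then genes detected in fewer than
#' `min_cells_per_gene` of the *surviving* cells are removed. The order is
#' fixed — it changes the result — and matches filtering cells before genes.
#'
#' @param x A `umi_counts` object.
#' @param config A [qc_config()].
#' @param mode `"cell"` (min 400 genes by default) or `"nucleus"` (min 300).
#' @return The filtered `umi_counts` (possibly empty, with a warning).
#' @export
filter_matrix <- function(x, config = qc_config(),
                          mode = c("cell", "nucleus")) {
  mode <- match.arg(mode)
  min_genes <- if (mode == "cell") config$min_genes_cell else
    config$min_genes_nucleus
  detected <- genes_detected_per_cell(x, config$detection_min_umi)
  keep_cells <- detected >= min_genes
  m <- x$counts[, keep_cells, drop = FALSE]
  cells_per_gene <- Matrix::rowSums(m >= config$detection_min_umi)
  keep_genes <- cells_per_gene >= config$min_cells_per_gene
  m <- m[keep_genes, , drop = FALSE]
  if (ncol(m) == 0 || nrow(m) == 0) {
    warn("QC filter removed every cell and/or gene")
  }
  new_umi_counts(m, x$mode)
}

#' Per-cell gene-detection gain from intron inclusion
#'
#' For each barcode, the ratio of genes detected under exon+intron counting
#' to genes detected under exon-only counting — the quantity that averages
#' about 1.5x for droplet single-nucleus libraries. Cells detecting nothing
#' in exon-only mode have an infinite ratio; they are reported but excluded
#' from the mean.
#'
#' @param exon_x,both_x `umi_counts` in `exon_only` / `exon_plus_intron`
#'   mode over the same barcodes.
#' @param detection_min_umi UMIs needed for a gene to count as detected.
#' @return A `detection_gain` tibble with `barcode`, `genes_exon`,
#'   `genes_both`, `gain`; `glance()` gives the mean finite gain and the
#'   number of infinite ratios.
#' @export
detection_gain <- function(exon_x, both_x, detection_min_umi = 1L) {
  ce <- colnames(exon_x$counts)
  cb <- colnames(both_x$counts)
  if (!setequal(ce, cb)) {
    abort(sprintf(
      "barcode mismatch between matrices (%d only in exon-only, %d only in exon+intron)",
      length(setdiff(ce, cb)), length(setdiff(cb, ce))
    ))
  }
  ge <- genes_detected_per_cell(exon_x, detection_min_umi)
  gb <- genes_detected_per_cell(both_x, detection_min_umi)[ce]
  out <- tibble(
    barcode = ce,
    genes_exon = as.integer(ge),
    genes_both = as.integer(gb),
    gain = unname(gb / ge)
  )
  structure(out, class = c("detection_gain", class(tibble())))
}

#' @export
glance.detection_gain <- function(x, ...) {
  finite <- is.finite(x$gain)
  tibble(
    mean_gain = mean(x$gain[finite]),
    n_cells = nrow(x),
    n_infinite = sum(!finite)
  )
}

#' Read-fraction breakdown across genomic regions
#'
#' @param assignments Tibble from [assign_reads()] (nonempty).
#' @return Tibble over the four regions (`exonic`, `intronic`, `ambiguous`,
#'   `intergenic`) with `reads` and `fraction` (fractions sum to 1).
#' @export
region_fractions <- function(assignments) {
  if (nrow(assignments) == 0) abort("no assignments: cannot compute fractions")
  regions <- c("exonic", "intronic", "ambiguous", "intergenic")
  n <- vapply(regions, function(r) sum(assignments$region == r), integer(1))
  tibble(region = regions, reads = unname(n),
         fraction = unname(n) / sum(n))
}

#' Top genes by share of total counts
#'
#' The library-level "percentage of counts for the top N genes" view: in
#' whole cells it is dominated by mitochondrial and ribosomal genes, in
#' nuclei by nuclear-retained lncRNAs.
#'
#' @param x A `umi_counts` object (nonempty).
#' @param n How many genes to report (default 15); capped at the gene count.
#' @return Tibble with `gene_id` and `fraction`, descending, ties broken by
#'   `gene_id`.
#' @export
top_gene_fractions <- function(x, n = 15L) {
  tot <- Matrix::rowSums(x$counts)
  if (sum(tot) == 0) abort("count matrix has no counts")
  ord <- order(-tot, rownames(x$counts))
  ord <- ord[seq_len(min(n, length(ord)))]
  tibble(gene_id = rownames(x$counts)[ord],
         fraction = unname(tot[ord] / sum(tot)))
}

#' Select the top fraction of cells by gene detection
#'
#' Keeps the `ceiling(fraction * n_cells)` cells with the most detected
#' genes; ties are broken by total UMI count, then barcode, so the selection
#' is deterministic.
#'
#' @param x A `umi_counts` object.
#' @param fraction Fraction of cells to keep, in (0, 1] (default 0.30).
#' @param detection_min_umi UMIs needed for a gene to count as detected.
#' @return The subset `umi_counts`.
#' @export
select_top_cells <- function(x, fraction = 0.30, detection_min_umi = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  cs <- per_cell_summary(x, detection_min_umi = detection_min_umi)
  cs <- arrange(cs, desc(.data$genes_detected), desc(.data$total_umi),
                .data$barcode)
  keep <- cs$barcode[seq_len(ceiling(fraction * nrow(cs)))]
  new_umi_counts(x$counts[, keep, drop = FALSE], x$mode)
}
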