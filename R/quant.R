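#' Assign aligned reads to exonic or intronic gene features
#'
#' Each read (an aligned interval, not a split alignment) is compared against
#' the exon and intron intervals of the annotation. The outcome per read is
#' one of four regions:
#'
#' * `exonic` — the read overlaps exon intervals of exactly one gene (an
#'   overlap with that same gene's introns does not demote it: exon takes
#'   precedence within a gene, and the gene-level UMI sum is identical
#'   either way);
#' * `intronic` — the read overlaps intron intervals of exactly one gene and
#'   exons of none;
#' * `ambiguous` — features of two or more distinct genes are hit (unless
#'   `exon_priority = TRUE` and exactly one gene is hit in its exons, in
#'   which case that gene wins);
#' * `intergenic` — no feature overlap, including reads on chromosomes
#'   absent from the annotation (warned about).
#'
#' @param reads Tibble of aligned reads with columns `cell_barcode`, `umi`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`; an `is_primary`
#'   column, if present, drops secondary alignments.
#' @param genes A `gene_models` tibble with introns derived.
#' @param stranded If `TRUE`, only same-strand features are considered
#'   (default `FALSE`, the common counter default).
#' @param exon_priority If `TRUE`, an exonic overlap of a single gene beats
#'   intronic overlaps of other genes instead of being ambiguous.
#' @return The read tibble with `gene_id` (NA for ambiguous/intergenic) and
#'   `region` columns appended.
#' @export
assign_reads <- function(reads, genes, stranded = FALSE,
                         exon_priority = FALSE) {
  stopifnot(inherits(genes, "gene_models"))
  if (any(vapply(genes$introns, is.null, logical(1)))) {
    abort("introns not derived; call derive_introns() first")
  }
  if ("is_primary" %in% names(reads)) {
    reads <- filter(reads, .data$is_primary)
  }
  check_intervals(reads, "read")

  feats <- gene_intervals(genes, "both")
  unknown <- setdiff(unique(reads$chrom), unique(feats$chrom))
  if (length(unknown) > 0) {
    warn(sprintf(
      "reads on chromosome(s) absent from the annotation treated as intergenic: %s",
      paste(unknown, collapse = ", ")
    ))
  }

  read_gr <- intervals_to_granges(reads)
  feat_gr <- intervals_to_granges(feats)
  # unknown chromosomes are already warned about above; silence the
  # redundant seqlevel warning from the overlap engine
  hits <- withCallingHandlers(
    GenomicRanges::findOverlaps(read_gr, feat_gr, ignore.strand = !stranded),
    warning = function(w) {
      if (grepl("sequence levels in common", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  idx <- S4Vectors::queryHits(hits)
  gid <- feats$gene_id[S4Vectors::subjectHits(hits)]
  feat <- feats$feature[S4Vectors::subjectHits(hits)]
  n <- nrow(reads)

  # distinct genes (and distinct exon-hit genes) per read, vectorized
  count_first <- function(idx, gid) {
    if (length(idx) == 0) {
      return(list(n = integer(n), first = rep(NA_character_, n)))
    }
    key <- !duplicated(paste(idx, gid, sep = "\r"))
    idx <- idx[key]
    gid <- gid[key]
    first <- rep(NA_character_, n)
    first_seen <- !duplicated(idx)
    first[idx[first_seen]] <- gid[first_seen]
    list(n = tabulate(idx, nbins = n), first = first)
  }
  all_hits <- count_first(idx, gid)
  exon_hits <- count_first(idx[feat == "exonic"], gid[feat == "exonic"])

  n_all <- all_hits$n
  n_exon <- exon_hits$n
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  one_gene <- n_all == 1
  region[one_gene & n_exon >= 1] <- "exonic"
  region[one_gene & n_exon == 0] <- "intronic"
  gene_id[one_gene] <- all_hits$first[one_gene]
  multi <- n_all >= 2
  if (exon_priority) {
    rescue <- multi & n_exon == 1
    region[rescue] <- "exonic"
    gene_id[rescue] <- exon_hits$first[rescue]
    multi <- multi & !rescue
  }
  region[multi] <- "ambiguous"

  reads$gene_id <- gene_id
  reads$region <- region
  reads
}

#' Build a deduplicated UMI count matrix
#'
#' Counts, for every (gene, cell), the number of distinct UMI strings among
#' the reads assigned to that gene in the admitted regions. In
#' `exon_plus_intron` mode a UMI observed in both an exonic and an intronic
#' read of the same gene counts once — the molecule was captured once.
#' Ambiguous and intergenic reads contribute nothing. UMI identity is exact
#' string match per (cell, gene); no edit-distance collapsing.
#'
#' @param assignments Tibble from [assign_reads()] (whitelisted barcodes
#'   only).
#' @param mode `"exon_plus_intron"` (count exonic and intronic reads, the
#'   intron-aware quantification that roughly halves the discarded reads in
#'   nuclear libraries) or `"exon_only"`.
#' @param gene_ids,cell_barcodes Optional fixed row/column universes; default
#'   the sorted genes/barcodes observed in the admitted assignments.
#' @return A `umi_counts` object: a sparse integer genes x cells matrix with
#'   a `mode` field.
#' @export
count_umis <- function(assignments,
                       mode = c("exon_plus_intron", "exon_only"),
                       gene_ids = NULL, cell_barcodes = NULL) {
  mode <- match.arg(mode)
  admitted <- if (mode == "exon_only") "exonic" else c("exonic", "intronic")
  mol <- assignments |>
    filter(.data$region %in% admitted) |>
    distinct(.data$cell_barcode, .data$gene_id, .data$umi)

  gene_ids <- gene_ids %||% sort(unique(mol$gene_id))
  cell_barcodes <- cell_barcodes %||% sort(unique(mol$cell_barcode))
  mol <- filter(mol, .data$gene_id %in% gene_ids,
                .data$cell_barcode %in% cell_barcodes)

  counts <- Matrix::sparseMatrix(
    i = match(mol$gene_id, gene_ids),
    j = match(mol$cell_barcode, cell_barcodes),
    x = 1L,
    dims = c(length(gene_ids), length(cell_barcodes)),
    dimnames = list(gene_ids, cell_barcodes)
  )
  new_umi_counts(counts, mode)
}

#' Construct a umi_counts object from a matrix
#'
#' @param counts A genes x cells matrix (dense or sparse) of non-negative
#'   integer UMI counts with row and column names.
#' @param mode `"exon_plus_intron"` or `"exon_only"`.
#' @return A `umi_counts` object.
#' @export
umi_counts <- function(counts, mode = c("exon_plus_intron", "exon_only")) {
  mode <- match.arg(mode)
  counts <- methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                        "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must carry gene rownames and barcode colnames")
  }
  new_umi_counts(counts, mode)
}

new_umi_counts <- function(counts, mode) {
  stopifnot(mode %in% c("exon_plus_intron", "exon_only"))
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort("counts must be non-negative integers")
  }
  structure(list(counts = counts, mode = mode), class = "umi_counts")
}

#' @export
dim.umi_counts <- function(x) dim(x$counts)

#' @export
dimnames.umi_counts <- function(x) dimnames(x$counts)

#' @export
print.umi_counts <- function(x, ...) {
  cat(sprintf(
    "<umi_counts[%s]> %d genes x %d cells, %d nonzero, %d total UMIs\n",
    x$mode, nrow(x$counts), ncol(x$counts),
    Matrix::nnzero(x$counts), sum(x$counts)
  ))
  invisible(x)
}

#' @export
tidy.umi_counts <- function(x, ...) {
  tr <- Matrix::summary(x$counts)
  tibble(
    gene_id = rownames(x$counts)[tr$i],
    cell_barcode = colnames(x$counts)[tr$j],
    umis = as.integer(tr$x)
  )
}

#' @export
glance.umi_counts <- function(x, ...) {
  tibble(
    mode = x$mode, n_genes = nrow(x$counts), n_cells = ncol(x$counts),
    total_umis = sum(x$counts),
    median_umis_per_cell = stats::median(Matrix::colSums(x$counts))
  )
}

#' Merge count matrices from multiple runs
#'
#' Takes the union of all genes; a gene absent from one run gets zero counts
#' for that run's cells. Columns are the concatenation of the inputs'
#' columns. Barcode collisions across runs are an error unless per-run
#' `suffixes` are supplied, in which case `"<barcode>-<suffix>"` is used.
#'
#' @param matrices List of `umi_counts` objects sharing one mode.
#' @param suffixes Optional character vector, one per matrix.
#' @return A merged `umi_counts`.
#' @export
merge_count_matrices <- function(matrices, suffixes = NULL) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, logical(1), "umi_counts")))
  modes <- unique(vapply(matrices, function(m) m$mode, character(1)))
  if (length(modes) != 1) abort("matrices mix counting modes; refusing to merge")
  if (!is.null(suffixes)) {
    stopifnot(length(suffixes) == length(matrices))
    matrices <- map2(matrices, suffixes, function(m, s) {
      colnames(m$counts) <- paste0(colnames(m$counts), "-", s)
      m
    })
  }
  all_cells <- unlist(map(matrices, function(m) colnames(m$counts)))
  dup <- unique(all_cells[duplicated(all_cells)])
  if (length(dup) > 0) {
    abort(sprintf(
      "barcode collision(s) across runs (pass suffixes= to disambiguate): %s",
      paste(head(dup, 10), collapse = ", ")
    ))
  }
  all_genes <- sort(unique(unlist(map(matrices, function(m) {
    rownames(m$counts)
  }))))
  blocks <- map(matrices, function(m) {
    tr <- Matrix::summary(m$counts)
    Matrix::sparseMatrix(
      i = match(rownames(m$counts)[tr$i], all_genes),
      j = tr$j, x = tr$x,
      dims = c(length(all_genes), ncol(m$counts)),
      dimnames = list(all_genes, colnames(m$counts))
    )
  })
  new_umi_counts(do.call(cbind, blocks), modes)
}

#' Write / read a count matrix in MatrixMarket form
#'
#' `write_counts()` writes `<prefix>.mtx` (coordinate MatrixMarket),
#' `<prefix>.genes.tsv`, `<prefix>.barcodes.tsv`, and `<prefix>.meta.json`
#' recording the counting mode. `read_counts()` reverses it exactly.
#'
#' @param x A `umi_counts` object.
#' @param prefix Path prefix for the output files.
#' @return `write_counts()`: `prefix`, invisibly. `read_counts()`: a
#'   `umi_counts`.
#' @export
write_counts <- function(x, prefix) {
  stopifnot(inherits(x, "umi_counts"))
  Matrix::writeMM(x$counts, paste0(prefix, ".mtx"))
  writeLines(rownames(x$counts), paste0(prefix, ".genes.tsv"))
  writeLines(colnames(x$counts), paste0(prefix, ".barcodes.tsv"))
  jsonlite::write_json(list(mode = x$mode), paste0(prefix, ".meta.json"),
                       auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_counts
#' @export
read_counts <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  genes <- readLines(paste0(prefix, ".genes.tsv"))
  cells <- readLines(paste0(prefix, ".barcodes.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    abort(sprintf(
      "matrix is %d x %d but id files list %d genes and %d barcodes",
      nrow(m), ncol(m), length(genes), length(cells)
    ))
  }
  meta_path <- paste0(prefix, ".meta.json")
  mode <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path)$mode
  } else "exon_plus_intron"
  m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  new_umi_counts(m, mode)
}
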