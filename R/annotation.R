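#' Gene models with exon unions and derived introns
#'
#' A `gene_models` object is a tibble with one row per gene and list-columns
#' holding per-gene exon and intron intervals. All coordinates are 0-based
#' half-open; GTF input (1-based closed) is converted on read. The intron of
#' a gene is defined operationally: the gene span minus the union of the
#' exons of all of its transcripts, on the same strand. This matters for
#' single-nucleus libraries, where up to half of the reads fall in introns of
#' unspliced transcripts and would be discarded by exon-only counting.
#'
#' @param path Path to a GTF file containing `gene` and `exon` feature lines
#'   whose attribute string carries a `gene_id` key. Coordinates are GTF
#'   1-based closed and are converted to the package's 0-based half-open
#'   convention.
#'
#' @return A `gene_models` tibble with columns `gene_id`, `gene_name`,
#'   `biotype`, `chrom`, `start`, `end`, `strand`, and list-columns `exons`
#'   and `introns` (each a tibble of `start`, `end`). `introns` is `NULL`
#'   per gene until [derive_introns()] is called.
#'
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'   'chr1\tx\tgene\t1\t1000\t.\t+\t.\tgene_id "g1"; gene_name "G1";',
#'   'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g1";',
#'   'chr1\tx\texon\t901\t1000\t.\t+\t.\tgene_id "g1";'
#' ), gtf)
#' gm <- read_gene_models(gtf)
#' derive_introns(gm)$introns[[1]]
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  body <- !startsWith(raw, "#") & nzchar(trimws(raw))
  fields_ok <- vapply(
    strsplit(raw[body], "\t", fixed = TRUE),
    function(f) length(f) >= 9 && grepl("gene_id", f[9], fixed = TRUE),
    logical(1)
  )
  if (any(!fields_ok)) {
    bad_line <- which(body)[which(!fields_ok)[1]]
    abort(sprintf(
      "malformed GTF attribute string (no gene_id) at line %d of %s",
      bad_line, path
    ))
  }

  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  gene_id <- as.character(md$gene_id)
  biotype_col <- intersect(c("gene_biotype", "gene_type"), names(md))
  genes_idx <- which(type == "gene")
  exons_idx <- which(type == "exon")
  if (length(genes_idx) == 0) abort("GTF contains no gene feature lines")

  orphan <- setdiff(gene_id[exons_idx], gene_id[genes_idx])
  if (length(orphan) > 0) {
    abort(sprintf(
      "exon line(s) reference gene_id(s) with no gene line: %s",
      paste(orphan, collapse = ", ")
    ))
  }

  genes <- tibble(
    gene_id = gene_id[genes_idx],
    gene_name = if ("gene_name" %in% names(md)) {
      as.character(md$gene_name[genes_idx])
    } else gene_id[genes_idx],
    biotype = if (length(biotype_col)) {
      as.character(md[[biotype_col[1]]][genes_idx])
    } else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)[genes_idx]),
    start = GenomicRanges::start(gr)[genes_idx] - 1L,
    end = GenomicRanges::end(gr)[genes_idx],
    strand = as.character(GenomicRanges::strand(gr)[genes_idx])
  )
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicated gene feature lines for the same gene_id")
  }

  # exon union (merged overlaps across all transcripts) per gene
  ex <- gr[exons_idx]
  ex_by_gene <- S4Vectors::split(IRanges::ranges(ex), gene_id[exons_idx])
  ex_by_gene <- IRanges::reduce(ex_by_gene)
  genes$exons <- map(genes$gene_id, function(g) {
    r <- ex_by_gene[[g]]
    if (is.null(r) || length(r) == 0) {
      return(tibble(start = integer(), end = integer()))
    }
    tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })

  outside <- map2(genes$exons, seq_len(nrow(genes)), function(e, i) {
    nrow(e) > 0 && (min(e$start) < genes$start[i] || max(e$end) > genes$end[i])
  })
  if (any(unlist(outside))) {
    abort(sprintf(
      "exon(s) outside the span of gene(s): %s",
      paste(genes$gene_id[unlist(outside)], collapse = ", ")
    ))
  }

  genes$introns <- rep(list(NULL), nrow(genes))
  new_gene_models(genes)
}

new_gene_models <- function(df) {
  structure(df, class = c("gene_models", class(tibble())))
}

#' Derive per-gene intron intervals by interval subtraction
#'
#' Subtracts each gene's merged exon union from its span, on the same strand;
#' the remainder is the gene's intron set. Together the exons and introns
#' tile the span exactly. A single-exon gene whose exon equals its span gets
#' an empty intron list. The operation is idempotent.
#'
#' @param genes A `gene_models` tibble from [read_gene_models()] or
#'   [simulate_genome_annotation()].
#' @return The same tibble with the `introns` list-column populated.
#' @export
derive_introns <- function(genes) {
  stopifnot(inherits(genes, "gene_models"))
  genes$introns <- pmap(
    list(genes$exons, genes$start, genes$end),
    function(ex, s, e) {
      if (nrow(ex) == 0) return(tibble(start = s, end = e))
      ex <- ex[order(ex$start), , drop = FALSE]
      # gaps between consecutive exons plus flanks inside the span
      starts <- unname(c(s, ex$end))
      ends <- unname(c(ex$start, e))
      keep <- starts < ends
      tibble(start = starts[keep], end = ends[keep])
    }
  )
  genes
}

#' Flatten gene models to one interval per feature
#'
#' @param genes A `gene_models` tibble.
#' @param which `"exon"`, `"intron"`, or `"both"`.
#' @return Tibble with `gene_id`, `feature`, `chrom`, `start`, `end`,
#'   `strand`, one row per interval (0-based half-open).
#' @export
gene_intervals <- function(genes, which = c("both", "exon", "intron")) {
  which <- match.arg(which)
  pick <- function(col, feature) {
    rows <- map2(genes[[col]], seq_len(nrow(genes)), function(iv, i) {
      if (is.null(iv) || nrow(iv) == 0) return(NULL)
      tibble(
        gene_id = genes$gene_id[i], feature = feature,
        chrom = genes$chrom[i], start = iv$start, end = iv$end,
        strand = genes$strand[i]
      )
    })
    bind_rows(rows)
  }
  out <- switch(which,
    exon = pick("exons", "exonic"),
    intron = pick("introns", "intronic"),
    both = bind_rows(pick("exons", "exonic"), pick("introns", "intronic"))
  )
  if (nrow(out) == 0) {
    out <- tibble(
      gene_id = character(), feature = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    )
  }
  arrange(out, .data$chrom, .data$start)
}

#' Write exon or intron intervals as BED6
#'
#' Emits one BED record per interval, named by `gene_id`, 0-based half-open
#' with the strand in column 6, so the derived annotation can feed external
#' counters. Round-trips through [read_intervals()].
#'
#' @param genes A `gene_models` tibble with introns derived (for
#'   `which = "intron"`).
#' @param which `"exon"` or `"intron"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(genes, which = c("exon", "intron"), path) {
  which <- match.arg(which)
  iv <- gene_intervals(genes, which)
  if (nrow(iv) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- intervals_to_granges(iv)
  names(gr) <- iv$gene_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED6 interval file
#'
#' @param path BED file path.
#' @return Tibble with `gene_id` (BED name), `chrom`, `start`, `end`,
#'   `strand` in the package's 0-based half-open convention.
#' @export
read_intervals <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }
  gr <- rtracklayer::import(path, format = "bed")
  out <- granges_to_intervals(gr)
  out$gene_id <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  select(out, "gene_id", "chrom", "start", "end", "strand")
}

#' @export
tidy.gene_models <- function(x, ...) gene_intervals(x, "both")

#' @export
glance.gene_models <- function(x, ...) {
  iv <- gene_intervals(x, "both")
  tibble(
    n_genes = nrow(x),
    n_exons = sum(iv$feature == "exonic"),
    n_introns = sum(iv$feature == "intronic"),
    exonic_bp = sum(iv$end[iv$feature == "exonic"] -
      iv$start[iv$feature == "exonic"]),
    intronic_bp = sum(iv$end[iv$feature == "intronic"] -
      iv$start[iv$feature == "intronic"])
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf(
    "<gene_models> %d genes on %d sequence(s); introns %s\n",
    nrow(x), length(unique(x$chrom)),
    if (all(!vapply(x$introns, is.null, logical(1)))) "derived" else "not derived"
  ))
  NextMethod()
}
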