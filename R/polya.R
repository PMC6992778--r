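#' Scan a genome for polyA tracts
#'
#' Finds every maximal run of at least `min_len` consecutive adenines on the
#' forward strand (reported as `+` tracts) and every maximal run of thymines
#' (an A-run on the reverse strand, reported as `-` tracts). These
#' genomically encoded A-tracts are where the polydT capture primer can
#' hybridize internally instead of at the true polyA tail, generating
#' intronic reads. Matching is case-insensitive (soft-masked bases count);
#' runs are broken by `N` and any other non-A/T letter. Merging overlapping
#' 5-mers is implicit: each maximal run is reported exactly once.
#'
#' @param genome A `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or a FASTA file path.
#' @param min_len Minimum run length (default 5).
#' @param strands `"both"` (default: A-runs as `+` tracts and T-runs as `-`
#'   tracts) or `"forward"` (A-runs only).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `length`, one row per tract.
#' @export
scan_polya <- function(genome, min_len = 5L,
                       strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
    abort("empty genome: nothing to scan")
  }
  chroms <- names(genome) %||% as.character(seq_along(genome))
  names(genome) <- chroms

  per_chrom <- map(chroms, function(ch) {
    s <- toupper(as.character(genome[[ch]]))
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    wanted <- if (strands == "both") c("A", "T") else "A"
    keep <- r$lengths >= min_len & r$values %in% wanted
    if (!any(keep)) return(NULL)
    tibble(
      chrom = ch,
      start = starts[keep],
      end = ends[keep],
      strand = ifelse(r$values[keep] == "A", "+", "-"),
      length = r$lengths[keep]
    )
  })
  out <- bind_rows(per_chrom)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), length = integer())
  }
  out
}

#' Intersect polyA tracts with flank-extended intronic reads
#'
#' Each intronic read is extended by `flank` bases on both sides and
#' intersected with the tract set; with `stranded = TRUE` (the default, and
#' the biologically meaningful choice — internal priming happens on A-runs
#' of the transcript strand) only tracts on the read's strand count.
#'
#' @param tracts Tract tibble from [scan_polya()].
#' @param reads Tibble of intronic reads (`chrom`, `start`, `end`,
#'   `strand`); if a `region` column is present only `region == "intronic"`
#'   rows are used. A `read_id` column is added if absent.
#' @param flank Extension in bp on each side (default 20).
#' @param stranded Require tract strand == read strand (default `TRUE`).
#' @return Tibble of hits: `read_id`, read coordinates, and
#'   `tract_start`, `tract_end`, `tract_strand`, `tract_length`.
#' @export
intersect_intronic <- function(tracts, reads, flank = 20L, stranded = TRUE) {
  if ("region" %in% names(reads)) {
    reads <- filter(reads, .data$region == "intronic")
  }
  if (!"read_id" %in% names(reads)) {
    reads$read_id <- seq_len(nrow(reads))
  }
  empty <- tibble(
    read_id = reads$read_id[0], chrom = character(), start = integer(),
    end = integer(), strand = character(), tract_start = integer(),
    tract_end = integer(), tract_strand = character(), tract_length = integer()
  )
  if (nrow(reads) == 0 || nrow(tracts) == 0) return(empty)

  ext <- mutate(reads, start = pmax(0L, .data$start - as.integer(flank)),
                end = .data$end + as.integer(flank))
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(ext), intervals_to_granges(tracts),
    ignore.strand = !stranded
  )
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  tibble(
    read_id = reads$read_id[qi],
    chrom = reads$chrom[qi],
    start = reads$start[qi],
    end = reads$end[qi],
    strand = reads$strand[qi],
    tract_start = tracts$start[si],
    tract_end = tracts$end[si],
    tract_strand = tracts$strand[si],
    tract_length = tracts$end[si] - tracts$start[si]
  )
}

#' Fraction of intronic reads adjacent to a polyA tract
#'
#' Counts each read once however many tracts it touches. Around 40% of
#' intronic reads in droplet single-nucleus data carry such a tract within
#' their 20 bp flanks — the internal-priming signature.
#'
#' @param hits Hit tibble from [intersect_intronic()].
#' @param reads The read tibble given to [intersect_intronic()] (nonempty;
#'   filtered to intronic rows the same way).
#' @return Proportion in `[0, 1]`.
#' @export
polya_read_fraction <- function(hits, reads) {
  if ("region" %in% names(reads)) {
    reads <- filter(reads, .data$region == "intronic")
  }
  if (nrow(reads) == 0) abort("no intronic reads: fraction undefined")
  if (!"read_id" %in% names(reads)) reads$read_id <- seq_len(nrow(reads))
  length(unique(hits$read_id)) / nrow(reads)
}

#' Histogram of tract 3' positions along reads
#'
#' For every (read, tract) hit, the offset of the tract's 3' end relative to
#' the read's 5' end, in read orientation: for a `+` read, `tract_end -
#' read_start`; for a `-` read the coordinates are mirrored, `read_end -
#' tract_start`. Offsets are binned over `[-flank, read_len + flank]`
#' (offsets from tracts running past the window are clamped into the edge
#' bins). Internal priming shows up as mass piled toward the 3' end of the
#' read; without it the histogram is flat up to sampling noise.
#'
#' @param hits Hit tibble from [intersect_intronic()].
#' @param flank Flank used in the intersection (default 20).
#' @param bin_width Bin width in bp (default 5).
#' @param read_len Read length; default the longest read seen in `hits`.
#' @return A `priming_histogram` tibble with `bin_start`, `bin_end`,
#'   `count`; `glance()` reports the 3'-half versus 5'-half mass split.
#' @export
motif_position_histogram <- function(hits, flank = 20L, bin_width = 5L,
                                     read_len = NULL) {
  read_len <- read_len %||%
    (if (nrow(hits) > 0) max(hits$end - hits$start) else 60L)
  breaks <- seq(-flank, read_len + flank, by = bin_width)
  if (breaks[length(breaks)] < read_len + flank) {
    breaks <- c(breaks, read_len + flank)
  }
  offset <- ifelse(hits$strand == "+",
                   hits$tract_end - hits$start,
                   hits$end - hits$tract_start)
  offset <- pmin(pmax(offset, breaks[1]), breaks[length(breaks)])
  bin <- cut(offset, breaks = breaks, right = FALSE, include.lowest = TRUE)
  counts <- as.integer(table(bin))
  out <- tibble(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    count = counts
  )
  structure(out, flank = flank, read_len = read_len,
            class = c("priming_histogram", class(tibble())))
}

#' @export
glance.priming_histogram <- function(x, ...) {
  read_len <- attr(x, "read_len")
  mid <- (x$bin_start + x$bin_end) / 2
  m3 <- sum(x$count[mid > read_len / 2])
  m5 <- sum(x$count[mid < read_len / 2])
  tibble(
    n_hits = sum(x$count),
    mass_3prime = m3,
    mass_5prime = m5,
    enrichment_3prime = m3 / max(m5, 1L)
  )
}
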