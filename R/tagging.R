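#' Count cell barcodes in a barcode-read FASTQ
#'
#' Read 1 of a droplet 3' library carries the cell barcode in its first
#' `cb_len` bases. This tallies reads per barcode as input for
#' [build_whitelist()].
#'
#' @param fastq1 Path to the read-1 FASTQ file.
#' @param cb_len Cell-barcode length in bases (default 12).
#' @return Tibble with `barcode` and `reads`, sorted by decreasing `reads`.
#' @export
count_barcodes <- function(fastq1, cb_len = 12L) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  bc <- as.character(Biostrings::subseq(
    r1[Biostrings::width(r1) >= cb_len], 1L, cb_len
  ))
  tb <- table(bc)
  arrange(
    tibble(barcode = names(tb), reads = as.integer(tb)),
    desc(.data$reads), .data$barcode
  )
}

#' Build a cell-barcode whitelist by read-count threshold
#'
#' A barcode enters the whitelist when it was seen on at least `min_reads`
#' read pairs. The default of 30,000 reads suits a full sequencing run at
#' 30k-40k reads per cell; synthetic or downsampled runs should lower it.
#' Barcodes containing `N` are excluded: they denote ambiguous cells. There
#' is no knee-point detection and no barcode error correction — the rule is
#' a hard, deterministic threshold.
#'
#' @param barcode_counts Tibble with columns `barcode` and `reads` (e.g. from
#'   [count_barcodes()]), or a named integer vector.
#' @param min_reads Minimum read count (default 30000).
#' @return A `whitelist` tibble with column `barcode`, carrying `min_reads`
#'   as an attribute.
#' @export
build_whitelist <- function(barcode_counts, min_reads = 30000L) {
  if (!is.data.frame(barcode_counts)) {
    barcode_counts <- tibble(
      barcode = names(barcode_counts),
      reads = as.integer(barcode_counts)
    )
  }
  stopifnot(all(c("barcode", "reads") %in% names(barcode_counts)))
  if (any(barcode_counts$reads < 0)) abort("barcode read counts must be >= 0")
  if (nrow(barcode_counts) == 0) {
    warn("empty barcode counts: whitelist is empty")
  }
  keep <- barcode_counts$reads >= min_reads &
    !grepl("N", barcode_counts$barcode, fixed = TRUE)
  out <- tibble(barcode = sort(barcode_counts$barcode[keep]))
  structure(out, min_reads = min_reads,
            class = c("whitelist", class(tibble())))
}

#' Fuse read pairs into barcode/UMI-tagged single-end records
#'
#' Each pair is collapsed into one record: the first `cb_len` bases of read 1
#' become the cell barcode, the next `umi_len` the UMI, and read 2 supplies
#' the cDNA sequence. Only pairs whose barcode is on the whitelist are kept.
#' Read-1 records shorter than `cb_len + umi_len` are skipped and counted.
#' The returned tibble carries a `tally` attribute with
#' `c(kept, filtered, skipped)`; these always sum to the number of input
#' pairs.
#'
#' @param fastq1,fastq2 Paths to the paired FASTQ files (read 1 =
#'   barcode+UMI, read 2 = cDNA). Files must be record-synchronized.
#' @param whitelist A `whitelist` from [build_whitelist()], or a character
#'   vector of barcodes.
#' @param cb_len,umi_len Barcode and UMI lengths (defaults 12 and 8).
#' @return A `tagged_reads` tibble with `cell_barcode`, `umi`, `sequence`,
#'   `qualities`.
#' @export
tag_read_pairs <- function(fastq1, fastq2, whitelist,
                           cb_len = 12L, umi_len = 8L) {
  if (is.data.frame(whitelist)) whitelist <- whitelist$barcode
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    abort(sprintf(
      "desynchronized pair files: %d records in read 1 vs %d in read 2 (first missing mate at record %d)",
      length(r1), length(r2), min(length(r1), length(r2)) + 1L
    ))
  }
  n <- length(r1)
  long_enough <- Biostrings::width(r1) >= cb_len + umi_len
  skipped <- sum(!long_enough)

  cb <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)
  cb[long_enough] <- as.character(
    Biostrings::subseq(r1[long_enough], 1L, cb_len)
  )
  umi[long_enough] <- as.character(
    Biostrings::subseq(r1[long_enough], cb_len + 1L, cb_len + umi_len)
  )
  keep <- long_enough & cb %in% whitelist
  filtered <- sum(long_enough) - sum(keep)

  quals <- S4Vectors::mcols(r2)$qualities
  out <- tibble(
    cell_barcode = unname(cb[keep]),
    umi = unname(umi[keep]),
    sequence = unname(as.character(r2[keep])),
    qualities = if (!is.null(quals)) {
      unname(as.character(quals[keep]))
    } else NA_character_
  )
  structure(out,
    tally = c(kept = sum(keep), filtered = filtered, skipped = skipped),
    class = c("tagged_reads", class(tibble()))
  )
}

#' Trim a 3'-terminal polyA run
#'
#' Removes a maximal run of at least `min_run` terminal adenines — the
#' signature of reading through into the polyA tail (or an internally primed
#' A-tract). Shorter terminal runs and internal runs are untouched, and no
#' 5' bases are ever removed. Idempotent; vectorized over sequences.
#'
#' @param sequence Character vector of read sequences over `{A,C,G,T,N}`.
#' @param min_run Minimum terminal A-run length to trim (default 6, the
#'   shortest run unlikely to arise by chance at the end of a 60 bp read).
#' @return Trimmed sequences, same length as the input vector.
#' @export
trim_polya <- function(sequence, min_run = 6L) {
  stopifnot(min_run >= 1)
  sub(sprintf("A{%d,}$", as.integer(min_run)), "", sequence)
}

#' Write tagged reads as FASTQ
#'
#' The read name encodes the tags as `<cell_barcode>_<umi>_<serial>`, the
#' form downstream counting expects in alignment output.
#'
#' @param reads A `tagged_reads` tibble from [tag_read_pairs()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_tagged_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- sprintf("%s_%s_%d", reads$cell_barcode, reads$umi,
                         seq_len(nrow(reads)))
  quals <- reads$qualities
  if (all(!is.na(quals))) {
    Biostrings::writeXStringSet(
      seqs, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals)
    )
  } else {
    Biostrings::writeXStringSet(seqs, path, format = "fastq")
  }
  invisible(path)
}

#' @export
glance.tagged_reads <- function(x, ...) {
  tl <- attr(x, "tally")
  tibble(kept = unname(tl["kept"]), filtered = unname(tl["filtered"]),
         skipped = unname(tl["skipped"]))
}
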