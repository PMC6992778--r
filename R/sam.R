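#' Write aligned reads as SAM with barcode/UMI-encoding read names
#'
#' Emits a coordinate-sorted SAM file whose read names carry the tags as
#' `<cell_barcode>_<umi>_<serial>` — the convention produced by
#' [write_tagged_fastq()] and consumed by [read_sam()]. Alignments are
#' simple full-length matches (`<len>M`); sequence and qualities are
#' omitted (`*`).
#'
#' @param reads Read tibble (`cell_barcode`, `umi`, `chrom`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param chrom_lengths Named integer vector of reference lengths.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_lengths, path) {
  check_intervals(reads, "read")
  reads <- arrange(reads, .data$chrom, .data$start)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths))
  )
  serial <- if ("read_id" %in% names(reads)) reads$read_id else
    seq_len(nrow(reads))
  body <- sprintf(
    "%s_%s_%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
    reads$cell_barcode, reads$umi, serial,
    ifelse(reads$strand == "-", 16L, 0L),
    reads$chrom, reads$start + 1L, reads$end - reads$start
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read tagged alignments from SAM or BAM
#'
#' Accepts the SAM dialect written by [write_sam()] (or any BAM whose read
#' names follow `<cell_barcode>_<umi>_<serial>`). SAM input is converted
#' through `Rsamtools::asBam()`.
#'
#' @param path SAM or BAM file.
#' @param cb_len,umi_len Barcode and UMI lengths used for a sanity check on
#'   the parsed name fields.
#' @return Read tibble with `read_id`, `cell_barcode`, `umi`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `is_primary`.
#' @export
read_sam <- function(path, cb_len = 12L, umi_len = 8L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "strand")
    )
  )[[1]]
  parts <- stringr::str_match(rec$qname, "^([ACGTN]+)_([ACGTN]+)_(\\d+)$")
  if (anyNA(parts[, 1])) {
    abort("read name(s) not in <barcode>_<umi>_<serial> form")
  }
  if (any(nchar(parts[, 2]) != cb_len) || any(nchar(parts[, 3]) != umi_len)) {
    abort(sprintf("read-name tags are not %d bp barcode + %d bp UMI",
                  cb_len, umi_len))
  }
  width <- vapply(
    stringr::str_match_all(rec$cigar, "(\\d+)([MDN=X])"),
    function(m) sum(as.integer(m[, 2])), numeric(1)
  )
  tibble(
    read_id = as.integer(parts[, 4]),
    cell_barcode = parts[, 2],
    umi = parts[, 3],
    chrom = as.character(rec$rname),
    start = rec$pos - 1L,
    end = as.integer(rec$pos - 1L + width),
    strand = as.character(rec$strand),
    is_primary = bitwAnd(rec$flag, 256L) == 0L
  )
}

#' Emit paired FASTQ for simulated reads
#'
#' Read 1 carries the 12 bp cell barcode followed by the 8 bp UMI; read 2 is
#' the cDNA sequence extracted from the simulated genome (reverse-
#' complemented for `-` alignments so the FASTQ records read in sequencing
#' orientation). Qualities are uniform.
#'
#' @param sim A `sim_reads` object from [simulate_reads()].
#' @param ann The `sim_annotation` the reads were placed on.
#' @param fastq1,fastq2 Output paths for the pair.
#' @return `c(fastq1, fastq2)`, invisibly.
#' @export
simulate_fastq_pairs <- function(sim, ann, fastq1, fastq2) {
  truth <- sim$truth
  r1 <- Biostrings::DNAStringSet(paste0(truth$cell_barcode, truth$umi))
  seqs <- map_chr(seq_len(nrow(truth)), function(i) {
    as.character(Biostrings::subseq(
      ann$genome[[truth$chrom[i]]], truth$start[i] + 1L, truth$end[i]
    ))
  })
  r2 <- Biostrings::DNAStringSet(seqs)
  neg <- truth$strand == "-"
  r2[neg] <- Biostrings::reverseComplement(r2[neg])
  ids <- sprintf("sim%d", truth$read_id)
  names(r1) <- ids
  names(r2) <- ids
  q1 <- Biostrings::BStringSet(strrep("I", Biostrings::width(r1)))
  q2 <- Biostrings::BStringSet(strrep("I", Biostrings::width(r2)))
  Biostrings::writeXStringSet(r1, fastq1, format = "fastq", qualities = q1)
  Biostrings::writeXStringSet(r2, fastq2, format = "fastq", qualities = q2)
  invisible(c(fastq1, fastq2))
}
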