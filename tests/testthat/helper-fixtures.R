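# Fixture builders shared across test files. Everything is generated in
# code; coordinates handed to these helpers are the package's 0-based
# half-open convention and converted to GTF 1-based closed on write.

write_test_gtf <- function(genes, path = tempfile(fileext = ".gtf")) {
  lines <- unlist(lapply(genes, function(g) {
    attrs <- sprintf('gene_id "%s";', g$gene_id)
    out <- sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   g$chrom, g$start + 1L, g$end, g$strand, attrs)
    for (e in g$exons) {
      out <- c(out, sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
                            g$chrom, e[1] + 1L, e[2], g$strand, attrs))
    }
    out
  }))
  writeLines(lines, path)
  path
}

# one gene spec for write_test_gtf
tg <- function(gene_id, start, end, exons, strand = "+", chrom = "chr1") {
  list(gene_id = gene_id, chrom = chrom, start = start, end = end,
       strand = strand, exons = exons)
}

# random gene structure: span plus sorted disjoint exon union inside it,
# first and last exon anchored at the span ends
random_gene_structure <- function(max_len = 5000) {
  span_start <- sample(0:1000, 1)
  n_ex <- sample(1:5, 1)
  ex_len <- sample(20:200, n_ex, replace = TRUE)
  gap_len <- if (n_ex > 1) sample(10:300, n_ex - 1, replace = TRUE) else
    integer(0)
  starts <- span_start + cumsum(c(0, ex_len[-n_ex] + gap_len))
  list(start = span_start, end = starts[n_ex] + ex_len[n_ex],
       exons = cbind(starts, starts + ex_len))
}

# per-base oracle: intron bases are span bases not covered by any exon
brute_force_introns <- function(span_start, span_end, exons) {
  bases <- span_start:(span_end - 1)
  exonic <- unlist(apply(exons, 1, function(e) e[1]:(e[2] - 1),
                         simplify = FALSE))
  intron_bases <- sort(setdiff(bases, exonic))
  if (length(intron_bases) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  grp <- cumsum(c(1, diff(intron_bases) != 1))
  tibble::tibble(
    start = as.integer(tapply(intron_bases, grp, min)),
    end = as.integer(tapply(intron_bases, grp, max)) + 1L
  )
}

# write a 4-line-per-record FASTQ from sequences (qualities uniform)
write_test_fastq <- function(seqs, path = tempfile(fileext = ".fq"),
                             ids = NULL) {
  ids <- ids %||% sprintf("r%d", seq_along(seqs))
  writeLines(as.vector(rbind(
    paste0("@", ids), seqs, "+", strrep("I", nchar(seqs))
  )), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic umi_counts fixture
make_counts <- function(m, mode = "exon_plus_intron") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
  umi_counts(m, mode)
}
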