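test_that("polyA scan finds maximal A- and T-runs on the right strands", {
  tr <- scan_polya(c(chr1 = "GGAAAAATTTTTCC"))
  expect_equal(nrow(tr), 2)
  a <- tr[tr$strand == "+", ]
  t <- tr[tr$strand == "-", ]
  expect_equal(c(a$start, a$end), c(2, 7))
  expect_equal(c(t$start, t$end), c(7, 12))

  # below-threshold runs, N-broken runs, case-insensitivity
  expect_equal(nrow(scan_polya(c(chr1 = "CCAAAACC"))), 0)
  expect_equal(nrow(scan_polya(c(chr1 = "AAANAAA"))), 0)
  low <- scan_polya(c(chr1 = "ggaaaaagg"))
  expect_equal(c(low$start, low$end), c(2, 7))

  # forward-only scanning drops T-runs
  fwd <- scan_polya(c(chr1 = "GGAAAAATTTTTCC"), strands = "forward")
  expect_equal(fwd$strand, "+")

  expect_error(scan_polya(Biostrings::DNAStringSet()), "empty")
})

test_that("polyA scan equals a regex oracle on random sequence", {
  set.seed(53)
  s <- paste(sample(c("A", "C", "G", "T"), 100000, replace = TRUE,
                    prob = c(.3, .2, .2, .3)), collapse = "")
  tr <- scan_polya(c(chrX = s))
  oracle <- function(base, strand) {
    m <- gregexpr(sprintf("%s{5,}", base), s)[[1]]
    if (m[1] == -1) return(NULL)
    tibble::tibble(start = as.integer(m) - 1L,
                   end = as.integer(m) - 1L + attr(m, "match.length"),
                   strand = strand)
  }
  exp <- dplyr::bind_rows(oracle("A", "+"), oracle("T", "-"))
  exp <- exp[order(exp$start), ]
  got <- tr[order(tr$start), c("start", "end", "strand")]
  expect_equal(as.data.frame(got), as.data.frame(exp),
               ignore_attr = TRUE)
})

test_that("tract-read intersection honors flanks and strand", {
  read <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1060L,
                         strand = "+", read_id = 1L)
  tract <- tibble::tibble(chrom = "chr1", start = 1075L, end = 1081L,
                          strand = "+")
  # overlaps only through the 20 bp extension (window ends at 1080)
  expect_equal(nrow(intersect_intronic(tract, read, flank = 20)), 1)
  expect_equal(nrow(intersect_intronic(tract, read, flank = 0)), 0)
  # strand rule
  tract_minus <- dplyr::mutate(tract, strand = "-", start = 1030L,
                               end = 1036L)
  expect_equal(nrow(intersect_intronic(tract_minus, read, stranded = TRUE)),
               0)
  expect_equal(nrow(intersect_intronic(tract_minus, read,
                                       stranded = FALSE)), 1)
})

test_that("polyA read fraction counts each read once", {
  reads <- tibble::tibble(chrom = "chr1",
                          start = c(0L, 100L, 200L, 300L, 400L),
                          end = c(0L, 100L, 200L, 300L, 400L) + 60L,
                          strand = "+", read_id = 1:5)
  tracts <- tibble::tibble(chrom = "chr1",
                           start = c(10L, 20L, 110L),
                           end = c(16L, 26L, 116L), strand = "+")
  hits <- intersect_intronic(tracts, reads)
  expect_equal(nrow(hits), 3)  # read 1 hit twice, read 2 once
  expect_equal(polya_read_fraction(hits, reads), 0.4)
  # no tracts at all
  expect_equal(polya_read_fraction(hits[0, ], reads), 0)
  expect_error(polya_read_fraction(hits, reads[0, ]), "no intronic reads")
})

test_that("histogram offsets follow the read-oriented 3'-end convention", {
  # + read [1000,1060), + tract [1050,1057): offset = 1057 - 1000 = 57
  read_p <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1060L,
                           strand = "+", read_id = 1L)
  tract_p <- tibble::tibble(chrom = "chr1", start = 1050L, end = 1057L,
                            strand = "+")
  h <- motif_position_histogram(intersect_intronic(tract_p, read_p),
                                read_len = 60)
  expect_equal(h$count[h$bin_start == 55], 1)
  expect_equal(sum(h$count), 1)

  # - read [1000,1060), - tract [1000,1006): mirrored offset = 60
  read_m <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1060L,
                           strand = "-", read_id = 1L)
  tract_m <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1006L,
                            strand = "-")
  h2 <- motif_position_histogram(intersect_intronic(tract_m, read_m),
                                 read_len = 60)
  expect_equal(h2$count[h2$bin_start == 60], 1)

  # counts always sum to the number of intersections
  set.seed(59)
  reads <- tibble::tibble(chrom = "chr1",
                          start = as.integer(sample(0:5000, 200)),
                          strand = sample(c("+", "-"), 200, replace = TRUE),
                          read_id = 1:200)
  reads$end <- reads$start + 60L
  tracts <- tibble::tibble(chrom = "chr1",
                           start = as.integer(sample(0:5000, 300)),
                           strand = sample(c("+", "-"), 300, replace = TRUE))
  tracts$end <- tracts$start + 6L
  hh <- intersect_intronic(tracts, reads)
  expect_equal(sum(motif_position_histogram(hh)$count), nrow(hh))
})

test_that("histogram is flat for uniform tracts and 3'-skewed with priming", {
  sim_polya <- function(priming_rate, seed) {
    cfg <- sim_config(seed = seed, mode = "nucleus", n_cells = 60,
                      mean_umis = 250, internal_priming_rate = priming_rate)
    ann <- simulate_genome_annotation(cfg)
    expr <- simulate_expression(cfg, ann)
    sim <- simulate_reads(cfg, ann, expr)
    asn <- assign_reads(sim$reads, ann$genes)
    motif_position_histogram(intersect_intronic(scan_polya(ann$genome), asn))
  }
  h_on <- sim_polya(0.4, seed = 61)
  g_on <- glance(h_on)
  expect_gt(g_on$mass_3prime, g_on$mass_5prime)

  h_off <- sim_polya(0, seed = 62)
  # interior bins (edge bins absorb clamped overshoot) are flat
  interior <- h_off$count[2:(nrow(h_off) - 1)]
  p <- suppressWarnings(chisq.test(interior))$p.value
  expect_gt(p, 0.01)
})

test_that("reverse-complementing the genome leaves the fraction unchanged", {
  set.seed(67)
  L <- 20000L
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  reads <- tibble::tibble(chrom = "chr1",
                          start = as.integer(sample(0:(L - 100), 300)),
                          strand = sample(c("+", "-"), 300, replace = TRUE),
                          read_id = 1:300)
  reads$end <- reads$start + 60L
  f1 <- polya_read_fraction(
    intersect_intronic(scan_polya(c(chr1 = s)), reads), reads
  )
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  flipped <- dplyr::mutate(reads, start2 = L - end, end = L - start,
                           start = start2,
                           strand = ifelse(strand == "+", "-", "+"))
  f2 <- polya_read_fraction(
    intersect_intronic(scan_polya(c(chr1 = rc)), flipped), flipped
  )
  expect_equal(f1, f2)
})
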