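make_two_gene_models <- function() {
  # g1: exon [0,100) + intron [100,300) + exon [300,400), plus strand
  # g2: disjoint downstream gene [1000,1500) with intron [1100,1400)
  derive_introns(read_gene_models(write_test_gtf(list(
    tg("g1", 0, 400, list(c(0, 100), c(300, 400))),
    tg("g2", 1000, 1500, list(c(1000, 1100), c(1400, 1500)))
  ))))
}

read_row <- function(start, end, strand = "+", cb = "AAAACCCCGGGG",
                     umi = "ACGTACGT", chrom = "chr1") {
  tibble::tibble(cell_barcode = cb, umi = umi, chrom = chrom,
                 start = start, end = end, strand = strand)
}

test_that("reads are assigned to exonic/intronic/ambiguous/intergenic", {
  gm <- make_two_gene_models()
  reads <- dplyr::bind_rows(
    read_row(50, 110),     # overlaps exon and intron of g1 -> exonic
    read_row(150, 210),    # inside g1 intron -> intronic
    read_row(600, 660),    # between genes -> intergenic
    read_row(1120, 1180)   # g2 intron -> intronic
  )
  asn <- assign_reads(reads, gm)
  expect_equal(asn$region, c("exonic", "intronic", "intergenic", "intronic"))
  expect_equal(asn$gene_id, c("g1", "g1", NA, "g2"))

  # conservation across categories
  fr <- region_fractions(asn)
  expect_equal(sum(fr$reads), nrow(reads))
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
})

test_that("overlapping genes make reads ambiguous unless exon priority", {
  # g1 exon [0,100); g2 spans [50, 450) with exon [400,450): bases
  # [50,100) are exonic in g1 and intronic in g2
  gm <- derive_introns(read_gene_models(write_test_gtf(list(
    tg("g1", 0, 100, list(c(0, 100))),
    tg("g2", 50, 450, list(c(50, 60), c(400, 450)))
  ))))
  r <- read_row(60, 95)
  expect_equal(assign_reads(r, gm)$region, "ambiguous")
  expect_true(is.na(assign_reads(r, gm)$gene_id))
  rescued <- assign_reads(r, gm, exon_priority = TRUE)
  expect_equal(rescued$region, "exonic")
  expect_equal(rescued$gene_id, "g1")
})

test_that("stranded assignment ignores opposite-strand features", {
  gm <- derive_introns(read_gene_models(write_test_gtf(list(
    tg("g1", 0, 400, list(c(0, 400)), strand = "+")
  ))))
  r_minus <- read_row(100, 160, strand = "-")
  expect_equal(assign_reads(r_minus, gm, stranded = TRUE)$region,
               "intergenic")
  expect_equal(assign_reads(r_minus, gm, stranded = FALSE)$region, "exonic")

  # unknown chromosome: intergenic with a warning
  r_off <- read_row(0, 60, chrom = "chrZ")
  expect_warning(a <- assign_reads(r_off, gm), "chrZ")
  expect_equal(a$region, "intergenic")
})

test_that("assignment matches a per-base membership oracle on random layouts", {
  set.seed(21)
  # random genes, some overlapping, on one chromosome
  genes <- lapply(1:15, function(i) {
    st <- random_gene_structure()
    shift <- sample(0:4000, 1)
    tg(sprintf("g%02d", i), st$start + shift, st$end + shift,
       lapply(asplit(st$exons, 1), function(e) e + shift))
  })
  gm <- derive_introns(read_gene_models(write_test_gtf(genes)))

  reads <- dplyr::bind_rows(lapply(1:300, function(i) {
    s <- sample(0:6000, 1)
    read_row(s, s + 60, umi = sprintf("UMI%05d", i))
  }))
  asn <- assign_reads(reads, gm)

  # oracle: per-base feature membership, brute force over genes
  iv <- gene_intervals(gm, "both")
  oracle_one <- function(s, e) {
    bases <- s:(e - 1)
    touch <- iv[vapply(seq_len(nrow(iv)), function(k) {
      any(bases >= iv$start[k] & bases < iv$end[k])
    }, logical(1)), ]
    gset <- unique(touch$gene_id)
    if (length(gset) == 0) return("intergenic")
    if (length(gset) > 1) return("ambiguous")
    if (any(touch$feature == "exonic")) "exonic" else "intronic"
  }
  expected <- vapply(seq_len(nrow(reads)), function(i) {
    oracle_one(reads$start[i], reads$end[i])
  }, character(1))
  expect_equal(asn$region, expected)
})

test_that("UMI counting deduplicates within gene and cell", {
  asn <- tibble::tibble(
    cell_barcode = "c1",
    umi = c("u1", "u1", "u1", "u2", "u1"),
    gene_id = c("gA", "gA", "gA", "gA", "gB"),
    region = "exonic"
  )
  m <- count_umis(asn, "exon_only")
  expect_equal(as.numeric(m$counts["gA", "c1"]), 2)
  expect_equal(as.numeric(m$counts["gB", "c1"]), 1)

  # a UMI seen in exon and intron of the same gene counts once
  asn2 <- tibble::tibble(
    cell_barcode = "c1", umi = c("u1", "u1"), gene_id = "gA",
    region = c("exonic", "intronic")
  )
  m2 <- count_umis(asn2, "exon_plus_intron")
  expect_equal(as.numeric(m2$counts["gA", "c1"]), 1)
})

test_that("UMI counting equals a set-count brute force on planted triplets", {
  set.seed(13)
  triplets <- tibble::tibble(
    cell_barcode = sample(sprintf("c%02d", 1:10), 500, replace = TRUE),
    gene_id = sample(sprintf("g%02d", 1:20), 500, replace = TRUE),
    umi = sample(sprintf("u%03d", 1:50), 500, replace = TRUE),
    region = sample(c("exonic", "intronic", "ambiguous", "intergenic"),
                    500, replace = TRUE, prob = c(.4, .3, .15, .15))
  )
  # add duplicate reads of the same molecules
  asn <- dplyr::bind_rows(triplets, triplets[sample(500, 200), ])

  for (mode in c("exon_only", "exon_plus_intron")) {
    admitted <- if (mode == "exon_only") "exonic" else
      c("exonic", "intronic")
    m <- count_umis(asn, mode)
    sets <- unique(asn[asn$region %in% admitted,
                       c("cell_barcode", "gene_id", "umi")])
    brute <- table(sets$gene_id, sets$cell_barcode)
    for (g in rownames(m$counts)) for (cc in colnames(m$counts)) {
      expect_equal(as.numeric(m$counts[g, cc]),
                   if (g %in% rownames(brute) && cc %in% colnames(brute)) {
                     as.numeric(brute[g, cc])
                   } else 0)
    }
  }

  # entrywise monotonicity on a shared universe
  both <- count_umis(asn, "exon_plus_intron")
  exon <- count_umis(asn, "exon_only", gene_ids = rownames(both$counts),
                     cell_barcodes = colnames(both$counts))
  expect_true(all(both$counts - exon$counts >= 0))
})

test_that("matrix merging unions genes and preserves columns", {
  a <- make_counts(matrix(5, 1, 1, dimnames = list("gA", "c1")))
  b <- make_counts(matrix(7, 1, 1, dimnames = list("gB", "c2")))
  m <- merge_count_matrices(list(a, b))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(as.numeric(m$counts["gA", "c1"]), 5)
  expect_equal(as.numeric(m$counts["gB", "c2"]), 7)
  expect_equal(as.numeric(m$counts["gA", "c2"]), 0)

  # merging one matrix is the identity
  expect_equal(as.matrix(merge_count_matrices(list(a))$counts),
               as.matrix(a$counts))

  # split/merge round trip
  set.seed(31)
  big <- make_counts(matrix(rpois(200, 1), 10, 20))
  left <- make_counts(as.matrix(big$counts[, 1:8]))
  right <- make_counts(as.matrix(big$counts[, 9:20]))
  back <- merge_count_matrices(list(left, right))
  expect_equal(as.matrix(back$counts[rownames(big$counts),
                                     colnames(big$counts)]),
               as.matrix(big$counts))

  # barcode collision without suffixes errors; with suffixes it works
  expect_error(merge_count_matrices(list(a, a)), "collision")
  ok <- merge_count_matrices(list(a, a), suffixes = c("r1", "r2"))
  expect_setequal(colnames(ok$counts), c("c1-r1", "c1-r2"))
})

test_that("MatrixMarket round trip is exact", {
  set.seed(17)
  m <- make_counts(matrix(rpois(200 * 300, 0.05), 200, 300), "exon_only")
  prefix <- tempfile()
  write_counts(m, prefix)
  back <- read_counts(prefix)
  expect_equal(as.matrix(back$counts), as.matrix(m$counts))
  expect_equal(back$mode, "exon_only")

  # tiny matrix with one nonzero: exactly one data line after the header
  one <- make_counts(matrix(c(0, 0, 3, 0), 2, 2))
  p1 <- tempfile()
  write_counts(one, p1)
  body <- grep("^%", readLines(paste0(p1, ".mtx")), invert = TRUE,
               value = TRUE)
  expect_equal(length(body), 2)  # dimension line + one entry

  # dimension mismatch between matrix and id files is an error
  writeLines(c(readLines(paste0(p1, ".genes.tsv")), "extra"),
             paste0(p1, ".genes.tsv"))
  expect_error(read_counts(p1), "id files")
})
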