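test_that("the normalization ladder computes TP10k, log, standardized", {
  m <- make_counts(matrix(c(2L, 8L), 2, 1,
                          dimnames = list(c("g1", "g2"), "c1")))
  tp <- normalize_counts(m, "tp10k")
  expect_equal(unname(tp[, 1]), c(2000, 8000))
  expect_equal(attr(tp, "ladder"), "tp10k")

  set.seed(71)
  r <- make_counts(matrix(rpois(50 * 40, 2) + 1L, 50, 40))
  tp_r <- normalize_counts(r, "tp10k")
  expect_true(all(abs(colSums(tp_r) - 1e4) < 1e-6))

  # log rung: zero TP10k maps to 0 through the pseudo-count
  lg <- normalize_counts(r, "log1p_tp10k")
  expect_equal(lg, log1p(tp_r), ignore_attr = TRUE)

  # standardized rows: mean 0 variance 1 (brute-force recompute)
  st <- normalize_counts(r, "standardized")
  expect_true(all(abs(rowMeans(st)) < 1e-9))
  expect_true(all(abs(apply(st, 1, var) - 1) < 1e-9))

  # constant genes become zero rows and are flagged
  mc <- as.matrix(r$counts)
  mc[1, ] <- 0L
  stc <- normalize_counts(make_counts(mc), "standardized")
  expect_true(all(stc[1, ] == 0))
  expect_equal(attr(stc, "constant_genes"), rownames(mc)[1])

  # all-zero cells must be filtered first
  mz <- as.matrix(m$counts)
  mz <- cbind(mz, c0 = c(0L, 0L))
  expect_error(normalize_counts(make_counts(mz)), "filter_matrix")

  # normalization commutes with column permutation
  perm <- sample(ncol(r$counts))
  st_perm <- normalize_counts(make_counts(as.matrix(r$counts)[, perm]),
                              "standardized")
  expect_equal(st_perm, st[, perm], ignore_attr = TRUE)
})

test_that("variable-gene selection flags planted high-dispersion genes", {
  set.seed(73)
  n_cells <- 60
  base <- matrix(rep(log1p(10), 50 * n_cells), 50, n_cells)
  base <- base + matrix(rnorm(50 * n_cells, sd = 0.01), 50, n_cells)
  planted <- matrix(log1p(c(0, 25)[rep(1:2, length.out = n_cells)]),
                    1, n_cells)
  lx <- rbind(base, planted)
  rownames(lx) <- c(sprintf("flat%02d", 1:50), "planted")

  hv <- select_hvg(lx, n_bins = 5)
  expect_true(hv$selected[hv$gene_id == "planted"])
  expect_equal(hv$gene_id[which.max(hv$dispersion_z)], "planted")

  # high dispersion but sub-threshold mean expression is screened out
  dim_gene <- matrix(log1p(c(0, 0.2)[rep(1:2, length.out = n_cells)]),
                     1, n_cells, dimnames = list("dim", NULL))
  hv_dim <- select_hvg(rbind(lx, dim_gene), n_bins = 5)
  expect_false(hv_dim$selected[hv_dim$gene_id == "dim"])

  # a constant gene is never selected under real thresholds
  cx <- rbind(lx, constant = rep(log1p(10), n_cells))
  hv2 <- select_hvg(cx, n_bins = 5)
  expect_false(hv2$selected[hv2$gene_id == "constant"])

  # thresholds at -Inf select everything
  hv3 <- select_hvg(lx, dispersion_min = -Inf, mean_min = -Inf, n_bins = 5)
  expect_true(all(hv3$selected))

  # fewer genes than bins: bins reduced with a warning
  expect_warning(select_hvg(lx[1:3, ], n_bins = 20), "bins")
})

test_that("pseudo-bulk aggregation sums counts then log-normalizes", {
  m <- make_counts(matrix(c(1L, 0L, 3L, 4L), 2, 2,
                          dimnames = list(c("g1", "g2"), c("c1", "c2"))))
  pb <- pseudobulk_profiles(m, c(c1 = "grp", c2 = "grp"))
  expect_equal(unname(pb[, "grp"]), log1p(c(5000, 5000)))

  # a single-cell group equals that cell's log1p TP10k
  pb2 <- pseudobulk_profiles(m, c(c1 = "a", c2 = "b"))
  lg <- normalize_counts(m, "log1p_tp10k")
  expect_equal(unname(pb2[, "a"]), unname(lg[, "c1"]))

  # random groups equal a brute-force group-sum recompute
  set.seed(79)
  r <- make_counts(matrix(rpois(30 * 20, 2) + 1L, 30, 20))
  lab <- sample(c("x", "y", "z"), 20, replace = TRUE)
  names(lab) <- colnames(r$counts)
  pb3 <- pseudobulk_profiles(r, lab)
  for (L in c("x", "y", "z")) {
    sums <- rowSums(as.matrix(r$counts)[, lab == L, drop = FALSE])
    expect_equal(unname(pb3[, L]), unname(log1p(1e4 * sums / sum(sums))))
  }

  expect_error(pseudobulk_profiles(m, c(c1 = "a")), "no group label")
})

test_that("correlation profiles match the textbook formula", {
  q <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("g", 1:3), "q"))
  expect_equal(as.numeric(correlate_profiles(q, q)), 1)
  r <- matrix(c(3, 2, 1), 3, 1, dimnames = list(paste0("g", 1:3), "r"))
  expect_equal(as.numeric(correlate_profiles(q, r)), -1)

  set.seed(83)
  qm <- matrix(rnorm(40), 20, 2,
               dimnames = list(sprintf("g%02d", 1:20), c("q1", "q2")))
  rm_ <- matrix(rnorm(60), 20, 3,
                dimnames = list(sprintf("g%02d", 1:20), c("r1", "r2", "r3")))
  cc <- correlate_profiles(qm, rm_)
  for (i in 1:2) for (j in 1:3) {
    x <- qm[, i]; y <- rm_[, j]
    manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unclass(cc)[i, j], manual)
  }

  # invariant to affine rescaling of either side
  cc2 <- correlate_profiles(qm * 3 + 7, rm_)
  expect_equal(unclass(cc2), unclass(cc), ignore_attr = TRUE)

  # zero-variance profile yields NA with a warning
  qz <- cbind(qm, flat = rep(1, 20))
  expect_warning(ccz <- correlate_profiles(qz, rm_), "zero variance")
  expect_true(all(is.na(unclass(ccz)["flat", ])))

  expect_error(correlate_profiles(qm[1:2, , drop = FALSE],
                                  rm_[1:2, , drop = FALSE]), "at least 3")
})

test_that("pseudobulk of a union lies between the parts on the count scale", {
  set.seed(89)
  r <- make_counts(matrix(rpois(30 * 10, 3) + 1L, 30, 10))
  ga <- colnames(r$counts)[1:4]
  gb <- colnames(r$counts)[5:10]
  dense <- as.matrix(r$counts)
  sum_a <- rowSums(dense[, ga]); sum_b <- rowSums(dense[, gb])
  sum_ab <- rowSums(dense)
  expect_true(all(sum_ab >= pmin(sum_a, sum_b) &
                  sum_ab <= sum_a + sum_b))
})

test_that("bi-clustering groups planted blocks and handles degenerates", {
  # identical columns merge first and sit adjacent
  set.seed(97)
  m <- matrix(rnorm(36), 6, 6,
              dimnames = list(paste0("r", 1:6), paste0("c", 1:6)))
  m[, 2] <- m[, 5]
  bc <- bicluster(m)
  pos <- match(c(2, 5), bc$col_order)
  expect_equal(abs(diff(pos)), 1)

  # planted 2-block structure groups by block in rows and columns
  blocks <- matrix(0.1, 6, 6, dimnames = list(paste0("r", 1:6),
                                              paste0("c", 1:6)))
  blocks[1:3, 1:3] <- 0.9
  blocks[4:6, 4:6] <- 0.85
  blocks <- blocks + matrix(rnorm(36, sd = 0.02), 6, 6)
  bb <- bicluster(blocks)
  grouped <- function(ord) {
    pos <- sort(match(1:3, ord))
    all(pos %in% 1:3) || all(pos %in% 4:6)
  }
  expect_true(grouped(bb$row_order))
  expect_true(grouped(bb$col_order))

  # degenerate shapes return identity orders
  one_row <- matrix(rnorm(4), 1, 4)
  expect_equal(bicluster(one_row)$row_order, 1)
  expect_setequal(bicluster(one_row)$col_order, 1:4)
})
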