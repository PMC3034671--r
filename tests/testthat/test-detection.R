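test_that("pooled-variance t statistic matches hand evaluation", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE)
  r <- t_test_line(m, "row", 1, alpha = 0.01)
  expect_equal(r$statistic, -3 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_false(r$flagged)

  # equal means -> t = 0, p = 1
  m2 <- rbind(c(1, 3), c(0, 4), c(2, 2))
  r2 <- t_test_line(m2, "row", 1, alpha = 0.05)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  # a strongly shifted line is flagged at alpha = 0.01
  set.seed(1)
  m3 <- matrix(rnorm(96), 8, 12)
  m3[, 4] <- m3[, 4] + 10
  r3 <- t_test_line(m3, "column", 4, alpha = 0.01)
  expect_true(r3$flagged)
  expect_lt(r3$p_value, 1e-6)

  expect_error(t_test_line(m, "row", 9), "out of range")
  small <- matrix(c(1, 2, NA, NA), 2, 2)
  expect_error(t_test_line(small, "row", 2), "fewer than 2 valid wells")
})

test_that("t statistic equals the textbook pooled t on random splits", {
  set.seed(2)
  for (i in 1:100) {
    m <- matrix(rnorm(48, sd = runif(1, 0.5, 3)), 6, 8)
    line <- sample(c("row", "column"), 1)
    idx <- if (line == "row") sample(6, 1) else sample(8, 1)
    s1 <- if (line == "row") m[idx, ] else m[, idx]
    s2 <- if (line == "row") as.vector(m[-idx, ]) else as.vector(m[, -idx])
    ours <- t_test_line(m, line, idx)
    ref <- t.test(s1, s2, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("t-test is invariant under positive affine transforms of the plate", {
  set.seed(3)
  m <- matrix(rnorm(96), 8, 12)
  r1 <- t_test_line(m, "column", 7)
  r2 <- t_test_line(3.5 * m + 11, "column", 7)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("assay t scan covers every line and degenerates sensibly", {
  a <- random_assay(3, 8, 12, seed = 4)
  sc <- scan_assay_ttest(a, alpha = 0.01)
  expect_equal(nrow(sc), 3 * (8 + 12))
  expect_equal(sum(sc$line == "row"), 3 * 8)
  # alpha = 1 flags everything (p < 1 almost surely)
  sc1 <- scan_assay_ttest(a, alpha = 1)
  expect_true(all(sc1$flagged))
  # fully masked control columns yield NA results, reported not fatal
  am <- mask_wells(a, cols = c(1, 12))
  scm <- scan_assay_ttest(am, alpha = 0.01)
  expect_true(all(is.na(scm$statistic[scm$line == "column" & scm$index %in% c(1, 12)])))
  expect_false(anyNA(scm$statistic[scm$line == "row"]))
})

test_that("chi-squared statistics match direct evaluation and a brute-force oracle", {
  s <- surface_from_counts(rbind(c(1, 2, 3), c(5, 1, 0)))
  expect_equal(s$expected, 2)
  r <- chi2_line(s, "row", 1)
  expect_equal(r$statistic, 1.0)
  expect_equal(r$df, 2)

  s2 <- surface_from_counts(matrix(c(4, 0, 0, 4), 2, 2))
  rs <- chi2_surface(s2)
  expect_equal(rs$statistic, 8)
  expect_equal(rs$df, 3)

  uniform <- surface_from_counts(matrix(2, 4, 4))
  expect_equal(chi2_surface(uniform)$statistic, 0)
  expect_equal(chi2_surface(uniform)$p_value, 1)
  expect_equal(chi2_line(uniform, "column", 2)$statistic, 0)

  expect_error(chi2_surface(surface_from_counts(matrix(0, 3, 3))), "no hits")

  set.seed(5)
  counts <- matrix(rpois(96, 3), 8, 12)
  s3 <- surface_from_counts(counts)
  E <- sum(counts) / 96
  brute <- sum(vapply(seq_len(96), function(k) (counts[k] - E)^2 / E, numeric(1)))
  expect_identical(chi2_surface(s3)$statistic, brute)
  brute_row <- sum((counts[3, ] - E)^2 / E)
  expect_identical(chi2_line(s3, "row", 3)$statistic, brute_row)
  sc <- scan_surface_chi2(s3)
  expect_equal(nrow(sc), 20)
})

test_that("DFT power spectrum matches closed forms and skips masked wells", {
  # constant signal: all energy at DC, which is excluded
  expect_true(all(dft_power_spectrum(matrix(2, 4, 4))$powers < 1e-18))

  # alternating +1/-1 of length 16 puts all power n^2 at the Nyquist bin
  alt <- matrix(rep(c(1, -1), 8), 4, 4) # column-major fill alternates down columns
  sp <- dft_power_spectrum(alt, "column_major")
  expect_equal(sp$powers[8], 16^2, tolerance = 1e-9)
  expect_true(all(abs(sp$powers[-8]) < 1e-18))

  # masked wells are dropped from the unrolled sequence
  m <- matrix(rnorm(24), 4, 6)
  msk <- matrix(TRUE, 4, 6)
  msk[2, 3] <- FALSE
  p <- plate_grid(m, msk)
  sp2 <- dft_power_spectrum(p, "row_major")
  expect_equal(sp2$n, 23)
  expect_length(sp2$powers, 22)

  expect_error(dft_power_spectrum(matrix(c(1, 2, NA, NA), 2, 2)), "at least 4")
})

test_that("DFT spectrum equals the naive transform", {
  set.seed(6)
  x <- rnorm(30)
  sp <- dft_power_spectrum(matrix(x, 5, 6), "column_major")
  naive <- vapply(1:29, function(k) {
    j <- 0:29
    Mod(sum(x * exp(-2i * pi * k * j / 30)))^2
  }, numeric(1))
  expect_equal(sp$powers, naive, tolerance = 1e-9)
})

test_that("rank-based K-S statistic is forced by the tie structure", {
  expect_equal(ks_statistic(c(3, 1, 2, 5, 4)), 1 / 5)
  expect_equal(ks_statistic(rep(2, 4)), 1)
  set.seed(7)
  for (i in 1:50) {
    y <- sample(rexp(sample(3:20, 1)), replace = TRUE)
    d <- ks_statistic(y)
    expect_gte(d, 1 / length(y))
    expect_lte(d, 1)
  }
})

test_that("DFT + K-S plate test flags strong column effects via the row-major order", {
  set.seed(8)
  hits <- replicate(100, {
    m <- matrix(rnorm(96), 8, 12)
    m[, 5] <- m[, 5] + 3
    ks_test_plate(m, alpha = 0.01, orders = "row_major")$flagged
  })
  expect_gte(mean(hits), 0.9)

  # alpha = 0 never flags
  expect_false(any(ks_test_plate(matrix(rnorm(96), 8, 12), alpha = 0)$flagged))

  # per-line expansion: row-major decision lands on columns, column-major on rows
  a <- hts_assay(list(plate_grid(matrix(rnorm(96), 8, 12))))
  sc <- scan_assay_ks(a, alpha = 0.05)
  expect_equal(nrow(sc), 20)
  kt <- ks_test_plate(a$plates[[1]], alpha = 0.05)
  expect_true(all(
    sc$flagged[sc$line == "column"] == kt$flagged[kt$order == "row_major"]
  ))
  expect_true(all(
    sc$flagged[sc$line == "row"] == kt$flagged[kt$order == "column_major"]
  ))
})

test_that("t-test power on type-B data is non-decreasing in error size", {
  res <- run_simulation1(
    format = "96", n_plates = 20, h = 1,
    err_sds = c(0.6, 1.2, 1.8, 2.4, 3.0), types = "B", tests = "t",
    alpha = 0.01, n_datasets = 10, seed = 101
  )
  expect_false(is.unsorted(res$sensitivity))
})
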