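test_that("hit selection applies mu - c*sigma to valid wells", {
  v <- matrix(0, 8, 12)
  v[1, 1] <- -10
  a <- hts_assay(list(plate_grid(v)))
  hits <- select_hits(a, 3, "plate_wise")
  expect_equal(sum(hits[[1]]), 1)
  expect_true(hits[[1]][1, 1])

  # c = 0 selects the at-or-below-mean mass
  set.seed(1)
  a2 <- random_assay(1, 8, 12, seed = 1)
  h0 <- select_hits(a2, 0)[[1]]
  expect_identical(h0, a2$plates[[1]]$values <= mean(valid_values(a2$plates[[1]])))

  expect_error(select_hits(hts_assay(list(plate_grid(matrix(1, 2, 2))))), "sigma = 0")
})

test_that("hit sets nest as the threshold relaxes and are affine-invariant", {
  a <- random_assay(5, 8, 12, seed = 2)
  h3 <- select_hits(a, 3)
  h229 <- select_hits(a, 2.29)
  h2 <- select_hits(a, 2)
  for (p in 1:5) {
    expect_true(all(h2[[p]][h229[[p]]]))
    expect_true(all(h229[[p]][h3[[p]]]))
  }
  # per-plate positive affine transform leaves plate-wise hits unchanged
  b <- a
  for (p in 1:5) b$plates[[p]]$values <- 2.5 * b$plates[[p]]$values + p
  expect_identical(select_hits(b, 2.29), h229)
})

test_that("hit surfaces count hits per location and mask control columns", {
  a <- mask_wells(random_assay(6, 8, 12, seed = 3), cols = c(1, 12))
  surf <- hit_distribution_surface(a, 2, "plate_wise")
  hits <- select_hits(a, 2, "plate_wise")
  expect_equal(surf$total, sum(vapply(hits, sum, integer(1))))
  expect_equal(sum(surf$counts[surf$mask]), surf$total)
  expect_true(all(is.na(surf$counts[, c(1, 12)])))
  expect_equal(surf$expected, surf$total / 80)
  expect_true(all(surf$counts[surf$mask] >= 0 & surf$counts[surf$mask] <= 6))

  single <- hit_distribution_surface(random_assay(1, 8, 12, seed = 4), 2)
  expect_true(all(single$counts %in% 0:1))
})

test_that("a constant column bias inflates the affected column counts", {
  base <- generate_base_assay(50, "96", seed = 5)
  spec <- make_error_spec("B", "96", err_sd = 3, noise_sd = 0, seed = 6)
  # force a strongly negative offset so the column gains hits
  spec$col_offsets <- -abs(spec$col_offsets) - 2
  out <- apply_error(base, spec)
  surf <- hit_distribution_surface(out$assay, 3, "plate_wise")
  j <- spec$cols[1]
  expect_gt(mean(surf$counts[, j]), surf$expected)
  expect_true(chi2_line(surf, "column", j, alpha = 0.01)$flagged)
})

test_that("replicate combination averages pairs under each policy", {
  a <- random_replicated_assay(4, 8, 12, seed = 7)
  # make pairs identical
  a$plates[[2]]$values <- a$plates[[1]]$values
  a$plates[[4]]$values <- a$plates[[3]]$values
  avg <- combine_replicates(a, corrector = "none")
  expect_equal(n_plates(avg), 2)
  expect_equal(avg$plates[[1]]$values, a$plates[[1]]$values)

  # without correction the average is the elementwise mean
  b <- random_replicated_assay(2, 8, 12, seed = 8)
  avg_b <- combine_replicates(b, corrector = "none")
  expect_equal(
    avg_b$plates[[1]]$values,
    (b$plates[[1]]$values + b$plates[[2]]$values) / 2
  )

  expect_error(combine_replicates(random_assay(2, 4, 6, seed = 9)), "pairing")
})

test_that("detection-gated B-score policy corrects only the flagged replicate", {
  # full 12x12 circulant: every row and column holds the same value multiset,
  # so all line t statistics are exactly 0 and the clean replicate can never
  # be flagged; plate 1 then gets a strong injected column effect
  set.seed(10)
  base <- rnorm(12)
  circulant <- t(vapply(0:11, function(s) base[(seq_len(12) + s - 1) %% 12 + 1],
                        numeric(12)))
  clean <- circulant
  biased <- circulant
  biased[, 6] <- biased[, 6] + 3 # injected column effect in plate 1 only
  a <- hts_assay(
    list(plate_grid(biased), plate_grid(clean)),
    replicate_of = c(2L, 1L)
  )
  sc <- scan_assay_ttest(a, 0.01)
  expect_true(any(sc$flagged[sc$plate == 1]))
  expect_false(any(sc$flagged[sc$plate == 2]))

  avg <- combine_replicates(a, alpha = 0.01, corrector = "bscore_if_flagged")
  expect_equal(n_plates(avg), 1)
  # plate 1 B-scored then both Z-scored: the average equals the mean of
  # zscore(bscore(plate1)) and zscore(plate2)
  p1 <- zscore_plate(bscore_plate(a$plates[[1]]))
  p2 <- zscore_plate(a$plates[[2]])
  expect_equal(avg$plates[[1]]$values, (p1$values + p2$values) / 2, tolerance = 1e-12)
})

test_that("consensus hits are a subset of average hits", {
  # identical replicates: the two lists coincide
  a <- random_replicated_assay(2, 8, 12, seed = 11)
  a$plates[[2]]$values <- a$plates[[1]]$values
  both <- consensus_and_average_hits(a, 2)
  expect_identical(both$consensus, both$average)

  # (-4 sigma, 0) pair: average hit at c <= 2 but never a consensus hit
  v1 <- matrix(rnorm(96), 8, 12)
  v2 <- matrix(rnorm(96), 8, 12)
  v1 <- (v1 - mean(v1)) / sd(v1)
  v2 <- (v2 - mean(v2)) / sd(v2)
  v1[1, 1] <- -4
  v2[1, 1] <- 0
  b <- hts_assay(list(plate_grid(v1), plate_grid(v2)), replicate_of = c(2L, 1L))
  res2 <- consensus_and_average_hits(b, 1.9, scope = "assay_wise")
  expect_false(any(res2$consensus$row == 1 & res2$consensus$col == 1))
  expect_true(any(res2$average$row == 1 & res2$average$col == 1))

  # property: consensus subset of average on random replicated assays
  for (s in 1:200) {
    r <- random_replicated_assay(2, 4, 6, seed = 1000 + s)
    cc <- consensus_and_average_hits(r, runif(1, 1, 3))
    key <- function(d) paste(d$pair, d$row, d$col)
    expect_true(all(key(cc$consensus) %in% key(cc$average)))
  }
})
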