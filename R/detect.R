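# Systematic-error detection tests: pooled-variance t-test scan, chi-squared
# goodness-of-fit on hit surfaces, and DFT power spectrum + Kolmogorov-Smirnov.

.as_value_mask <- function(x) {
  if (inherits(x, "plate_grid")) {
    list(values = x$values, mask = x$mask)
  } else if (inherits(x, "hit_surface")) {
    list(values = x$counts, mask = x$mask)
  } else if (is.matrix(x)) {
    list(values = x, mask = !is.na(x))
  } else {
    stop("expected a plate_grid, hit_surface or numeric matrix")
  }
}

# Pooled two-sample t for all rows and columns of one masked matrix at once.
# Each line is tested against all remaining valid wells of the same matrix.
.t_scan_matrix <- function(values, mask, alpha, plate = NA_integer_) {
  v <- values
  v[!mask] <- NA_real_
  n_row_valid <- rowSums(mask)
  n_col_valid <- colSums(mask)
  rs <- rowSums(v, na.rm = TRUE)
  cs <- colSums(v, na.rm = TRUE)
  rss <- rowSums(v^2, na.rm = TRUE)
  css <- colSums(v^2, na.rm = TRUE)
  N <- sum(mask)
  S <- sum(rs)
  SS <- sum(rss)
  line_stats <- function(n1, s1, ss1) {
    n2 <- N - n1
    ok <- n1 >= 2L & n2 >= 2L
    mean1 <- ifelse(n1 > 0, s1 / n1, NA_real_)
    mean2 <- (S - s1) / pmax(n2, 1L)
    var1 <- (ss1 - n1 * mean1^2) / pmax(n1 - 1L, 1L)
    var2 <- ((SS - ss1) - n2 * mean2^2) / pmax(n2 - 1L, 1L)
    sp2 <- ((n1 - 1L) * var1 + (n2 - 1L) * var2) / (n1 + n2 - 2L)
    # degenerate lines (too few valid wells) are masked to NA below; the
    # arithmetic may produce NaN for them, which is expected and silenced
    tt <- suppressWarnings((mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2)))
    df <- n1 + n2 - 2L
    p <- suppressWarnings(2 * stats::pt(-abs(tt), df))
    data.frame(
      n1 = n1, n2 = n2,
      statistic = ifelse(ok, tt, NA_real_),
      df = ifelse(ok, df, NA_integer_),
      p_value = ifelse(ok, p, NA_real_)
    )
  }
  rows <- line_stats(n_row_valid, rs, rss)
  cols <- line_stats(n_col_valid, cs, css)
  out <- rbind(
    data.frame(plate = plate, line = "row", index = seq_len(nrow(values)), rows),
    data.frame(plate = plate, line = "column", index = seq_len(ncol(values)), cols)
  )
  out$alpha <- alpha
  out$flagged <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Pooled-variance t-test of one plate line against the remainder
#'
#' Tests whether the valid wells of one row or column differ in mean from all
#' remaining valid wells of the same plate (or hit-distribution surface). The
#' two-sample statistic uses the pooled variance
#' `s_p^2 = ((N1-1) s1^2 + (N2-1) s2^2) / (N1+N2-2)` and a two-sided p-value
#' from Student's t with `N1+N2-2` degrees of freedom. Rejection means the
#' line carries systematic error.
#'
#' @param x A `plate_grid`, `hit_surface`, or numeric matrix (`NA` = masked).
#' @param line `"row"` or `"column"`.
#' @param index 1-based line index.
#' @param alpha Significance level (no multiplicity adjustment, by design).
#' @return One-row data.frame: `plate`, `line`, `index`, `n1`, `n2`,
#'   `statistic`, `df`, `p_value`, `alpha`, `flagged`.
#' @export
t_test_line <- function(x, line = c("row", "column"), index, alpha = 0.01) {
  line <- match.arg(line)
  vm <- .as_value_mask(x)
  n_lines <- if (line == "row") nrow(vm$values) else ncol(vm$values)
  if (index < 1 || index > n_lines) stop("line index out of range")
  scan <- .t_scan_matrix(vm$values, vm$mask, alpha)
  res <- scan[scan$line == line & scan$index == index, , drop = FALSE]
  if (is.na(res$statistic)) {
    stop("t-test undefined: tested line or remainder has fewer than 2 valid wells")
  }
  rownames(res) <- NULL
  res
}

#' t-test scan of every row and column of every plate
#'
#' Runs [t_test_line()] on all `P * (n_row + n_col)` lines of the assay at a
#' raw per-test significance level. Lines with fewer than 2 valid wells on
#' either side yield `NA` statistics and are reported, not fatal.
#'
#' @param assay An `hts_assay`.
#' @param alpha Per-test significance level.
#' @return data.frame with one row per (plate, line); columns as in
#'   [t_test_line()].
#' @export
scan_assay_ttest <- function(assay, alpha = 0.01) {
  out <- lapply(assay$plates, function(p) {
    .t_scan_matrix(p$values, p$mask, alpha, plate = p$plate_index)
  })
  do.call(rbind, out)
}

#' Chi-squared goodness-of-fit test of one hit-surface line
#'
#' Under the no-error null, hits are uniform over well locations with
#' expected count E = total hits / number of valid locations. The statistic
#' is `sum((x - E)^2 / E)` over the tested line's valid cells, with an
#' upper-tail p-value on (cells in line - 1) degrees of freedom.
#'
#' @param surface A [hit_distribution_surface()] result (or counts matrix).
#' @param line `"row"` or `"column"`.
#' @param index 1-based line index.
#' @param alpha Significance level.
#' @return One-row data.frame as in [t_test_line()] (with `df` the chi-squared
#'   degrees of freedom).
#' @export
chi2_line <- function(surface, line = c("row", "column"), index, alpha = 0.01) {
  line <- match.arg(line)
  vm <- .as_value_mask(surface)
  E <- sum(vm$values[vm$mask]) / sum(vm$mask)
  if (E == 0) stop("chi-squared test undefined: surface contains no hits")
  cells <- if (line == "row") {
    vm$values[index, vm$mask[index, ]]
  } else {
    vm$values[vm$mask[, index], index]
  }
  stat <- sum((cells - E)^2 / E)
  df <- length(cells) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(
    plate = NA_integer_, line = line, index = index, n1 = length(cells),
    n2 = sum(vm$mask) - length(cells), statistic = stat, df = df,
    p_value = p, alpha = alpha, flagged = p < alpha
  )
}

#' Chi-squared goodness-of-fit test of a whole hit surface
#'
#' As [chi2_line()], but summed over every valid well location, with
#' (valid locations - 1) degrees of freedom. Sensitive to well-level error
#' not confined to a row or column.
#'
#' @inheritParams chi2_line
#' @return One-row data.frame.
#' @export
chi2_surface <- function(surface, alpha = 0.01) {
  vm <- .as_value_mask(surface)
  n_cells <- sum(vm$mask)
  E <- sum(vm$values[vm$mask]) / n_cells
  if (E == 0) stop("chi-squared test undefined: surface contains no hits")
  stat <- sum((vm$values[vm$mask] - E)^2 / E)
  df <- n_cells - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(
    plate = NA_integer_, line = "surface", index = NA_integer_, n1 = n_cells,
    n2 = 0L, statistic = stat, df = df, p_value = p, alpha = alpha,
    flagged = p < alpha
  )
}

#' Chi-squared scan of all rows and columns of a hit surface
#'
#' @inheritParams chi2_surface
#' @return data.frame with one row per surface line.
#' @export
scan_surface_chi2 <- function(surface, alpha = 0.01) {
  vm <- .as_value_mask(surface)
  rows <- lapply(seq_len(nrow(vm$values)), function(i) {
    chi2_line(surface, "row", i, alpha)
  })
  cols <- lapply(seq_len(ncol(vm$values)), function(j) {
    chi2_line(surface, "column", j, alpha)
  })
  do.call(rbind, c(rows, cols))
}

#' DFT power density spectrum of an unrolled plate
#'
#' Concatenates the valid wells in row-major order (first row, then second,
#' ...) or column-major order, skipping masked wells, and returns the squared
#' moduli of the discrete Fourier transform coefficients with the DC (zero
#' frequency) component excluded. Row-major unrolling turns a column effect
#' into a periodic signal (and vice versa), concentrating spectral power at
#' the corresponding frequency.
#'
#' @param x A `plate_grid`, `hit_surface`, or numeric matrix.
#' @param order `"row_major"` or `"column_major"`.
#' @return Object of class `power_spectrum`: `powers` (length n_valid - 1),
#'   `order`, `n` (sequence length).
#' @export
dft_power_spectrum <- function(x, order = c("row_major", "column_major")) {
  order <- match.arg(order)
  vm <- .as_value_mask(x)
  seqv <- if (order == "row_major") {
    t(vm$values)[t(vm$mask)]
  } else {
    vm$values[vm$mask]
  }
  if (length(seqv) < 4L) stop("DFT needs at least 4 valid wells")
  co <- stats::fft(seqv)
  powers <- Mod(co)^2
  structure(
    list(powers = powers[-1L], order = order, n = length(seqv)),
    class = "power_spectrum"
  )
}

#' Rank-based Kolmogorov-Smirnov statistic of a power spectrum
#'
#' The statistic as printed in the method's source: with the spectrum sorted
#' ascending and `F(y)` the fraction of spectrum values strictly below `y`,
#' `D = max_k max(F(y_(k)) - (k-1)/N, k/N - F(y_(k)))`. Because `F` is the
#' spectrum's own empirical count, this quantity depends only on the tie
#' structure: it equals 1/N for all-distinct values and grows only with
#' multiplicities (1 when all values are equal). It is retained for
#' reference; the operational plate test ([ks_test_plate()]) compares the
#' spectrum against a fitted normal instead, which is the form whose
#' behaviour the method's results describe.
#'
#' @param spectrum A `power_spectrum` or numeric vector.
#' @return The statistic D in \[1/N, 1\].
#' @export
ks_statistic <- function(spectrum) {
  y <- if (inherits(spectrum, "power_spectrum")) spectrum$powers else spectrum
  if (!length(y)) stop("empty spectrum")
  n <- length(y)
  ys <- sort(y)
  f <- (findInterval(ys, ys, left.open = TRUE)) / n # strict-lower count
  k <- seq_len(n)
  max(pmax(f - (k - 1) / n, k / n - f))
}

# Classical one-sample K-S distance of x from the normal with x's own
# moments (mean, sample sd).
.ks_normal_distance <- function(x) {
  n <- length(x)
  f0 <- stats::pnorm(sort(x), mean = mean(x), sd = stats::sd(x))
  k <- seq_len(n)
  max(pmax(f0 - (k - 1) / n, k / n - f0))
}

# Asymptotic Kolmogorov tail probability Q(lambda) = P(sqrt(N) D > lambda).
.kolmogorov_p <- function(lambda) {
  if (lambda <= 0) return(1)
  i <- 1:100
  p <- 2 * sum((-1)^(i - 1) * exp(-2 * i^2 * lambda^2))
  min(max(p, 0), 1)
}

#' DFT + Kolmogorov-Smirnov systematic-error test of a plate
#'
#' For each unrolling order, computes the DFT power spectrum and tests it for
#' normality with the one-sample Kolmogorov-Smirnov statistic against a
#' normal with the spectrum's own mean and SD; the p-value is the asymptotic
#' Kolmogorov tail probability of `sqrt(N) D`. A periodic positional effect
#' concentrates power at one frequency and makes the spectrum strongly
#' non-normal. The row-major sequence detects column effects; the
#' column-major sequence detects row effects. Note that spectra of pure-noise
#' plates already deviate from normality, so this test rejects more often
#' than the nominal level on error-free data — a known miscalibration of the
#' DFT+K-S approach.
#'
#' @param x A `plate_grid`, `hit_surface`, or numeric matrix.
#' @param alpha Significance level.
#' @param orders Unrolling orders to test (both by default).
#' @return data.frame with one row per order: `order`, `target` (the line
#'   type the order detects), `n`, `statistic` (D), `p_value`, `alpha`,
#'   `flagged`.
#' @export
ks_test_plate <- function(x, alpha = 0.01,
                          orders = c("row_major", "column_major")) {
  orders <- match.arg(orders, several.ok = TRUE)
  out <- lapply(orders, function(ord) {
    sp <- dft_power_spectrum(x, ord)
    n <- length(sp$powers)
    D <- .ks_normal_distance(sp$powers)
    p <- .kolmogorov_p(sqrt(n) * D)
    data.frame(
      order = ord,
      target = if (ord == "row_major") "column" else "row",
      n = n, statistic = D, p_value = p, alpha = alpha, flagged = p < alpha
    )
  })
  do.call(rbind, out)
}

#' DFT + K-S scan of every plate, expanded to per-line decisions
#'
#' Runs [ks_test_plate()] on every plate and propagates each order's single
#' decision to the lines it targets: the row-major result to every column of
#' the plate, the column-major result to every row. This yields the same
#' per-(plate, line) decision table as [scan_assay_ttest()], comparable
#' against ground truth.
#'
#' @param assay An `hts_assay`.
#' @param alpha Per-test significance level.
#' @return data.frame with one row per (plate, line).
#' @export
scan_assay_ks <- function(assay, alpha = 0.01) {
  nr <- assay$n_row
  nc <- assay$n_col
  out <- lapply(assay$plates, function(p) {
    kt <- ks_test_plate(p, alpha)
    col_row <- kt[kt$order == "row_major", ]
    row_row <- kt[kt$order == "column_major", ]
    rbind(
      data.frame(
        plate = p$plate_index, line = "row", index = seq_len(nr),
        n1 = rowSums(p$mask), n2 = sum(p$mask) - rowSums(p$mask),
        statistic = row_row$statistic, df = NA_integer_,
        p_value = row_row$p_value, alpha = alpha, flagged = row_row$flagged
      ),
      data.frame(
        plate = p$plate_index, line = "column", index = seq_len(nc),
        n1 = colSums(p$mask), n2 = sum(p$mask) - colSums(p$mask),
        statistic = col_row$statistic, df = NA_integer_,
        p_value = col_row$p_value, alpha = alpha, flagged = col_row$flagged
      )
    )
  })
  do.call(rbind, out)
}

#' Scan a hit-distribution surface with a chosen test
#'
#' Applies the t-test, chi-squared test, or DFT+K-S test to every row and
#' column of a hit surface, returning per-line decisions.
#'
#' @param surface A `hit_surface`.
#' @param test `"t"`, `"chi2"` or `"ks"`.
#' @param alpha Per-test significance level.
#' @return data.frame with one row per surface line.
#' @export
scan_surface <- function(surface, test = c("t", "chi2", "ks"), alpha = 0.01) {
  test <- match.arg(test)
  vm <- .as_value_mask(surface)
  if (test == "t") {
    .t_scan_matrix(vm$values, vm$mask, alpha)
  } else if (test == "chi2") {
    scan_surface_chi2(surface, alpha)
  } else {
    kt <- ks_test_plate(surface, alpha)
    col_row <- kt[kt$order == "row_major", ]
    row_row <- kt[kt$order == "column_major", ]
    rbind(
      data.frame(
        plate = NA_integer_, line = "row", index = seq_len(nrow(vm$values)),
        n1 = rowSums(vm$mask), n2 = sum(vm$mask) - rowSums(vm$mask),
        statistic = row_row$statistic, df = NA_integer_,
        p_value = row_row$p_value, alpha = alpha, flagged = row_row$flagged
      ),
      data.frame(
        plate = NA_integer_, line = "column", index = seq_len(ncol(vm$values)),
        n1 = colSums(vm$mask), n2 = sum(vm$mask) - colSums(vm$mask),
        statistic = col_row$statistic, df = NA_integer_,
        p_value = col_row$p_value, alpha = alpha, flagged = col_row$flagged
      )
    )
  }
}
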