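# Plate normalization and systematic-error correction procedures.

#' Percent-of-control normalization
#'
#' Divides every valid well by the positive-control mean.
#'
#' @param plate A `plate_grid`.
#' @param controls A [control_stats()] with nonzero `mu_pos`.
#' @return The normalized `plate_grid`.
#' @export
percent_of_control <- function(plate, controls) {
  if (is.na(controls$mu_pos) || controls$mu_pos == 0) {
    stop("percent-of-control undefined: mu_pos is zero or missing")
  }
  plate$values[plate$mask] <- plate$values[plate$mask] / controls$mu_pos
  plate
}

#' Normalized percent inhibition
#'
#' Affine rescale `(x - mu_neg) / (mu_pos - mu_neg)`: the negative-control
#' mean maps to 0 and the positive-control mean to 1.
#'
#' @inheritParams percent_of_control
#' @return The normalized `plate_grid`.
#' @export
normalized_percent_inhibition <- function(plate, controls) {
  if (is.na(controls$mu_pos) || is.na(controls$mu_neg) ||
      controls$mu_pos == controls$mu_neg) {
    stop("normalized percent inhibition undefined: mu_pos equals mu_neg (or missing)")
  }
  plate$values[plate$mask] <-
    (plate$values[plate$mask] - controls$mu_neg) /
    (controls$mu_pos - controls$mu_neg)
  plate
}

#' Z-score a plate
#'
#' Centers and scales the valid wells by the plate mean and sample SD, so the
#' output has mean 0 and SD 1 over valid wells.
#'
#' @param plate A `plate_grid` with nonconstant valid wells.
#' @return The normalized `plate_grid`.
#' @export
zscore_plate <- function(plate) {
  st <- plate_stats(plate)
  if (st["sd"] == 0) stop("Z-score undefined: plate is constant over valid wells")
  plate$values[plate$mask] <- (plate$values[plate$mask] - st["mean"]) / st["sd"]
  plate
}

#' Two-way median polish of a plate
#'
#' Tukey's alternating median-sweep decomposition of the plate into
#' grand + row effect + column effect + residual, computed over valid wells
#' only. Sweeps start from a zero grand effect, rows first, then columns,
#' re-centring the effect vectors by their medians, and stop when the largest
#' absolute change in any effect is at most `tol` or `max_iter` is reached.
#' The reconstruction identity (value = grand + row + col + residual on every
#' valid well) holds exactly by construction, converged or not.
#'
#' @param plate A `plate_grid` (>= 2 rows and columns).
#' @param max_iter Maximum number of full row+column sweeps.
#' @param tol Convergence tolerance on effect changes.
#' @return An object of class `median_polish` with elements `grand`,
#'   `row_effects`, `col_effects`, `residuals` (matrix, `NA` at masked
#'   wells), `iterations`, `converged`.
#' @export
median_polish <- function(plate, max_iter = 100L, tol = 1e-6) {
  z <- plate$values
  z[!plate$mask] <- NA_real_
  nr <- nrow(z)
  nc <- ncol(z)
  grand <- 0
  row_eff <- numeric(nr)
  col_eff <- numeric(nc)
  converged <- FALSE
  iter <- 0L
  med <- function(x) stats::median(x, na.rm = TRUE)
  for (iter in seq_len(max_iter)) {
    rdelta <- apply(z, 1L, med)
    rdelta[is.na(rdelta)] <- 0
    z <- z - rdelta
    row_eff <- row_eff + rdelta
    d <- med(col_eff)
    if (is.na(d)) d <- 0
    col_eff <- col_eff - d
    grand <- grand + d
    cdelta <- apply(z, 2L, med)
    cdelta[is.na(cdelta)] <- 0
    z <- sweep(z, 2L, cdelta)
    col_eff <- col_eff + cdelta
    d <- med(row_eff)
    if (is.na(d)) d <- 0
    row_eff <- row_eff - d
    grand <- grand + d
    # convergence tracks the residual sweeps only, so the stopping point is
    # unaffected by constant offsets the effects absorb in the first pass
    if (max(abs(rdelta), abs(cdelta)) <= tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      grand = grand, row_effects = row_eff, col_effects = col_eff,
      residuals = z, iterations = iter, converged = converged
    ),
    class = "median_polish"
  )
}

#' @export
print.median_polish <- function(x, ...) {
  cat(sprintf(
    "<median_polish> grand = %.4g, %d iteration(s), %sconverged\n",
    x$grand, x$iterations, if (x$converged) "" else "NOT "
  ))
  invisible(x)
}

# Unscaled median absolute deviation: median(|x - median(x)|).
.mad0 <- function(x) stats::median(abs(x - stats::median(x)))

#' B-score normalization of a plate
#'
#' Residuals of the two-way median polish divided by the plate's (unscaled)
#' median absolute deviation of residuals. No cross-plate smoothing is
#' applied. An exactly additive plate has zero residuals everywhere, hence a
#' zero MAD, and is rejected as degenerate.
#'
#' @inheritParams median_polish
#' @return The B-scored `plate_grid`.
#' @export
bscore_plate <- function(plate, max_iter = 100L, tol = 1e-6) {
  mp <- median_polish(plate, max_iter = max_iter, tol = tol)
  res <- mp$residuals[plate$mask]
  madp <- .mad0(res)
  if (madp == 0) {
    stop("B-score undefined: median absolute deviation of residuals is 0")
  }
  plate$values[plate$mask] <- res / madp
  plate
}

#' Well correction across an assay
#'
#' For each well location independently: fit an ordinary least-squares
#' polynomial trend of the measurement against plate order over the plates
#' where the location is valid, subtract the fit, then Z-score the detrended
#' series across plates. Corrected series have mean 0, SD 1 and (for
#' `degree >= 1`) zero OLS slope. Locations masked on every plate (e.g.
#' control columns) are skipped.
#'
#' @param assay An `hts_assay` with at least 3 plates.
#' @param degree Polynomial degree of the trend fit (0, 1 or 2; default 1).
#' @return The corrected `hts_assay`.
#' @export
well_correction <- function(assay, degree = 1L) {
  if (!degree %in% 0:2) stop("degree must be 0, 1 or 2")
  P <- n_plates(assay)
  if (P < 3L) stop("well correction needs at least 3 plates")
  nr <- assay$n_row
  nc <- assay$n_col
  vals <- vapply(assay$plates, function(p) p$values, matrix(0, nr, nc))
  msk <- vapply(assay$plates, function(p) p$mask, matrix(TRUE, nr, nc))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ok <- which(msk[i, j, ])
      if (!length(ok)) next
      if (length(ok) < 3L) {
        stop(sprintf("well (%d, %d) is valid in fewer than 3 plates", i, j))
      }
      y <- vals[i, j, ok]
      X <- outer(as.numeric(ok), 0:degree, `^`)
      fit <- stats::lm.fit(X, y)
      r <- fit$residuals
      s <- stats::sd(r)
      # residuals of a perfectly fit trend are numerically, not exactly, zero
      if (s <= sqrt(.Machine$double.eps) * max(1, max(abs(y)))) {
        stop(sprintf("well (%d, %d) is constant after detrending", i, j))
      }
      vals[i, j, ok] <- (r - mean(r)) / s
    }
  }
  for (p in seq_len(P)) assay$plates[[p]]$values <- vals[, , p]
  assay
}
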