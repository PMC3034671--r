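# Hit selection, hit-distribution surfaces, and replicated-assay pipelines.

# Per-plate or whole-assay (mean, sd) thresholds mu - c*sigma.
.hit_thresholds <- function(assay, c, scope) {
  if (scope == "assay_wise") {
    v <- unlist(lapply(assay$plates, valid_values))
    if (length(v) < 2L || stats::sd(v) == 0) {
      stop("hit threshold undefined: assay is constant (sigma = 0)")
    }
    rep(mean(v) - c * stats::sd(v), n_plates(assay))
  } else {
    vapply(assay$plates, function(p) {
      st <- plate_stats(p)
      if (st["sd"] == 0) stop("hit threshold undefined: constant plate (sigma = 0)")
      st["mean"] - c * st["sd"]
    }, numeric(1))
  }
}

#' Select hits at a mean-minus-c-sigma threshold
#'
#' Inhibition convention: a valid well is a hit iff its value is less than or
#' equal to `mu - c * sigma`, with the mean and sample SD taken over the
#' plate's valid wells (`plate_wise`) or the whole assay (`assay_wise`).
#'
#' @param assay An `hts_assay`.
#' @param c Threshold multiplier (3 is the common choice).
#' @param scope `"plate_wise"` or `"assay_wise"`.
#' @return List of logical hit matrices, one per plate (masked wells FALSE).
#' @export
select_hits <- function(assay, c = 3, scope = c("plate_wise", "assay_wise")) {
  scope <- match.arg(scope)
  thr <- .hit_thresholds(assay, c, scope)
  lapply(seq_along(assay$plates), function(p) {
    pl <- assay$plates[[p]]
    pl$mask & !is.na(pl$values) & pl$values <= thr[p]
  })
}

#' Hit-distribution surface of an assay
#'
#' Counts, for each well location, in how many plates that location is a hit
#' at the `mu - c sigma` threshold. An even surface indicates no positional
#' bias; elevated rows/columns betray systematic error that repeats across
#' plates. Locations valid in no plate (e.g. control columns) are masked.
#'
#' @inheritParams select_hits
#' @return Object of class `hit_surface`: `counts` (matrix), `mask`, `total`,
#'   `expected` (total / valid locations), `threshold_c`, `scope`,
#'   `n_plates`.
#' @export
hit_distribution_surface <- function(assay, c = 3,
                                     scope = c("plate_wise", "assay_wise")) {
  scope <- match.arg(scope)
  hits <- select_hits(assay, c, scope)
  counts <- Reduce(`+`, lapply(hits, function(h) h * 1L))
  loc_mask <- Reduce(`|`, lapply(assay$plates, function(p) p$mask))
  counts[!loc_mask] <- NA_integer_
  total <- sum(counts[loc_mask])
  structure(
    list(
      counts = counts, mask = loc_mask, total = total,
      expected = total / sum(loc_mask), threshold_c = c, scope = scope,
      n_plates = n_plates(assay)
    ),
    class = "hit_surface"
  )
}

#' @export
print.hit_surface <- function(x, ...) {
  cat(sprintf(
    "<hit_surface> %d x %d, %d plates, %d hits (E = %.3f), threshold mu - %g sigma (%s)\n",
    nrow(x$counts), ncol(x$counts), x$n_plates, x$total, x$expected,
    x$threshold_c, x$scope
  ))
  invisible(x)
}

# Elementwise mean of two plates; valid where both replicates are valid.
.average_pair <- function(p1, p2) {
  mask <- p1$mask & p2$mask
  vals <- (p1$values + p2$values) / 2
  vals[!mask] <- NA_real_
  plate_grid(vals, mask)
}

#' Combine replicate plates into one averaged assay
#'
#' For each replicate pair, optionally corrects systematic error before
#' averaging. Policy `bscore_if_flagged` (the error-detection-gated pipeline):
#' each plate is scanned with the row/column t-test and B-scored if at least
#' one line is flagged; when exactly one plate of a pair was B-scored, its
#' residual scale is incomparable with the raw replicate, so both plates are
#' Z-scored before averaging; when neither or both were corrected they are
#' averaged as-is. Policy `zscore` Z-scores both replicates; `none` averages
#' raw values.
#'
#' @param assay An `hts_assay` with a perfect replicate pairing
#'   (`replicate_of`).
#' @param alpha Significance level for the t-test scan (policy
#'   `bscore_if_flagged`).
#' @param corrector `"bscore_if_flagged"`, `"zscore"` or `"none"`.
#' @return An `hts_assay` with one averaged plate per pair, in order of the
#'   pair's first plate.
#' @export
combine_replicates <- function(assay, alpha = 0.01,
                               corrector = c("bscore_if_flagged", "zscore", "none")) {
  corrector <- match.arg(corrector)
  if (is.null(assay$replicate_of) || anyNA(assay$replicate_of)) {
    stop("combine_replicates needs a complete replicate pairing")
  }
  first <- which(seq_along(assay$plates) < assay$replicate_of)
  averaged <- lapply(first, function(i) {
    j <- assay$replicate_of[i]
    p1 <- assay$plates[[i]]
    p2 <- assay$plates[[j]]
    if (corrector == "zscore") {
      p1 <- zscore_plate(p1)
      p2 <- zscore_plate(p2)
    } else if (corrector == "bscore_if_flagged") {
      f1 <- any(.t_scan_matrix(p1$values, p1$mask, alpha)$flagged, na.rm = TRUE)
      f2 <- any(.t_scan_matrix(p2$values, p2$mask, alpha)$flagged, na.rm = TRUE)
      if (f1) p1 <- bscore_plate(p1)
      if (f2) p2 <- bscore_plate(p2)
      if (xor(f1, f2)) {
        p1 <- zscore_plate(p1)
        p2 <- zscore_plate(p2)
      }
    }
    .average_pair(p1, p2)
  })
  hts_assay(averaged)
}

#' Consensus and average hit lists of a replicated assay
#'
#' Consensus hits are compounds that pass the threshold in both replicate
#' measurements; average hits are compounds whose replicate-averaged value
#' passes the (pair-averaged) threshold. With the same monotone threshold
#' rule on both lists, every consensus hit is an average hit.
#'
#' @param assay An `hts_assay` with a complete replicate pairing.
#' @param c Threshold multiplier in `mu - c sigma`.
#' @param scope Statistic scope for the thresholds, as in [select_hits()].
#' @return List of two data.frames, `consensus` and `average`, each with
#'   columns `pair` (index of the pair's first plate), `row`, `col`.
#' @export
consensus_and_average_hits <- function(assay, c = 3,
                                       scope = c("plate_wise", "assay_wise")) {
  scope <- match.arg(scope)
  if (is.null(assay$replicate_of) || anyNA(assay$replicate_of)) {
    stop("consensus/average hits need a complete replicate pairing")
  }
  thr <- .hit_thresholds(assay, c, scope)
  first <- which(seq_along(assay$plates) < assay$replicate_of)
  cons <- list()
  avg <- list()
  for (i in first) {
    j <- assay$replicate_of[i]
    p1 <- assay$plates[[i]]
    p2 <- assay$plates[[j]]
    both <- p1$mask & p2$mask
    hit1 <- both & p1$values <= thr[i]
    hit2 <- both & p2$values <= thr[j]
    hit_avg <- both & (p1$values + p2$values) / 2 <= (thr[i] + thr[j]) / 2
    ci <- which(hit1 & hit2, arr.ind = TRUE)
    ai <- which(hit_avg, arr.ind = TRUE)
    if (nrow(ci)) cons[[length(cons) + 1L]] <-
      data.frame(pair = i, row = ci[, 1], col = ci[, 2])
    if (nrow(ai)) avg[[length(avg) + 1L]] <-
      data.frame(pair = i, row = ai[, 1], col = ai[, 2])
  }
  empty <- data.frame(pair = integer(), row = integer(), col = integer())
  list(
    consensus = if (length(cons)) do.call(rbind, cons) else empty,
    average = if (length(avg)) do.call(rbind, avg) else empty
  )
}
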