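# Scoring detector output against simulation ground truth, and the two
# campaign drivers (plate-scan detection; hit-surface detection).

#' Confusion counts of a detection scan against ground truth
#'
#' Each scanned line (row or column) contributes to exactly one cell: TP if
#' error was added and detected, FP if detected but not added, TN if neither,
#' FN if added but missed. For a plate scan, lines are counted over all
#' plates (`P * (n_row + n_col)` total); for a surface scan, over the single
#' surface's lines, against the assay-level truth of [surface_truth()].
#'
#' @param detections Per-line decision data.frame from [scan_assay_ttest()],
#'   [scan_assay_ks()] or [scan_surface()].
#' @param truth A `ground_truth` (plate scope) or a [surface_truth()] list
#'   (surface scope).
#' @return Object of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `total`.
#' @export
confusion_counts <- function(detections, truth) {
  if (inherits(truth, "ground_truth")) {
    P <- nrow(truth$row_flags)
    nr <- ncol(truth$row_flags)
    nc <- ncol(truth$col_flags)
    expect_n <- P * (nr + nc)
    if (nrow(detections) != expect_n) {
      stop(sprintf(
        "detections cover %d lines but ground truth labels %d",
        nrow(detections), expect_n
      ))
    }
    is_row <- detections$line == "row"
    truth_flag <- logical(nrow(detections))
    truth_flag[is_row] <- truth$row_flags[cbind(
      detections$plate[is_row], detections$index[is_row]
    )]
    truth_flag[!is_row] <- truth$col_flags[cbind(
      detections$plate[!is_row], detections$index[!is_row]
    )]
  } else {
    expect_n <- length(truth$rows) + length(truth$cols)
    if (nrow(detections) != expect_n) {
      stop(sprintf(
        "detections cover %d lines but surface truth labels %d",
        nrow(detections), expect_n
      ))
    }
    is_row <- detections$line == "row"
    truth_flag <- logical(nrow(detections))
    truth_flag[is_row] <- truth$rows[detections$index[is_row]]
    truth_flag[!is_row] <- truth$cols[detections$index[!is_row]]
  }
  det_flag <- detections$flagged
  if (anyNA(det_flag)) {
    stop("detections contain undefined (NA) decisions; cannot score")
  }
  structure(
    list(
      tp = sum(det_flag & truth_flag), fp = sum(det_flag & !truth_flag),
      tn = sum(!det_flag & !truth_flag), fn = sum(!det_flag & truth_flag),
      total = length(det_flag)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> TP %d, FP %d, TN %d, FN %d (total %d)\n",
    x$tp, x$fp, x$tn, x$fn, x$total
  ))
  invisible(x)
}

#' Cohen's kappa of a confusion table
#'
#' Chance-corrected agreement between the detector and ground truth:
#' `kappa = (Pr(a) - Pr(e)) / (1 - Pr(e))` with observed agreement
#' `Pr(a) = (TP + TN) / n` and chance agreement
#' `Pr(e) = ((TP+FN)(TP+FP) + (TN+FN)(TN+FP)) / n^2`. Undefined (NA) when
#' the truth contains no positives (`TP + FN = 0`, e.g. error-free data or
#' well-only error scored on lines) or when `Pr(e) = 1`.
#'
#' @param counts A `confusion_counts`.
#' @return Kappa, or `NA` where undefined.
#' @export
cohens_kappa <- function(counts) {
  n <- counts$total
  if (n <= 0) stop("empty confusion table")
  if (counts$tp + counts$fn == 0) return(NA_real_)
  pr_a <- (counts$tp + counts$tn) / n
  pr_e <- ((counts$tp + counts$fn) * (counts$tp + counts$fp) +
             (counts$tn + counts$fn) * (counts$tn + counts$fp)) / n^2
  if (pr_e == 1) return(NA_real_)
  (pr_a - pr_e) / (1 - pr_e)
}

#' Sensitivity, specificity and success rate of a confusion table
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `success_rate = (TP + TN) / n` (identical to the observed agreement
#' Pr(a)). Ratios with zero denominators are `NA`.
#'
#' @param counts A `confusion_counts`.
#' @return Named list `sensitivity`, `specificity`, `success_rate`.
#' @export
rates <- function(counts) {
  n <- counts$total
  if (n <= 0) stop("empty confusion table")
  sens <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else NA_real_
  spec <- if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp) else NA_real_
  list(
    sensitivity = sens, specificity = spec,
    success_rate = (counts$tp + counts$tn) / n
  )
}

# Mean over defined values; NA when none are defined.
.na_mean <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)

.score_scan <- function(detections, truth) {
  cc <- confusion_counts(detections, truth)
  r <- rates(cc)
  c(
    kappa = cohens_kappa(cc), sensitivity = r$sensitivity,
    specificity = r$specificity, success_rate = r$success_rate
  )
}

#' Plate-scan detection campaign
#'
#' Generates replicate synthetic assays for each error type and error size,
#' scans every plate's rows and columns with the requested tests, scores the
#' decisions against ground truth, and averages Cohen's kappa, sensitivity,
#' specificity and success rate over datasets (skipping undefined values).
#' For each dataset the same error-free background, hit locations, error
#' pattern and noise are reused across error sizes, with only the offset
#' amplitude rescaled, so the error-size sweep perturbs one error structure
#' at growing amplitude. The full-size campaign of the original study used
#' 1250-plate assays and 500 datasets per condition; desk-scale defaults are
#' provided, and every output is reproducible from (config, seed).
#'
#' @param format Plate format.
#' @param n_plates Plates per assay.
#' @param h Hit percentage injected before error.
#' @param err_sds Systematic-error SDs (multiples of the base SD).
#' @param types Error types to simulate (subset of A..E).
#' @param tests Detection tests: `"t"` and/or `"ks"`.
#' @param alpha Per-test significance level.
#' @param n_datasets Datasets per condition.
#' @param noise_sd Random-error SD (multiples of the base SD).
#' @param seed Campaign seed; per-dataset seeds derive from it.
#' @return data.frame with one row per (error type, err_sd, test): mean
#'   metrics plus `n_datasets` and `n_defined_kappa`.
#' @export
run_simulation1 <- function(format = "96", n_plates = 50, h = 1,
                            err_sds = c(0, 0.6, 1.2, 1.8, 2.4, 3.0),
                            types = c("A", "B", "C", "D", "E"),
                            tests = c("t", "ks"), alpha = 0.01,
                            n_datasets = 20, noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  ds_seeds <- matrix(
    sample.int(2147480000L, length(types) * n_datasets),
    nrow = length(types)
  )
  out <- list()
  for (ti in seq_along(types)) {
    type <- types[ti]
    acc <- array(
      NA_real_,
      dim = c(length(err_sds), length(tests), 4L, n_datasets),
      dimnames = list(NULL, tests, c("kappa", "sensitivity", "specificity", "success_rate"), NULL)
    )
    for (k in seq_len(n_datasets)) {
      sk <- ds_seeds[ti, k]
      base <- generate_base_assay(n_plates, format, seed = sk)
      withhits <- inject_hits(base, h, seed = sk + 1L)$assay
      for (ei in seq_along(err_sds)) {
        spec <- make_error_spec(
          type, format, err_sd = err_sds[ei], noise_sd = noise_sd,
          seed = sk + 2L, n_plates = n_plates
        )
        pe <- apply_error(withhits, spec)
        for (te in tests) {
          scan <- if (te == "t") {
            scan_assay_ttest(pe$assay, alpha)
          } else {
            scan_assay_ks(pe$assay, alpha)
          }
          acc[ei, te, , k] <- .score_scan(scan, pe$truth)
        }
      }
    }
    for (ei in seq_along(err_sds)) {
      for (te in tests) {
        out[[length(out) + 1L]] <- data.frame(
          error_type = type, err_sd = err_sds[ei], test = te, alpha = alpha,
          kappa = .na_mean(acc[ei, te, "kappa", ]),
          sensitivity = .na_mean(acc[ei, te, "sensitivity", ]),
          specificity = .na_mean(acc[ei, te, "specificity", ]),
          success_rate = .na_mean(acc[ei, te, "success_rate", ]),
          n_datasets = n_datasets,
          n_defined_kappa = sum(!is.na(acc[ei, te, "kappa", ]))
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Hit-surface detection campaign
#'
#' Generates replicate synthetic assays over a sweep of hit percentages at a
#' fixed error size, builds each assay's hit-distribution surface at the
#' `mu - c sigma` threshold, applies the requested tests to the surface's
#' rows and columns, and scores against the assay-level truth. Because
#' surfaces aggregate across plates, only error repeating along all plates
#' (types A and B) is traceable; for types C, D and E sensitivity and kappa
#' are undefined (NA) while specificity and success rate are still scored.
#'
#' @param format Plate format.
#' @param n_plates Plates per assay.
#' @param hs Hit percentages to sweep.
#' @param err_sd Systematic-error SD (multiples of the base SD).
#' @param types Error types (subset of A..E).
#' @param tests Detection tests: any of `"t"`, `"chi2"`, `"ks"`.
#' @param alpha Per-test significance level.
#' @param threshold_c Hit-selection multiplier in `mu - c sigma`.
#' @param n_datasets Datasets per condition.
#' @param noise_sd Random-error SD (multiples of the base SD).
#' @param seed Campaign seed.
#' @return data.frame with one row per (error type, hit percentage, test).
#' @export
run_simulation2 <- function(format = "96", n_plates = 50,
                            hs = c(0.5, 1, 2, 3, 4, 5), err_sd = 1.2,
                            types = c("A", "B", "C", "D", "E"),
                            tests = c("t", "chi2", "ks"), alpha = 0.01,
                            threshold_c = 3, n_datasets = 20,
                            noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  ds_seeds <- array(
    sample.int(2147480000L, length(types) * length(hs) * n_datasets),
    dim = c(length(types), length(hs), n_datasets)
  )
  out <- list()
  for (ti in seq_along(types)) {
    type <- types[ti]
    for (hi in seq_along(hs)) {
      acc <- array(
        NA_real_, dim = c(length(tests), 4L, n_datasets),
        dimnames = list(tests, c("kappa", "sensitivity", "specificity", "success_rate"), NULL)
      )
      for (k in seq_len(n_datasets)) {
        sk <- ds_seeds[ti, hi, k]
        base <- generate_base_assay(n_plates, format, seed = sk)
        withhits <- inject_hits(base, hs[hi], seed = sk + 1L)$assay
        spec <- make_error_spec(
          type, format, err_sd = err_sd, noise_sd = noise_sd,
          seed = sk + 2L, n_plates = n_plates
        )
        pe <- apply_error(withhits, spec)
        surf <- hit_distribution_surface(pe$assay, threshold_c, "plate_wise")
        struth <- surface_truth(pe$truth)
        for (te in tests) {
          if (te == "chi2" && surf$total == 0) next
          scan <- scan_surface(surf, te, alpha)
          acc[te, , k] <- .score_scan(scan, struth)
        }
      }
      for (te in tests) {
        out[[length(out) + 1L]] <- data.frame(
          error_type = type, hit_pct = hs[hi], test = te, alpha = alpha,
          kappa = .na_mean(acc[te, "kappa", ]),
          sensitivity = .na_mean(acc[te, "sensitivity", ]),
          specificity = .na_mean(acc[te, "specificity", ]),
          success_rate = .na_mean(acc[te, "success_rate", ]),
          n_datasets = n_datasets,
          n_defined_kappa = sum(!is.na(acc[te, "kappa", ]))
        )
      }
    }
  }
  do.call(rbind, out)
}
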