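# Synthetic assay generation: error-free backgrounds, hit injection, and the
# five positional-error models (A: row+column, B: column only, C: well,
# D: per-plate row+column, E: random noise only).

# Affected-line caps per standard format; type C is capped at 10% of wells.
.line_caps <- function(dims) {
  wells <- dims[1] * dims[2]
  caps <- switch(as.character(wells),
    "96" = c(2L, 2L), "384" = c(4L, 4L), "1536" = c(8L, 8L),
    c(max(1L, dims[1] %/% 4L), max(1L, dims[2] %/% 6L))
  )
  list(rows = caps[1], cols = caps[2], wells = max(1L, as.integer(wells * 0.10)))
}

#' Generate an error-free assay of standard-normal measurements
#'
#' Every valid well is an independent N(0, 1) draw, the background model used
#' by the simulation campaigns. All wells start valid; use [mask_wells()] to
#' emulate control columns.
#'
#' @param n_plates Number of plates (>= 1).
#' @param format Plate format (see [plate_format_dims()]).
#' @param seed Optional integer seed; the output is fully determined by it.
#' @return An `hts_assay`.
#' @export
generate_base_assay <- function(n_plates, format = "96", seed = NULL) {
  if (n_plates < 1) stop("n_plates must be >= 1")
  dims <- plate_format_dims(format)
  if (!is.null(seed)) set.seed(seed)
  plates <- lapply(seq_len(n_plates), function(p) {
    plate_grid(matrix(stats::rnorm(dims[1] * dims[2]), dims[1], dims[2]),
               plate_index = p)
  })
  hts_assay(plates)
}

#' Inject hits into an assay
#'
#' Each valid well independently becomes a hit with probability `h`/100; a hit
#' well's measurement is replaced by a draw from N(mu - 5 SD, SD), where mu
#' and SD are the mean and sample standard deviation of the whole error-free
#' assay before injection (inhibition convention: hits are low values).
#'
#' @param assay An `hts_assay` (error-free background).
#' @param h Hit percentage in \[0, 100\].
#' @param seed Optional integer seed.
#' @return List with elements `assay` (hits injected) and `hits`, a
#'   data.frame of the injected (plate, row, col) locations.
#' @export
inject_hits <- function(assay, h, seed = NULL) {
  if (h < 0 || h > 100) stop("hit percentage h must lie in [0, 100]")
  if (!is.null(seed)) set.seed(seed)
  all_vals <- unlist(lapply(assay$plates, valid_values))
  mu <- mean(all_vals)
  sdev <- stats::sd(all_vals)
  pr <- h / 100
  locs <- vector("list", n_plates(assay))
  for (p in seq_along(assay$plates)) {
    pl <- assay$plates[[p]]
    u <- matrix(stats::runif(length(pl$values)), nrow(pl$values))
    hit <- pl$mask & u < pr
    n_hit <- sum(hit)
    if (n_hit > 0) {
      pl$values[hit] <- stats::rnorm(n_hit, mean = mu - 5 * sdev, sd = sdev)
      idx <- which(hit, arr.ind = TRUE)
      locs[[p]] <- data.frame(plate = p, row = idx[, 1], col = idx[, 2])
    }
    assay$plates[[p]] <- pl
  }
  hits <- if (length(lh <- Filter(Negate(is.null), locs))) {
    do.call(rbind, lh)
  } else {
    data.frame(plate = integer(), row = integer(), col = integer())
  }
  rownames(hits) <- NULL
  list(assay = assay, hits = hits)
}

#' Draw a systematic-error recipe
#'
#' Chooses which rows/columns/wells carry systematic error and draws their
#' offsets. Affected counts are uniform on 1..cap (cap: 2 rows and 2 columns
#' for 96-well plates, 4/4 for 384, 8/8 for 1536; 10% of wells for type C),
#' locations are sampled without replacement, and offsets are N(0,
#' (err_sd * base_sd)^2). Offsets are stored as unit draws scaled by
#' `err_sd`, so the same seed at two error sizes yields the same error
#' structure, only rescaled (the error-size sweeps of the simulation
#' campaigns perturb one error pattern at increasing amplitude). For type D
#' the counts, locations and offsets are redrawn independently per plate;
#' type E has no systematic component.
#'
#' @param error_type One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param format Plate format.
#' @param err_sd Standard deviation of systematic offsets, in multiples of
#'   the base-assay SD.
#' @param noise_sd Standard deviation of the additive random-error term, in
#'   multiples of the base-assay SD (default 0.2).
#' @param seed Optional integer seed.
#' @param n_plates Number of plates; required for type D.
#' @param base_sd Base-assay standard deviation the multiples refer to
#'   (1 for the standard-normal generator).
#' @return An object of class `error_spec`.
#' @export
make_error_spec <- function(error_type, format = "96", err_sd = 1.2,
                            noise_sd = 0.2, seed = NULL, n_plates = NULL,
                            base_sd = 1) {
  if (!error_type %in% c("A", "B", "C", "D", "E")) {
    stop("unknown error_type '", error_type, "' (use A, B, C, D or E)")
  }
  if (err_sd < 0) stop("err_sd must be >= 0")
  dims <- plate_format_dims(format)
  caps <- .line_caps(dims)
  if (!is.null(seed)) set.seed(seed)
  scale <- err_sd * base_sd
  draw_lines <- function(n_avail, cap) {
    k <- sample.int(cap, 1L)
    list(idx = sort(sample.int(n_avail, k)), z = stats::rnorm(k))
  }
  spec <- list(
    error_type = error_type, dims = dims, err_sd = err_sd,
    noise_sd = noise_sd, base_sd = base_sd, seed = seed,
    rows = integer(), row_offsets = numeric(),
    cols = integer(), col_offsets = numeric(),
    wells = matrix(integer(), 0, 2), well_offsets = numeric(),
    per_plate = NULL
  )
  if (error_type == "A" || error_type == "B") {
    if (error_type == "A") {
      r <- draw_lines(dims[1], caps$rows)
      spec$rows <- r$idx
      spec$row_offsets <- scale * r$z
    }
    cl <- draw_lines(dims[2], caps$cols)
    spec$cols <- cl$idx
    spec$col_offsets <- scale * cl$z
  } else if (error_type == "C") {
    k <- sample.int(caps$wells, 1L)
    cells <- sample.int(dims[1] * dims[2], k)
    spec$wells <- cbind(
      row = ((cells - 1L) %% dims[1]) + 1L,
      col = ((cells - 1L) %/% dims[1]) + 1L
    )
    spec$well_offsets <- scale * stats::rnorm(k)
  } else if (error_type == "D") {
    if (is.null(n_plates)) stop("type D needs n_plates (per-plate redraw)")
    spec$per_plate <- lapply(seq_len(n_plates), function(p) {
      r <- draw_lines(dims[1], caps$rows)
      cl <- draw_lines(dims[2], caps$cols)
      list(
        rows = r$idx, row_offsets = scale * r$z,
        cols = cl$idx, col_offsets = scale * cl$z
      )
    })
  }
  structure(spec, class = "error_spec")
}

#' @export
print.error_spec <- function(x, ...) {
  cat(sprintf(
    "<error_spec> type %s, %d x %d, err_sd = %g SD, noise_sd = %g SD\n",
    x$error_type, x$dims[1], x$dims[2], x$err_sd, x$noise_sd
  ))
  invisible(x)
}

#' Apply a systematic-error recipe to an assay
#'
#' Adds the recipe's systematic offsets to the affected lines/wells and an
#' independent random-error draw N(0, (noise_sd * base_sd)^2) to every valid
#' well of every plate (all five types, including E). Masked wells are left
#' untouched. The random-error stream is seeded from the recipe seed, so
#' (assay, spec) fully determines the output.
#'
#' @param assay An `hts_assay` whose format matches the recipe.
#' @param spec An `error_spec`.
#' @return List with elements `assay` (perturbed copy) and `truth`, a
#'   `ground_truth` object flagging exactly the rows/columns/wells that
#'   received a nonzero systematic offset.
#' @export
apply_error <- function(assay, spec) {
  if (!inherits(spec, "error_spec")) stop("spec must be an error_spec")
  if (assay$n_row != spec$dims[1] || assay$n_col != spec$dims[2]) {
    stop("assay format does not match error spec format")
  }
  P <- n_plates(assay)
  if (spec$error_type == "D" && length(spec$per_plate) != P) {
    stop("type D spec was drawn for a different number of plates")
  }
  nr <- assay$n_row
  nc <- assay$n_col
  row_flags <- matrix(FALSE, P, nr)
  col_flags <- matrix(FALSE, P, nc)
  well_flags <- matrix(FALSE, nr, nc)
  # offset field shared by types A, B, C (constant across plates)
  shared <- matrix(0, nr, nc)
  if (length(spec$rows)) {
    shared[spec$rows, ] <- shared[spec$rows, ] + spec$row_offsets
  }
  if (length(spec$cols)) {
    shared <- shared + matrix(
      replace(numeric(nc), spec$cols, spec$col_offsets),
      nr, nc, byrow = TRUE
    )
  }
  if (nrow(spec$wells)) {
    shared[spec$wells] <- shared[spec$wells] + spec$well_offsets
  }
  nz_rows <- spec$rows[spec$row_offsets != 0]
  nz_cols <- spec$cols[spec$col_offsets != 0]
  if (nrow(spec$wells)) well_flags[spec$wells[spec$well_offsets != 0, , drop = FALSE]] <- TRUE
  noise_scale <- spec$noise_sd * spec$base_sd
  if (!is.null(spec$seed)) set.seed(spec$seed + 500009L)
  for (p in seq_len(P)) {
    pl <- assay$plates[[p]]
    off <- shared
    if (spec$error_type == "D") {
      pp <- spec$per_plate[[p]]
      off <- matrix(0, nr, nc)
      off[pp$rows, ] <- off[pp$rows, ] + pp$row_offsets
      off <- off + matrix(
        replace(numeric(nc), pp$cols, pp$col_offsets),
        nr, nc, byrow = TRUE
      )
      row_flags[p, pp$rows[pp$row_offsets != 0]] <- TRUE
      col_flags[p, pp$cols[pp$col_offsets != 0]] <- TRUE
    } else {
      row_flags[p, nz_rows] <- TRUE
      col_flags[p, nz_cols] <- TRUE
    }
    if (noise_scale > 0) {
      rnd <- matrix(stats::rnorm(nr * nc, sd = noise_scale), nr, nc)
      off <- off + rnd
    }
    pl$values[pl$mask] <- pl$values[pl$mask] + off[pl$mask]
    assay$plates[[p]] <- pl
  }
  truth <- structure(
    list(
      error_type = spec$error_type, row_flags = row_flags,
      col_flags = col_flags, well_flags = well_flags
    ),
    class = "ground_truth"
  )
  list(assay = assay, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> type %s: %d flagged row-lines, %d flagged column-lines, %d flagged wells\n",
    x$error_type, sum(x$row_flags), sum(x$col_flags), sum(x$well_flags)
  ))
  invisible(x)
}

#' Assay-level row/column truth for hit-distribution surfaces
#'
#' A hit surface aggregates across plates, so only error that repeats along
#' all plates (types A and B) leaves a row/column trace: for those types the
#' per-assay flags are returned; for types C, D and E all lines are negative
#' (their surfaces cannot be used to retrace row or column error, and
#' sensitivity/kappa are then undefined).
#'
#' @param truth A `ground_truth`.
#' @return List with logical vectors `rows` and `cols`.
#' @export
surface_truth <- function(truth) {
  if (truth$error_type %in% c("A", "B")) {
    list(rows = truth$row_flags[1, ], cols = truth$col_flags[1, ])
  } else {
    list(
      rows = rep(FALSE, ncol(truth$row_flags)),
      cols = rep(FALSE, ncol(truth$col_flags))
    )
  }
}
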