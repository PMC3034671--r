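#' @keywords internal
"_PACKAGE"

# Standard microtiter formats: wells -> c(rows, cols)
.plate_formats <- list("96" = c(8L, 12L), "384" = c(16L, 24L), "1536" = c(32L, 48L))

#' Resolve a plate format to row/column dimensions
#'
#' @param format Either one of `"96"`, `"384"`, `"1536"` (character or
#'   numeric), or an integer vector `c(n_rows, n_cols)` for a custom format.
#' @return Integer vector `c(n_rows, n_cols)`.
#' @export
plate_format_dims <- function(format) {
  if (length(format) == 1L) {
    key <- as.character(format)
    dims <- .plate_formats[[key]]
    if (is.null(dims)) {
      stop("unknown plate format '", key, "'; use 96, 384, 1536 or c(n_rows, n_cols)")
    }
    return(dims)
  }
  if (length(format) == 2L && all(format >= 2)) {
    return(as.integer(format))
  }
  stop("invalid plate format; need at least 2 rows and 2 columns")
}

#' Construct a single plate of measurements
#'
#' A plate is a numeric matrix of activity measurements plus a logical
#' validity mask. Masked wells (controls, missing measurements) are excluded
#' from every statistic computed by the package; masking rather than deleting
#' preserves plate geometry, which the line tests and DFT unrolling need.
#'
#' @param values Numeric matrix, rows x columns of the plate.
#' @param mask Logical matrix of the same dimension; `TRUE` marks a well that
#'   participates in statistics. Defaults to `!is.na(values)`.
#' @param plate_index 1-based position of the plate within its assay.
#' @return An object of class `plate_grid` with elements `values`, `mask`,
#'   `plate_index`.
#' @export
plate_grid <- function(values, mask = NULL, plate_index = 1L) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("plate values must be a numeric matrix")
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("a plate needs at least 2 rows and 2 columns")
  }
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.matrix(mask) || !is.logical(mask) || !identical(dim(mask), dim(values))) {
    stop("mask must be a logical matrix with the same dimensions as values")
  }
  mask[is.na(mask)] <- FALSE
  structure(
    list(values = values, mask = mask, plate_index = as.integer(plate_index)),
    class = "plate_grid"
  )
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(sprintf(
    "<plate_grid> %d x %d, plate %d, %d valid wells\n",
    nrow(x$values), ncol(x$values), x$plate_index, sum(x$mask)
  ))
  invisible(x)
}

#' Valid (unmasked) measurements of a plate
#' @param plate A `plate_grid`.
#' @return Numeric vector of the valid wells.
#' @export
valid_values <- function(plate) plate$values[plate$mask]

#' Mean and standard deviation over the valid wells of a plate
#'
#' The sample standard deviation (n - 1 denominator) is used, as everywhere
#' in the package.
#'
#' @param plate A `plate_grid`.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
plate_stats <- function(plate) {
  v <- valid_values(plate)
  if (length(v) < 2L) {
    stop("plate statistics undefined: fewer than 2 valid wells")
  }
  c(mean = mean(v), sd = stats::sd(v))
}

#' Construct an assay: an ordered set of same-format plates
#'
#' @param plates List of `plate_grid` objects sharing one format. Plate
#'   indices are renumbered 1..P in list order.
#' @param replicate_of Optional integer vector of length P pairing replicate
#'   plates: `replicate_of[i] = j` means plates i and j measured the same
#'   compounds. Must be a perfect matching on the paired plates
#'   (`replicate_of[j] = i`, no plate in two pairs); `NA` for unpaired plates.
#' @return An object of class `hts_assay` with elements `plates`, `n_row`,
#'   `n_col`, `replicate_of`.
#' @export
hts_assay <- function(plates, replicate_of = NULL) {
  if (length(plates) < 1L) stop("an assay needs at least one plate")
  if (!all(vapply(plates, inherits, logical(1), "plate_grid"))) {
    stop("plates must be a list of plate_grid objects")
  }
  dims <- vapply(plates, function(p) dim(p$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all plates of an assay must share the same dimensions")
  }
  for (i in seq_along(plates)) plates[[i]]$plate_index <- i
  if (!is.null(replicate_of)) {
    replicate_of <- as.integer(replicate_of)
    if (length(replicate_of) != length(plates)) {
      stop("replicate_of must have one entry per plate")
    }
    paired <- which(!is.na(replicate_of))
    for (i in paired) {
      j <- replicate_of[i]
      if (j < 1L || j > length(plates) || j == i || is.na(replicate_of[j]) ||
          replicate_of[j] != i) {
        stop("replicate_of must be a perfect matching of plate pairs")
      }
    }
  }
  structure(
    list(
      plates = plates, n_row = dims[1, 1], n_col = dims[2, 1],
      replicate_of = replicate_of
    ),
    class = "hts_assay"
  )
}

#' @export
print.hts_assay <- function(x, ...) {
  cat(sprintf(
    "<hts_assay> %d plates of %d x %d (%d wells), %d valid wells total\n",
    length(x$plates), x$n_row, x$n_col, x$n_row * x$n_col,
    sum(vapply(x$plates, function(p) sum(p$mask), integer(1)))
  ))
  invisible(x)
}

#' Number of plates in an assay
#' @param assay An `hts_assay`.
#' @return Integer plate count.
#' @export
n_plates <- function(assay) length(assay$plates)

#' Control-well summary statistics
#'
#' @param mu_pos Mean of positive-control wells.
#' @param mu_neg Mean of negative-control wells (optional; required by
#'   [normalized_percent_inhibition()]).
#' @return An object of class `control_stats`.
#' @export
control_stats <- function(mu_pos, mu_neg = NA_real_) {
  structure(list(mu_pos = mu_pos, mu_neg = mu_neg), class = "control_stats")
}

#' Mask control or otherwise excluded wells across an assay
#'
#' Marks whole rows, whole columns, or individual well locations invalid on
#' every plate, e.g. control columns 1 and 12 of a 96-well screen. Values are
#' retained; only the mask changes.
#'
#' @param assay An `hts_assay`.
#' @param rows,cols Integer vectors of row / column indices to mask.
#' @param wells Two-column matrix of (row, col) well locations to mask.
#' @return The assay with updated masks.
#' @export
mask_wells <- function(assay, rows = NULL, cols = NULL, wells = NULL) {
  for (p in seq_along(assay$plates)) {
    m <- assay$plates[[p]]$mask
    if (!is.null(rows)) m[rows, ] <- FALSE
    if (!is.null(cols)) m[, cols] <- FALSE
    if (!is.null(wells)) m[as.matrix(wells)] <- FALSE
    assay$plates[[p]]$mask <- m
  }
  assay
}

.long_csv_header <- c("assay", "plate", "row", "col", "value", "is_control")

#' Read an assay from disk
#'
#' Two layouts are supported. `long_csv` is a single comma-separated file with
#' header `assay,plate,row,col,value,is_control` ('.' decimal, UTF-8);
#' `is_control = 1` wells are masked. `matrix_dir` is a directory of per-plate
#' CSV matrices named `plate_<index>.csv` with `NA` marking missing wells.
#' Well coordinates are 1-based.
#'
#' @param path File (long_csv) or directory (matrix_dir).
#' @param layout `"long_csv"` or `"matrix_dir"`.
#' @param control_spec Optional list with any of `rows`, `cols`, `wells`
#'   (as in [mask_wells()]) masked on every plate after loading.
#' @param quiet Suppress the load report message.
#' @return An `hts_assay`. The load report (plate count, masked-well count)
#'   is attached as attribute `"load_report"`.
#' @export
read_assay <- function(path, layout = c("long_csv", "matrix_dir"),
                       control_spec = NULL, quiet = TRUE) {
  layout <- match.arg(layout)
  if (layout == "long_csv") {
    if (!file.exists(path) || dir.exists(path)) {
      stop("long_csv layout expects an existing file: ", path)
    }
    if (file.size(path) == 0) stop("format error: empty file ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("plate", "row", "col", "value") %in% names(tab))) {
      stop("format error: long CSV needs columns plate,row,col,value")
    }
    if (nrow(tab) == 0) stop("format error: no data rows in ", path)
    plate <- as.integer(tab$plate)
    row <- as.integer(tab$row)
    col <- as.integer(tab$col)
    value <- suppressWarnings(as.numeric(tab$value))
    bad <- which(!is.na(tab$value) & tab$value != "NA" & tab$value != "" &
                   is.na(value))
    if (length(bad)) {
      stop(sprintf(
        "format error: non-numeric value '%s' at plate %s row %s col %s",
        tab$value[bad[1]], tab$plate[bad[1]], tab$row[bad[1]], tab$col[bad[1]]
      ))
    }
    is_control <- if ("is_control" %in% names(tab)) {
      as.integer(tab$is_control) != 0L
    } else rep(FALSE, nrow(tab))
    key <- paste(plate, row, col)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop("format error: duplicate well (plate row col) ", d)
    }
    P <- max(plate)
    if (!setequal(unique(plate), seq_len(P))) {
      stop("format error: plate indices must be 1..P with no gaps")
    }
    nr <- max(row)
    nc <- max(col)
    plates <- vector("list", P)
    n_missing <- 0L
    for (p in seq_len(P)) {
      sel <- plate == p
      vals <- matrix(NA_real_, nr, nc)
      msk <- matrix(FALSE, nr, nc)
      vals[cbind(row[sel], col[sel])] <- value[sel]
      msk[cbind(row[sel], col[sel])] <- !is_control[sel] & !is.na(value[sel])
      n_missing <- n_missing + sum(is.na(vals))
      plates[[p]] <- plate_grid(vals, msk, p)
    }
    assay <- hts_assay(plates)
  } else {
    if (!dir.exists(path)) stop("matrix_dir layout expects a directory: ", path)
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) stop("format error: no plate CSV files in ", path)
    idx <- as.integer(sub(".*?([0-9]+)\\.csv$", "\\1", files))
    if (anyNA(idx)) stop("format error: plate file names must encode a plate index")
    files <- files[order(idx)]
    plates <- vector("list", length(files))
    dims <- NULL
    for (k in seq_along(files)) {
      m <- as.matrix(utils::read.csv(files[k], header = FALSE))
      storage.mode(m) <- "double"
      dimnames(m) <- NULL
      if (is.null(dims)) dims <- dim(m)
      if (!identical(dim(m), dims)) {
        stop("format error: plate dimension mismatch in ", files[k])
      }
      plates[[k]] <- plate_grid(m, !is.na(m), k)
    }
    assay <- hts_assay(plates)
  }
  if (!is.null(control_spec)) {
    assay <- mask_wells(
      assay,
      rows = control_spec$rows, cols = control_spec$cols,
      wells = control_spec$wells
    )
  }
  report <- list(
    n_plates = n_plates(assay),
    n_masked = sum(vapply(assay$plates, function(p) sum(!p$mask), integer(1)))
  )
  if (!quiet) {
    message(sprintf(
      "loaded %d plate(s) of %d x %d; %d masked well(s)",
      report$n_plates, assay$n_row, assay$n_col, report$n_masked
    ))
  }
  attr(assay, "load_report") <- report
  assay
}

#' Write an assay to disk
#'
#' Inverse of [read_assay()]: `read_assay(write_assay(a))` reproduces the
#' values bit-for-bit on valid wells and preserves the mask. In the long CSV
#' layout, masked wells are written with `is_control = 1`.
#'
#' @param assay An `hts_assay`.
#' @param path Target file (long_csv) or directory (matrix_dir).
#' @param layout `"long_csv"` or `"matrix_dir"`.
#' @param assay_id Identifier written to the `assay` column (long_csv only).
#' @return `path`, invisibly.
#' @export
write_assay <- function(assay, path, layout = c("long_csv", "matrix_dir"),
                        assay_id = "assay1") {
  layout <- match.arg(layout)
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1))
    out
  }
  if (layout == "long_csv") {
    nr <- assay$n_row
    nc <- assay$n_col
    rows <- lapply(assay$plates, function(p) {
      data.frame(
        assay = assay_id, plate = p$plate_index,
        row = rep(seq_len(nr), times = nc), col = rep(seq_len(nc), each = nr),
        value = fmt(as.vector(p$values)),
        is_control = as.integer(!as.vector(p$mask)),
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (p in assay$plates) {
      v <- p$values
      v[!p$mask] <- NA_real_
      m <- matrix(fmt(as.vector(v)), nrow(v), ncol(v))
      utils::write.table(
        m, file.path(path, sprintf("plate_%04d.csv", p$plate_index)),
        sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
      )
    }
  }
  invisible(path)
}
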