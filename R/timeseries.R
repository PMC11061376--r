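# Data model for multi-ROI BOLD time-series: containers, I/O, min-max
# normalisation, masking/fill strategies, Pearson connectivity and the
# deterministic dimension-halving pyramid shared by the losses and metrics.

#' Multi-ROI BOLD time-series container
#'
#' Wraps an `N x T` numeric matrix of ROI-level BOLD values (rows are ROIs,
#' columns are timepoints) together with optional ROI labels and the
#' repetition time. Values are unitless BOLD amplitudes; after
#' [normalize_minmax()] the matrix lies in `[0, 1]` and attains both bounds.
#'
#' @param values Numeric matrix, `N x T` with `N >= 2`, `T >= 8`, all finite.
#' @param roi_labels Optional character vector of length `N`.
#' @param tr_seconds Positive repetition time in seconds (default 3.0, the
#'   sampling interval of typical resting-state acquisitions).
#' @return An object of class `roi_timeseries`.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(40), 4, 10))
#' dim(ts$values)
#' @export
roi_timeseries <- function(values, roi_labels = NULL, tr_seconds = 3.0) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix (rows = ROIs, columns = timepoints)")
  }
  if (nrow(values) < 2L) stop("N >= 2 required (at least two ROIs)")
  if (ncol(values) < 8L) stop("T >= 8 required (at least eight timepoints)")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at ROI row %d, timepoint %d", bad[1L], bad[2L]))
  }
  if (!is.null(roi_labels)) {
    stopifnot(length(roi_labels) == nrow(values))
    roi_labels <- as.character(roi_labels)
  }
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1L, tr_seconds > 0)
  structure(list(values = values, roi_labels = roi_labels,
                 tr_seconds = tr_seconds),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  v <- x$values
  cat(sprintf("<roi_timeseries> %d ROIs x %d timepoints (TR = %g s), range [%.3g, %.3g]\n",
              nrow(v), ncol(v), x$tr_seconds, min(v), max(v)))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$values)

# Accept either a roi_timeseries or a bare matrix.
ts_values <- function(x) {
  if (inherits(x, "roi_timeseries")) x$values else x
}

#' Missing-ROI mask and fill strategy
#'
#' Records which ROI rows are treated as missing (1-based indices) and how
#' the missing rows are initialised before restoration.
#'
#' @param missing_indices Integer vector of unique ROI row indices in
#'   `[1, N]`; fewer than `N` indices (at least one ROI must stay observed).
#' @param fill_strategy One of `"zero"`, `"random"`, `"gaussian"`, `"prior"`.
#'   `"prior"` fills each missing timepoint with the mean of the observed
#'   ROIs at that timepoint.
#' @param n_rois Optional total ROI count used to validate the indices.
#' @return An object of class `missing_mask`.
#' @examples
#' missing_mask(3, "prior")
#' @export
missing_mask <- function(missing_indices,
                         fill_strategy = c("prior", "zero", "random", "gaussian"),
                         n_rois = NULL) {
  fill_strategy <- match.arg(fill_strategy)
  missing_indices <- as.integer(missing_indices)
  if (length(missing_indices) < 1L) stop("mask must contain at least one index")
  if (anyDuplicated(missing_indices)) stop("mask indices must be unique")
  if (any(missing_indices < 1L)) stop("mask indices are 1-based and must be >= 1")
  if (!is.null(n_rois)) {
    if (any(missing_indices > n_rois)) stop("mask index exceeds ROI count")
    if (length(missing_indices) >= n_rois) {
      stop("at least one ROI must remain observed (N_m < N)")
    }
  }
  structure(list(missing_indices = sort(missing_indices),
                 fill_strategy = fill_strategy),
            class = "missing_mask")
}

#' @export
print.missing_mask <- function(x, ...) {
  cat(sprintf("<missing_mask> %d missing ROI(s): %s (fill = %s)\n",
              length(x$missing_indices),
              paste(x$missing_indices, collapse = ", "), x$fill_strategy))
  invisible(x)
}

check_mask <- function(mask, n_rois) {
  stopifnot(inherits(mask, "missing_mask"))
  if (any(mask$missing_indices > n_rois)) stop("mask index exceeds ROI count")
  if (length(mask$missing_indices) >= n_rois) {
    stop("at least one ROI must remain observed (N_m < N)")
  }
  invisible(mask)
}

#' Read a multi-ROI time-series matrix from disk
#'
#' Reads a rectangular numeric matrix with rows as ROIs and columns as
#' timepoints. Delimited files may carry an optional leading column of ROI
#' labels. `"rds"` is the package's binary matrix format.
#'
#' @param path File path.
#' @param format `"tsv"`, `"csv"` or `"rds"`; default guesses from the
#'   file extension.
#' @param tr_seconds Repetition time attached to the result.
#' @return A (un-normalised) [roi_timeseries()].
#' @export
read_timeseries <- function(path, format = c("auto", "tsv", "csv", "rds"),
                            tr_seconds = 3.0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", rds = "rds", "tsv")
  }
  if (format == "rds") {
    m <- readRDS(path)
    if (inherits(m, "roi_timeseries")) return(m)
    return(roi_timeseries(as.matrix(m), tr_seconds = tr_seconds))
  }
  sep <- if (format == "csv") "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  labels <- NULL
  first_col <- suppressWarnings(as.numeric(raw[[1L]]))
  if (anyNA(first_col)) {             # leading label column
    labels <- raw[[1L]]
    raw <- raw[, -1L, drop = FALSE]
  }
  if (ncol(raw) < 8L) stop("T >= 8 required (at least eight timepoints)")
  num <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or non-finite cell at row %d, column %d",
                 bad[1L, 1L], bad[1L, 2L]))
  }
  roi_timeseries(num, roi_labels = labels, tr_seconds = tr_seconds)
}

#' Write a multi-ROI time-series matrix to disk
#'
#' @param ts A [roi_timeseries()] (or bare matrix).
#' @param path Output path.
#' @param format `"tsv"`, `"csv"` or `"rds"`; default guesses from extension.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, format = c("auto", "tsv", "csv", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", rds = "rds", "tsv")
  }
  v <- ts_values(ts)
  if (format == "rds") {
    saveRDS(if (inherits(ts, "roi_timeseries")) ts else v, path)
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  out <- as.data.frame(v)
  labels <- if (inherits(ts, "roi_timeseries")) ts$roi_labels else NULL
  if (!is.null(labels)) out <- cbind(labels, out)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a missing-ROI mask as JSON
#'
#' The JSON object carries `missing_indices` (1-based) and `fill_strategy`.
#' @param path File path.
#' @return [missing_mask()] for `read_mask`; `path` invisibly for `write_mask`.
#' @export
read_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing_mask(obj$missing_indices, obj$fill_strategy)
}

#' @param mask A [missing_mask()].
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  jsonlite::write_json(list(missing_indices = mask$missing_indices,
                            fill_strategy = mask$fill_strategy),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Global min-max normalisation to [0, 1]
#'
#' Applies `(x - min) / (max - min)` with a single global minimum and
#' maximum over the whole matrix, so inter-ROI amplitude relations are
#' preserved (per-ROI scaling would distort the correlation structure the
#' connectivity-based losses rely on). Idempotent on its own output.
#'
#' @param ts A [roi_timeseries()] or numeric matrix.
#' @return A [roi_timeseries()] with values in `[0, 1]` attaining both bounds.
#' @export
normalize_minmax <- function(ts) {
  v <- ts_values(ts)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("degenerate signal: constant matrix cannot be normalised")
  out <- (v - lo) / (hi - lo)
  if (inherits(ts, "roi_timeseries")) {
    roi_timeseries(out, ts$roi_labels, ts$tr_seconds)
  } else {
    roi_timeseries(out)
  }
}

#' Mask ROIs and fill them according to a strategy
#'
#' Replaces the rows named by `mask` with an initial guess: `"zero"` (all
#' zeros), `"random"` (i.i.d. uniform on `[0, 1]`), `"gaussian"` (normal with
#' mean 0.5 and sd 0.17, clipped to `[0, 1]`, so +/- 3 sd spans the unit
#' interval) or `"prior"` (the per-timepoint mean over observed ROIs).
#' Observed rows are returned bit-identical.
#'
#' @param ts A normalised [roi_timeseries()].
#' @param mask A [missing_mask()].
#' @param seed Integer RNG seed, required for `"random"` and `"gaussian"`.
#' @return A [roi_timeseries()] with masked rows filled.
#' @export
apply_mask_and_fill <- function(ts, mask, seed = NULL) {
  v <- ts_values(ts)
  check_mask(mask, nrow(v))
  miss <- mask$missing_indices
  obs <- setdiff(seq_len(nrow(v)), miss)
  T <- ncol(v)
  fill <- switch(mask$fill_strategy,
    zero = matrix(0, length(miss), T),
    prior = {
      pr <- colMeans(v[obs, , drop = FALSE])
      matrix(rep(pr, each = length(miss)), length(miss), T)
    },
    random = {
      if (is.null(seed)) stop("seed required for the random fill strategy")
      withr_seed(seed, matrix(stats::runif(length(miss) * T), length(miss), T))
    },
    gaussian = {
      if (is.null(seed)) stop("seed required for the gaussian fill strategy")
      withr_seed(seed, {
        g <- matrix(stats::rnorm(length(miss) * T, mean = 0.5, sd = 0.17),
                    length(miss), T)
        pmin(pmax(g, 0), 1)
      })
    })
  out <- v
  out[miss, ] <- fill
  if (inherits(ts, "roi_timeseries")) {
    roi_timeseries(out, ts$roi_labels, ts$tr_seconds)
  } else {
    roi_timeseries(out)
  }
}

# Evaluate expr under a temporary RNG state.
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Pearson connectivity matrix of ROI rows
#'
#' Entry `(i, j)` is the Pearson correlation of ROI rows `i` and `j` across
#' time. The diagonal is exactly 1; rows with zero variance contribute 0 to
#' their off-diagonal entries (a finite convention instead of `NaN`).
#'
#' @param ts A [roi_timeseries()] or numeric matrix with `T >= 3`.
#' @return An `N x N` symmetric matrix with unit diagonal, entries in
#'   `[-1, 1]`.
#' @export
pcc_matrix <- function(ts) {
  v <- ts_values(ts)
  if (ncol(v) < 3L) stop("T >= 3 required for correlation")
  ag_corr_rows(v)
}

#' Deterministic temporal dimension-halving
#'
#' Applies `k` rounds of non-overlapping factor-2 temporal averaging (a
#' trailing odd sample is dropped before each round). This is the fixed
#' resampling used inside the multi-resolution consistency loss; the
#' discriminator's dimension-halving stages are learned convolutions and
#' share no code with it.
#'
#' @param ts A [roi_timeseries()] or numeric matrix.
#' @param k Integer number of halvings, `0 <= k <= 3`.
#' @return A matrix with `N` rows and `floor(.. floor(T/2) .. / 2)` columns.
#' @export
dh_resample <- function(ts, k) {
  v <- ts_values(ts)
  stopifnot(length(k) == 1L, k >= 0L, k <= 3L)
  if (ncol(v) < 2^k) stop("T too short for ", k, " halvings")
  for (i in seq_len(k)) v <- ag_avgpool2(v)
  v
}

#' Four-level resampling pyramid
#'
#' Levels `k = 0..3` of [dh_resample()]; level 0 is the input itself.
#'
#' @param ts A [roi_timeseries()] or numeric matrix with `T >= 8`.
#' @return A list of 4 matrices with temporal lengths `T, floor(T/2),
#'   floor(T/4), floor(T/8)`.
#' @export
build_pyramid <- function(ts) {
  v <- ts_values(ts)
  if (ncol(v) < 8L) stop("T >= 8 required for a four-level pyramid")
  out <- vector("list", 4L)
  out[[1L]] <- v
  for (k in 2:4) out[[k]] <- ag_avgpool2(out[[k - 1L]])
  out
}
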