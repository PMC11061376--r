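# Evaluation metrics over the missing ROIs only: MAE, RMSE, R^2, dynamic
# time warping, and connectivity-error summaries.

miss_rows <- function(x, mask) {
  v <- ts_values(x)
  check_mask(mask, nrow(v))
  v[mask$missing_indices, , drop = FALSE]
}

check_same_shape <- function(a, b) {
  if (!all(dim(ts_values(a)) == dim(ts_values(b)))) {
    stop("matrices must have identical shape")
  }
}

#' Mean absolute error over missing ROIs
#'
#' Per-element mean of `|Sg - Se|` restricted to the masked rows:
#' `1/(N_m * T) * sum_i sum_t |Sg[i,t] - Se[i,t]|`.
#'
#' @param sg Restored series ([roi_timeseries()] or matrix).
#' @param se Empirical (ground-truth) series, same shape.
#' @param mask A [missing_mask()].
#' @return Nonnegative scalar.
#' @export
mae_missing <- function(sg, se, mask) {
  check_same_shape(sg, se)
  mean(abs(miss_rows(sg, mask) - miss_rows(se, mask)))
}

#' Root mean square error over missing ROIs
#'
#' Per missing row, the square root of the mean squared difference over
#' time; then averaged over the `N_m` rows.
#'
#' @inheritParams mae_missing
#' @return Nonnegative scalar; always `>= mae_missing` on the same input.
#' @export
rmse_missing <- function(sg, se, mask) {
  check_same_shape(sg, se)
  d <- miss_rows(sg, mask) - miss_rows(se, mask)
  mean(sqrt(rowMeans(d * d)))
}

#' Coefficient of determination over missing ROIs
#'
#' Per missing row, `1 - SS_res / SS_tot` with the empirical row as truth;
#' averaged over rows. Requires nonzero variance in every truth row.
#'
#' @inheritParams mae_missing
#' @return Scalar `<= 1`.
#' @export
r2_missing <- function(sg, se, mask) {
  check_same_shape(sg, se)
  g <- miss_rows(sg, mask); e <- miss_rows(se, mask)
  ss_tot <- rowSums((e - rowMeans(e))^2)
  if (any(ss_tot <= 0)) stop("zero-variance truth row: R^2 undefined")
  ss_res <- rowSums((g - e)^2)
  mean(1 - ss_res / ss_tot)
}

#' Dynamic time warping distance between two series
#'
#' Classic dynamic-programming DTW with absolute-difference local cost and
#' the symmetric step pattern (match, insert, delete), no warping window.
#' The distance is the total cost of the optimal monotone alignment.
#'
#' @param x,y Numeric vectors (not necessarily the same length).
#' @return Nonnegative scalar; 0 iff an alignment with zero total cost
#'   exists. For equal-length series it is bounded above by
#'   `sum(abs(x - y))` (the diagonal path).
#' @export
dtw_distance <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("empty series")
  cost <- outer(x, y, function(a, b) abs(a - b))
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- cost[i, j] +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  D[n + 1L, m + 1L]
}

#' Mean DTW distance over missing ROIs
#'
#' [dtw_distance()] per missing row, averaged over the `N_m` rows.
#'
#' @inheritParams mae_missing
#' @return Nonnegative scalar.
#' @export
dtw_missing <- function(sg, se, mask) {
  check_same_shape(sg, se)
  g <- miss_rows(sg, mask); e <- miss_rows(se, mask)
  mean(vapply(seq_len(nrow(g)),
              function(i) dtw_distance(g[i, ], e[i, ]), numeric(1)))
}

#' Maximum connectivity change over missing-ROI-related connections
#'
#' Largest absolute difference between the Pearson connectivity of the
#' restored and empirical series, taken over the off-diagonal entries of the
#' missing ROIs' rows (the connections the restoration can disturb).
#'
#' @inheritParams mae_missing
#' @return Scalar in `[0, 2]`.
#' @export
fc_diff <- function(sg, se, mask) {
  check_same_shape(sg, se)
  dC <- abs(pcc_matrix(sg) - pcc_matrix(se))
  max(vapply(mask$missing_indices, function(m) max(dC[m, -m]), numeric(1)))
}

#' Full restoration report over the missing ROIs
#'
#' Computes MAE, RMSE, R^2 and DTW per missing ROI and in aggregate
#' (aggregates are the means of the per-ROI rows), plus the maximum
#' connectivity change [fc_diff()].
#'
#' @inheritParams mae_missing
#' @return An object of class `eval_report`: a list with scalar `mae`,
#'   `rmse`, `r2`, `dtw`, `fc_max_abs_diff` and a data frame `per_roi`.
#' @export
evaluate_restoration <- function(sg, se, mask) {
  check_same_shape(sg, se)
  g <- miss_rows(sg, mask); e <- miss_rows(se, mask)
  per <- data.frame(
    roi = mask$missing_indices,
    mae = rowMeans(abs(g - e)),
    rmse = sqrt(rowMeans((g - e)^2)),
    r2 = 1 - rowSums((g - e)^2) / rowSums((e - rowMeans(e))^2),
    dtw = vapply(seq_len(nrow(g)),
                 function(i) dtw_distance(g[i, ], e[i, ]), numeric(1))
  )
  structure(list(mae = mean(per$mae), rmse = mean(per$rmse),
                 r2 = mean(per$r2), dtw = mean(per$dtw),
                 fc_max_abs_diff = fc_diff(sg, se, mask),
                 per_roi = per),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> %d missing ROI(s)\n",
                     "  MAE %.4f  RMSE %.4f  R2 %.4f  DTW %.4f  max|dFC| %.4f\n"),
              nrow(x$per_roi), x$mae, x$rmse, x$r2, x$dtw, x$fc_max_abs_diff))
  invisible(x)
}

#' Serialise an evaluation report
#'
#' Writes the report as JSON (aggregate plus per-ROI rows) or as a TSV table
#' with one row per missing ROI and a final aggregate row.
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(mae = report$mae, rmse = report$rmse, r2 = report$r2,
           dtw = report$dtw, fc_max_abs_diff = report$fc_max_abs_diff,
           per_roi = report$per_roi),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    tab <- rbind(report$per_roi,
                 data.frame(roi = NA, mae = report$mae, rmse = report$rmse,
                            r2 = report$r2, dtw = report$dtw))
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
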