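#' Single change-point detectors
#'
#' Each detector scans every admissible split of the signal into two
#' segments, fits the segment model (constant mean, Gaussian variance, or
#' independent least-squares lines), and reports the first day of the new
#' regime that minimizes the two-segment cost. `score` is the cost reduction
#' relative to the one-segment fit; ties break to the earliest day. A signal
#' whose best split reduces the cost by (numerically) nothing is flagged
#' `degenerate` with confidence 0.
#'
#' @param signal numeric vector (length >= 4 for `cp_mean`, >= 6 for the
#'   others).
#' @return An object of class `change_point`: `kind`, `day`, `score`,
#'   `confidence` (`NA` until [cp_confidence()] is run, 0 if degenerate),
#'   `degenerate`.
#' @name change_point_detectors
NULL

new_change_point <- function(kind, scan, n) {
  degenerate <- scan$score <= 1e-9 * max(1, abs(scan$baseline))
  structure(list(kind = kind, day = as.integer(scan$day),
                 score = scan$score,
                 confidence = if (degenerate) 0 else NA_real_,
                 degenerate = degenerate, n = as.integer(n)),
            class = "change_point")
}

#' @rdname change_point_detectors
#' @export
cp_mean <- function(signal) {
  if (length(signal) < 4) stop("cp_mean needs at least 4 points")
  new_change_point("mean", cp_scan_mean_cpp(signal), length(signal))
}

#' @rdname change_point_detectors
#' @export
cp_variance <- function(signal) {
  if (length(signal) < 6) stop("cp_variance needs at least 6 points")
  new_change_point("variance", cp_scan_variance_cpp(signal), length(signal))
}

#' @rdname change_point_detectors
#' @export
cp_trend <- function(signal) {
  if (length(signal) < 6) stop("cp_trend needs at least 6 points")
  new_change_point("trend", cp_scan_trend_cpp(signal), length(signal))
}

cp_scan <- function(signal, kind) {
  switch(kind,
         mean = cp_scan_mean_cpp(signal),
         variance = cp_scan_variance_cpp(signal),
         trend = cp_scan_trend_cpp(signal),
         stop("unknown change-point kind: ", kind))
}

#' Permutation confidence of a change point
#'
#' Confidence is the add-one-corrected fraction of value-permuted surrogate
#' signals whose best cost-reduction score falls strictly below the
#' empirical score: `(r + 1) / (n_boot + 1)`. Degenerate change points get
#' confidence 0 without resampling.
#'
#' @param signal the signal the change point was detected on.
#' @param point the [cp_mean()]/[cp_variance()]/[cp_trend()] result (or a
#'   kind string, in which case the detector is re-run).
#' @param n_boot number of permutation surrogates.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return The `change_point` with `confidence` filled in.
#' @export
cp_confidence <- function(signal, point, n_boot = 500, seed = NULL) {
  if (is.character(point))
    point <- switch(point, mean = cp_mean(signal),
                    variance = cp_variance(signal), trend = cp_trend(signal))
  if (point$degenerate) {
    point$confidence <- 0
    return(point)
  }
  if (!is.null(seed)) set.seed(seed)
  r <- 0L
  for (b in seq_len(n_boot)) {
    if (cp_scan(sample(signal), point$kind)$score < point$score) r <- r + 1L
  }
  point$confidence <- (r + 1) / (n_boot + 1)
  point
}

#' Matrix-level change point via per-line pooling
#'
#' Runs the mean change-point detector on every line (row) of a matrix,
#' builds a day histogram of the non-degenerate line-level change points
#' (bin width one day), and reports the histogram mode as the matrix change
#' point (ties to the earliest day). Confidence is the fraction of
#' non-degenerate lines whose change day falls within `mode_window` days of
#' the mode. This is the pooling used for recurrence-plot lines and
#' time-frequency rows.
#'
#' @param mat numeric lines x days matrix.
#' @param kind `"rp_lines"` or `"tfd_lines"` (label only).
#' @param mode_window half-width of the agreement window (days).
#' @return A `change_point` whose `score` is the mode's histogram count,
#'   plus `line_days`, the non-degenerate line-level days.
#' @export
matrix_cp <- function(mat, kind = c("rp_lines", "tfd_lines"), mode_window = 3) {
  kind <- match.arg(kind)
  if (!is.matrix(mat) || nrow(mat) < 2) stop("need a matrix with >= 2 lines")
  days <- integer(0)
  for (i in seq_len(nrow(mat))) {
    row <- mat[i, ]
    row <- row[!is.na(row)]
    if (length(row) < 4) next
    scan <- cp_scan_mean_cpp(row)
    if (scan$score > 1e-9 * max(1, abs(scan$baseline)))
      days <- c(days, scan$day)
  }
  if (length(days) == 0)
    return(structure(list(kind = kind, day = NA_integer_, score = 0,
                          confidence = 0, degenerate = TRUE,
                          n = ncol(mat), line_days = integer(0)),
                     class = "change_point"))
  counts <- table(days)
  mode_day <- as.integer(names(counts)[which.max(counts)])  # earliest on ties
  conf <- mean(abs(days - mode_day) <= mode_window)
  structure(list(kind = kind, day = mode_day,
                 score = as.numeric(max(counts)), confidence = conf,
                 degenerate = FALSE, n = ncol(mat), line_days = days),
            class = "change_point")
}

#' @export
print.change_point <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("change_point[%s]: degenerate (no detectable change)\n", x$kind))
  } else {
    cat(sprintf("change_point[%s]: day %d, score %.4g, confidence %s\n",
                x$kind, x$day, x$score,
                if (is.na(x$confidence)) "<not computed>"
                else sprintf("%.3f", x$confidence)))
  }
  invisible(x)
}
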