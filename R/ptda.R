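#' Configuration of the pattern transition detection algorithm
#'
#' @param level analysis level: `"factor"` (the seven questionnaire factors,
#'   the conventional per-case readout) or `"item"`.
#' @param pooling `"case_level"` pools all channels' change points into one
#'   histogram (one transition estimate per case); `"per_channel"` estimates
#'   a transition per channel.
#' @param mode_window_w half-width (days) of the agreement window around the
#'   pooled mode used for the transition probability.
#' @param n_surrogates surrogates for the transition-level p value (>= 100).
#' @param cp_boot permutation count for per-detector confidence.
#' @param seed integer seed driving all randomness of a run.
#' @param complexity a [complexity_params()] for the DC stage.
#' @param recurrence a [recurrence_params()] for the recurrence-plot stage.
#' @param tfd_window window width (days) of the time-frequency stage.
#' @return An object of class `ptda_config`.
#' @export
ptda_config <- function(level = c("factor", "item"),
                        pooling = c("case_level", "per_channel"),
                        mode_window_w = 3, n_surrogates = 200, cp_boot = 200,
                        seed = 1L, complexity = complexity_params(seed = seed),
                        recurrence = recurrence_params(), tfd_window = 7) {
  level <- match.arg(level)
  pooling <- match.arg(pooling)
  stopifnot(mode_window_w >= 0, n_surrogates >= 100, cp_boot >= 50)
  structure(list(level = level, pooling = pooling,
                 mode_window_w = as.integer(mode_window_w),
                 n_surrogates = as.integer(n_surrogates),
                 cp_boot = as.integer(cp_boot), seed = as.integer(seed),
                 complexity = complexity, recurrence = recurrence,
                 tfd_window = as.integer(tfd_window)),
            class = "ptda_config")
}

#' The six change points of one channel
#'
#' Computes the change points pooled by the transition detector: mean,
#' variance and linear trend of the raw channel; a mean change of its
#' dynamic-complexity series; and line-pooled mean changes of its recurrence
#' plot and its time-frequency distribution. Days from the second-order
#' stages are mapped back to raw-day coordinates using the right-aligned
#' window/embedding-end convention. Stages whose input is too short are
#' recorded as degenerate with a `skipped` reason.
#'
#' @param x numeric channel (imputed, length >= 4).
#' @param config a [ptda_config()]; `config$cp_boot` controls the
#'   permutation count behind each detector's confidence.
#' @return A list of six `change_point` objects named `mean`, `variance`,
#'   `trend`, `dc_mean`, `rp_lines`, `tfd_lines`.
#' @export
six_change_points <- function(x, config = ptda_config()) {
  n <- length(x)
  if (n < 4) stop("fewer than 4 usable points")
  degenerate_cp <- function(kind, reason) {
    structure(list(kind = kind, day = NA_integer_, score = 0, confidence = 0,
                   degenerate = TRUE, n = n, skipped = reason),
              class = "change_point")
  }
  conf_or_raw <- function(sig, kind) {
    cp_confidence(sig, kind, n_boot = config$cp_boot)
  }

  out <- list()
  out$mean <- conf_or_raw(x, "mean")
  out$variance <- if (n >= 6) conf_or_raw(x, "variance")
                  else degenerate_cp("variance", "too short")
  out$trend <- if (n >= 6) conf_or_raw(x, "trend")
               else degenerate_cp("trend", "too short")

  # mean change of the DC series (defined part), day mapped to raw grid
  m <- config$complexity$window_m
  if (n >= m + 3) {
    dc <- dc_values(x, config$complexity)[m:n]
    pt <- conf_or_raw(dc, "mean")
    pt$kind <- "dc_mean"
    if (!pt$degenerate) pt$day <- pt$day + m - 1L
    out$dc_mean <- pt
  } else out$dc_mean <- degenerate_cp("dc_mean", "too short for DC window")

  # recurrence-plot lines
  emb_offset <- (config$recurrence$embed_dim - 1L) * config$recurrence$delay_tau
  if (n - emb_offset >= 4) {
    rp <- recurrence_matrix(delay_embed(x, config$recurrence), config$recurrence)
    if (rp$degenerate) {
      out$rp_lines <- degenerate_cp("rp_lines", "degenerate recurrence matrix")
    } else {
      pt <- matrix_cp(rp$matrix, "rp_lines", config$mode_window_w)
      if (!pt$degenerate) pt$day <- pt$day + emb_offset
      out$rp_lines <- pt
    }
  } else out$rp_lines <- degenerate_cp("rp_lines", "too short for embedding")

  # time-frequency rows
  w <- config$tfd_window
  if (n >= w + 3) {
    tfd <- tfd_matrix(x, w)
    vals <- tfd$values[, w:n, drop = FALSE]
    pt <- matrix_cp(vals, "tfd_lines", config$mode_window_w)
    if (!pt$degenerate) pt$day <- pt$day + w - 1L
    out$tfd_lines <- pt
  } else out$tfd_lines <- degenerate_cp("tfd_lines", "too short for TFD window")

  out
}

#' Pool change points into a transition estimate
#'
#' Builds a histogram of the non-degenerate change-point days weighted by
#' their confidences; the transition day is the weighted mode (ties to the
#' earliest day). The transition probability is the summed confidence of
#' points within `mode_window_w` days of the transition day, divided by the
#' total number of points including degenerate ones (each point can
#' contribute at most weight 1, and degenerate points count as evidence of
#' no change).
#'
#' @param points a flat list of `change_point` objects (one or many
#'   channels).
#' @param config a [ptda_config()].
#' @return An object of class `transition_estimate`: `transition_day`,
#'   `probability`, `surrogate_p` (`NA` until [ptda_surrogate_p()]),
#'   `pooled_histogram` (named day -> weight), `points`, `n_points`,
#'   `n_degenerate`.
#' @examples
#' pts <- lapply(c(65, 65, 64, 66, 63, 20), function(d)
#'   structure(list(kind = "mean", day = d, score = 1, confidence = 1,
#'                  degenerate = FALSE), class = "change_point"))
#' est <- pool_and_estimate(pts, ptda_config())
#' est$transition_day  # 65
#' est$probability     # 5/6
#' @export
pool_and_estimate <- function(points, config = ptda_config()) {
  stopifnot(length(points) >= 1)
  live <- Filter(function(p) !p$degenerate && !is.na(p$day), points)
  if (length(live) == 0) stop("all change points are degenerate")
  days <- vapply(live, function(p) p$day, integer(1))
  wts <- pmin(1, vapply(live, function(p) p$confidence, numeric(1)))
  if (anyNA(wts)) stop("points must carry confidences (run cp_confidence)")
  hist <- tapply(wts, days, sum)
  hist <- hist[order(as.integer(names(hist)))]
  td <- as.integer(names(hist)[which.max(hist)])  # earliest on weight ties
  in_window <- abs(days - td) <= config$mode_window_w
  prob <- sum(wts[in_window]) / length(points)
  structure(list(transition_day = td, probability = prob,
                 surrogate_p = NA_real_,
                 pooled_histogram = hist, points = points,
                 n_points = length(points),
                 n_degenerate = length(points) - length(live),
                 mode_window_w = config$mode_window_w),
            class = "transition_estimate")
}

#' Surrogate p value of a transition estimate
#'
#' Recomputes the full pooled transition probability on `n_surrogates`
#' copies of the series in which every channel's values are independently
#' permuted, and reports the add-one-corrected fraction of surrogates whose
#' probability reaches the empirical one.
#'
#' @param series the analyzed (imputed, analysis-level) [process_series()].
#' @param estimate the empirical [pool_and_estimate()] result.
#' @param config the [ptda_config()] used for the empirical run.
#' @return p value in (0, 1\].
#' @export
ptda_surrogate_p <- function(series, estimate, config = ptda_config()) {
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  r <- 0L
  for (s in seq_len(config$n_surrogates)) {
    surr <- series
    for (i in seq_len(nrow(surr$values)))
      surr$values[i, ] <- sample(surr$values[i, ])
    pts <- unlist(lapply(seq_len(nrow(surr$values)), function(i)
      six_change_points(surr$values[i, ], config)),
      recursive = FALSE)
    prob <- tryCatch(pool_and_estimate(pts, config)$probability,
                     error = function(e) 0)
    if (prob >= estimate$probability) r <- r + 1L
  }
  (r + 1) / (config$n_surrogates + 1)
}

#' Run the pattern transition detection algorithm
#'
#' Full pipeline: aggregate to factor scores if requested, compute the six
#' change points per channel, pool them per the configuration, and attach
#' the surrogate p value. All provenance (per-channel points, pooled
#' histogram) is retained on the returned estimate.
#'
#' @param series an imputed [process_series()] (item level is aggregated
#'   with [factor_scores()] when `config$level == "factor"`).
#' @param config a [ptda_config()].
#' @param surrogate compute the transition-level surrogate p value (the
#'   costliest stage; disable for simulation studies that only need the day
#'   and probability).
#' @return For case-level pooling, a `transition_estimate` with
#'   `per_channel` (the six points per channel) attached; for per-channel
#'   pooling, a named list of per-channel estimates.
#' @export
run_ptda <- function(series, config = ptda_config(), surrogate = TRUE) {
  if (any(series$missing)) stop("impute the series first (see locf_impute)")
  n <- length(series$days)
  if (n < 4 * config$complexity$window_m)
    stop("series too short for transition detection (need at least ",
         4 * config$complexity$window_m, " days)")
  if (config$level == "factor" && series$level == "item")
    series <- factor_scores(series)
  if (!is.null(config$seed)) set.seed(config$seed)
  per_channel <- lapply(seq_len(nrow(series$values)), function(i)
    six_change_points(series$values[i, ], config))
  names(per_channel) <- series$channels

  if (config$pooling == "per_channel") {
    return(lapply(per_channel, pool_and_estimate, config = config))
  }
  est <- pool_and_estimate(unlist(per_channel, recursive = FALSE), config)
  est$per_channel <- per_channel
  est$config <- config
  if (surrogate) est$surrogate_p <- ptda_surrogate_p(series, est, config)
  est
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat(sprintf("transition_estimate: day %d, probability %.3f",
              x$transition_day, x$probability))
  if (!is.na(x$surrogate_p)) cat(sprintf(", surrogate p %.3f", x$surrogate_p))
  cat(sprintf("\n  pooled from %d change points (%d degenerate)\n",
              x$n_points, x$n_degenerate))
  invisible(x)
}
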