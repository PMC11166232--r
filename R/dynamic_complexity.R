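#' Parameters for dynamic complexity analysis
#'
#' @param window_m sliding window width in days (>= 3); the conventional
#'   width for daily self-ratings is 7.
#' @param scale_min,scale_max scale bounds used to normalize the measures.
#' @param n_surrogates number of value-permutation surrogates (>= 100).
#' @param alpha_gray,alpha_black one-sided tail probabilities for the two
#'   significance shades of the complexity resonance diagram.
#' @param seed integer seed for the surrogate permutations.
#' @return An object of class `complexity_params`.
#' @export
complexity_params <- function(window_m = 7, scale_min = 0, scale_max = 100,
                              n_surrogates = 1000, alpha_gray = 0.05,
                              alpha_black = 0.01, seed = 1L) {
  stopifnot(window_m >= 3, n_surrogates >= 100,
            alpha_black > 0, alpha_black < alpha_gray, alpha_gray < 1,
            scale_min < scale_max)
  structure(list(window_m = as.integer(window_m),
                 scale_min = scale_min, scale_max = scale_max,
                 n_surrogates = as.integer(n_surrogates),
                 alpha_gray = alpha_gray, alpha_black = alpha_black,
                 seed = as.integer(seed)),
            class = "complexity_params")
}

check_window <- function(window, window_m, scale_min, scale_max) {
  if (length(window) != window_m)
    stop("window must have exactly ", window_m, " values")
  if (anyNA(window)) stop("window contains missing values")
  if (any(window < scale_min | window > scale_max))
    stop("window values outside scale bounds")
}

#' Fluctuation measure F of a single window
#'
#' Sums, over the maximal monotone segments of the window, the absolute
#' change across each segment divided by its length in steps, and normalizes
#' by the largest attainable value (full-scale alternation at every step).
#' Plateaus extend the current segment. F is 1 for a window alternating
#' between the scale bounds at every step and 0 for a constant window.
#'
#' @param window numeric vector of length `window_m`.
#' @param scale_min,scale_max scale bounds.
#' @param window_m window width; defaults to `length(window)`.
#' @return F in \[0, 1\].
#' @examples
#' fluctuation_intensity(c(0, 100, 0, 100, 0, 100, 0), 0, 100)  # 1
#' @export
fluctuation_intensity <- function(window, scale_min = 0, scale_max = 100,
                                  window_m = length(window)) {
  check_window(window, window_m, scale_min, scale_max)
  dc_fd_windows(matrix(window, ncol = 1), scale_min, scale_max)[1, 1]
}

#' Distribution measure D of a single window
#'
#' Compares the sorted window with an ideal equidistant spread across the
#' scale range: D = 1 minus the summed pairwise gap deficit relative to the
#' summed ideal gaps. D is 1 for an equidistant full-range window and 0 for
#' a constant one. D depends only on the multiset of values (it is
#' permutation invariant), while F is order sensitive.
#'
#' @inheritParams fluctuation_intensity
#' @return D in \[0, 1\].
#' @examples
#' distribution_measure(c(0, 100, 0, 100, 0, 100, 0), 0, 100)  # 0.75
#' @export
distribution_measure <- function(window, scale_min = 0, scale_max = 100,
                                 window_m = length(window)) {
  check_window(window, window_m, scale_min, scale_max)
  dc_fd_windows(matrix(window, ncol = 1), scale_min, scale_max)[2, 1]
}

#' Dynamic complexity values of one channel
#'
#' DC(t) = F * D on the right-aligned window ending at day t; the first
#' `window_m - 1` days are `NA` (no complete window yet).
#'
#' @param x numeric vector (one channel, no missing values).
#' @param params a [complexity_params()].
#' @return Numeric vector of length `length(x)`.
#' @export
dc_values <- function(x, params) {
  m <- params$window_m
  n <- length(x)
  if (n < m) stop("series shorter than the window width")
  if (anyNA(x)) stop("impute the series before computing dynamic complexity")
  win <- t(stats::embed(x, m)[, m:1, drop = FALSE])  # m x (n - m + 1) windows
  fd <- dc_fd_windows(win, params$scale_min, params$scale_max)
  c(rep(NA_real_, m - 1), fd[1, ] * fd[2, ])
}

#' Dynamic complexity field of a process series
#'
#' Computes DC per channel and day in a sliding right-aligned window.
#'
#' @param series an imputed [process_series()].
#' @param params a [complexity_params()]; scale bounds default to the
#'   series' schema.
#' @return An object of class `complexity_field`: `values` (channels x days
#'   matrix of DC, `NA` on the first `window_m - 1` days), `days`,
#'   `channels`, `params`. Significance layers are added by [build_crd()].
#' @export
dc_series <- function(series, params = NULL) {
  if (is.null(params))
    params <- complexity_params(scale_min = series$schema$scale_min,
                                scale_max = series$schema$scale_max)
  if (any(series$missing)) stop("impute the series first (see locf_impute)")
  vals <- t(apply(series$values, 1, dc_values, params = params))
  dimnames(vals) <- list(series$channels, NULL)
  structure(list(values = vals, days = series$days,
                 channels = series$channels, params = params,
                 case_id = series$case_id),
            class = "complexity_field")
}

#' Surrogate null distribution of dynamic complexity
#'
#' For each channel, draws `n_surrogates` independent random permutations of
#' the observed values, recomputes the DC series of each, and summarizes the
#' pooled null per channel (tail quantiles, mean, sd). The permutation
#' scheme preserves each channel's marginal value distribution while
#' destroying temporal order. Day-wise cross-channel mean DC surrogates are
#' retained for case-level instability testing.
#'
#' @param series an imputed [process_series()].
#' @param params a [complexity_params()] (seed taken from here).
#' @return An object of class `dc_null` with per-channel summaries
#'   (`q_gray`, `q_black`, `mean`, `sd`), the per-channel surrogate DC
#'   matrices (`samples`, surrogates x defined days), and the case-mean
#'   surrogate matrix (`case_mean`).
#' @export
surrogate_null <- function(series, params = NULL) {
  if (is.null(params))
    params <- complexity_params(scale_min = series$schema$scale_min,
                                scale_max = series$schema$scale_max)
  if (any(series$missing)) stop("impute the series first (see locf_impute)")
  if (params$n_surrogates < 100) stop("n_surrogates must be >= 100")
  if (!is.null(params$seed)) set.seed(params$seed)
  m <- params$window_m
  n <- length(series$days)
  ndef <- n - m + 1
  nch <- length(series$channels)
  samples <- vector("list", nch)
  names(samples) <- series$channels
  case_sum <- matrix(0, params$n_surrogates, ndef)
  for (i in seq_len(nch)) {
    x <- series$values[i, ]
    M <- matrix(NA_real_, params$n_surrogates, ndef)
    for (s in seq_len(params$n_surrogates)) {
      M[s, ] <- dc_values(sample(x), params)[m:n]
    }
    samples[[i]] <- M
    case_sum <- case_sum + M
  }
  q <- function(M, p) stats::quantile(M, p, names = FALSE)
  structure(list(
    channels = series$channels,
    q_gray = vapply(samples, q, numeric(1), p = 1 - params$alpha_gray),
    q_black = vapply(samples, q, numeric(1), p = 1 - params$alpha_black),
    mean = vapply(samples, mean, numeric(1)),
    sd = vapply(samples, stats::sd, numeric(1)),
    samples = samples,
    case_mean = case_sum / nch,
    defined_days = series$days[m:n],
    params = params
  ), class = "dc_null")
}

#' Build the complexity resonance diagram layers
#'
#' Adds z-values (DC standardized against the channel's surrogate null) and
#' the one-sided significance masks to a complexity field: `gray_mask` where
#' DC exceeds the channel's empirical (1 - alpha_gray) null quantile,
#' `black_mask` for (1 - alpha_black), and the per-day column histogram of
#' flagged cells. Masks are quantile-based (no normality assumption); the z
#' values are carried for display.
#'
#' @param field a [dc_series()] result.
#' @param null a [surrogate_null()] from the same series and parameters.
#' @return The field with `z`, `gray_mask`, `black_mask` and
#'   `column_histogram` filled in.
#' @export
build_crd <- function(field, null) {
  if (!identical(field$channels, null$channels))
    stop("field and null were not computed on the same channels")
  vals <- field$values
  z <- gray <- black <- matrix(NA_real_, nrow(vals), ncol(vals),
                               dimnames = dimnames(vals))
  for (i in seq_len(nrow(vals))) {
    x <- vals[i, ]
    sdv <- null$sd[i]
    if (sdv == 0) {
      defined <- x[!is.na(x)]
      if (any(abs(defined - null$mean[i]) > 1e-12))
        stop("degenerate surrogate null (sd = 0) with nonconstant empirical DC in channel ",
             field$channels[i])
      z[i, ] <- ifelse(is.na(x), NA, 0)
    } else {
      z[i, ] <- (x - null$mean[i]) / sdv
    }
    gray[i, ] <- !is.na(x) & x > null$q_gray[i]
    black[i, ] <- !is.na(x) & x > null$q_black[i]
  }
  field$z <- z
  field$gray_mask <- gray == 1
  field$black_mask <- black == 1
  field$column_histogram <- colSums(field$gray_mask | field$black_mask,
                                    na.rm = TRUE)
  field
}

#' Significant critical-instability periods
#'
#' Flags days whose (channel or cross-channel mean) DC exceeds the
#' `(1 - alpha)` surrogate null quantile, merges consecutive flagged days
#' (bridging gaps of at most `max_gap` days) into periods, and attaches to
#' each period a Monte-Carlo p value: the add-one-corrected fraction of
#' surrogate series whose maximum same-length rolling mean DC reaches the
#' period's mean DC.
#'
#' @param field a [dc_series()] result.
#' @param null the matching [surrogate_null()].
#' @param scope `"case_mean"` (day-wise mean DC across channels, one row of
#'   results) or `"per_channel"` (each channel separately).
#' @param alpha one-sided flagging level.
#' @param max_gap maximum run gap bridged when merging flagged days.
#' @return A data frame with columns `channel` (`"(case mean)"` for
#'   case-level scope), `start_day`, `end_day`, `mean_dc`, `p_value`.
#' @export
instability_periods <- function(field, null, scope = c("case_mean", "per_channel"),
                                alpha = 0.05, max_gap = 1) {
  scope <- match.arg(scope)
  m <- field$params$window_m
  def_idx <- which(field$days %in% null$defined_days)
  if (length(def_idx) == 0) stop("empty complexity field")
  one_scope <- function(emp, surr, label) {
    thr <- stats::quantile(surr, 1 - alpha, names = FALSE)
    flagged <- which(emp > thr)
    if (length(flagged) == 0) return(NULL)
    runs <- merge_runs(flagged, max_gap)
    do.call(rbind, lapply(runs, function(r) {
      len <- r[2] - r[1] + 1
      stat <- mean(emp[r[1]:r[2]])
      maxes <- apply(surr, 1, function(row) max(roll_mean(row, len)))
      p <- (sum(maxes >= stat) + 1) / (nrow(surr) + 1)
      data.frame(channel = label,
                 start_day = null$defined_days[r[1]],
                 end_day = null$defined_days[r[2]],
                 mean_dc = stat, p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- if (scope == "case_mean") {
    emp <- colMeans(field$values[, def_idx, drop = FALSE])
    one_scope(emp, null$case_mean, "(case mean)")
  } else {
    do.call(rbind, lapply(seq_along(field$channels), function(i) {
      one_scope(field$values[i, def_idx], null$samples[[i]], field$channels[i])
    }))
  }
  if (is.null(out))
    out <- data.frame(channel = character(), start_day = integer(),
                      end_day = integer(), mean_dc = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo p value of a candidate instability period
#'
#' The same statistic [instability_periods()] attaches to detected periods,
#' exposed for an arbitrary day range: the add-one-corrected fraction of
#' surrogate series whose maximum rolling mean DC (window = the period
#' length) reaches the empirical period mean.
#'
#' @inheritParams instability_periods
#' @param start_day,end_day period bounds in day coordinates (must lie in
#'   the defined part of the field).
#' @param channel channel label, required when `scope = "per_channel"`.
#' @return A single p value in (0, 1\].
#' @export
instability_pvalue <- function(field, null, start_day, end_day,
                               scope = c("case_mean", "per_channel"),
                               channel = NULL) {
  scope <- match.arg(scope)
  idx <- match(start_day:end_day, null$defined_days)
  if (anyNA(idx)) stop("period outside the defined day range")
  def_idx <- which(field$days %in% null$defined_days)
  if (scope == "case_mean") {
    emp <- colMeans(field$values[, def_idx, drop = FALSE])
    surr <- null$case_mean
  } else {
    if (is.null(channel)) stop("channel required for per_channel scope")
    i <- match(channel, field$channels)
    emp <- field$values[i, def_idx]
    surr <- null$samples[[i]]
  }
  len <- length(idx)
  stat <- mean(emp[idx])
  maxes <- apply(surr, 1, function(row) max(roll_mean(row, len)))
  (sum(maxes >= stat) + 1) / (nrow(surr) + 1)
}

# consecutive runs over sorted indices, bridging gaps <= max_gap + ... a gap
# of g missing days between flagged days is bridged when g <= max_gap
merge_runs <- function(idx, max_gap) {
  runs <- list()
  start <- prev <- idx[1]
  for (i in idx[-1]) {
    if (i - prev - 1 > max_gap) {
      runs[[length(runs) + 1]] <- c(start, prev)
      start <- i
    }
    prev <- i
  }
  runs[[length(runs) + 1]] <- c(start, prev)
  runs
}

roll_mean <- function(x, k) {
  if (k == 1) return(x)
  cs <- cumsum(c(0, x))
  (cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]) / k
}

#' Export a complexity resonance diagram as CSV
#'
#' Long-format companion table `channel, day, dc, z, gray, black`.
#'
#' @param field a [build_crd()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_crd_csv <- function(field, path) {
  df <- data.frame(
    channel = rep(field$channels, times = length(field$days)),
    day = rep(field$days, each = length(field$channels)),
    dc = as.vector(field$values),
    z = as.vector(field$z),
    gray = as.vector(field$gray_mask),
    black = as.vector(field$black_mask)
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
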