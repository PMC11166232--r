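#' Specification of a synthetic monitoring case
#'
#' Defines the generative conditions for a questionnaire-like multichannel
#' daily series: a stable pre-transition regime per factor, an optional
#' abrupt level shift (the pattern transition), an optional window of
#' elevated fluctuation (critical instability), an optional transient
#' relapse just before the shift, and completely-at-random missingness in
#' both the ratings and the diary-category timeline. Magnitudes are
#' expressed in units of the baseline noise sd so statistical power is
#' tunable.
#'
#' @param n_days series length in days (realistic monitoring stays run
#'   roughly 60-100 days).
#' @param schema a [tpq_schema()]; defaults to the 43-item / 7-factor one.
#' @param transition_day first day of the post-transition regime, or `NULL`
#'   for no planted transition.
#' @param level_shift_sd size of the level shift in baseline-noise-sd units.
#' @param shifted_channel_fraction fraction of factors receiving the shift.
#' @param instability_window integer `c(start, end)` of the critical
#'   instability window, or `NULL`.
#' @param instability_gain multiplier (>= 1) applied to the noise sd inside
#'   the window; half of it also drives a day-alternating latent component,
#'   so both the order-sensitive fluctuation measure and the
#'   distribution measure respond.
#' @param ar_phi AR(1) coefficient of the latent factor paths, in \[0, 1).
#' @param noise_sd baseline noise sd in scale units.
#' @param missing_rate_values MCAR missingness rate of the ratings.
#' @param missing_rate_entries MCAR missingness rate of the diary timeline.
#' @param relapse `NULL` or a list/vector `(day, depth_sd, duration)`: a
#'   transient excursion against the planted shift ending at or before the
#'   transition day.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_days = 90, schema = tpq43_schema(),
                           transition_day = 60, level_shift_sd = 1.5,
                           shifted_channel_fraction = 0.7,
                           instability_window = NULL, instability_gain = 3,
                           ar_phi = 0.6, noise_sd = 6,
                           missing_rate_values = 0.016,
                           missing_rate_entries = 0.152,
                           relapse = NULL, seed = 1L) {
  stopifnot(n_days >= 10, ar_phi >= 0, ar_phi < 1, noise_sd > 0,
            instability_gain >= 1,
            missing_rate_values >= 0, missing_rate_values <= 1,
            missing_rate_entries >= 0, missing_rate_entries <= 1,
            shifted_channel_fraction >= 0, shifted_channel_fraction <= 1)
  if (!is.null(transition_day) &&
      (transition_day <= 1 || transition_day > n_days))
    stop("transition_day must satisfy 1 < transition_day <= n_days")
  if (!is.null(instability_window)) {
    instability_window <- as.integer(instability_window)
    if (length(instability_window) != 2 || instability_window[1] > instability_window[2] ||
        instability_window[1] < 1 || instability_window[2] > n_days)
      stop("instability_window must be c(start, end) within the day range")
  }
  if (!is.null(relapse)) {
    relapse <- as.list(relapse)
    names(relapse) <- c("day", "depth_sd", "duration")[seq_along(relapse)]
    if (is.null(transition_day))
      stop("a relapse requires a planted transition")
    if (relapse$day < 1 || relapse$day + relapse$duration - 1 >= transition_day)
      stop("the relapse must end before the transition day")
  }
  structure(list(n_days = as.integer(n_days), schema = schema,
                 transition_day = if (is.null(transition_day)) NULL
                                  else as.integer(transition_day),
                 level_shift_sd = level_shift_sd,
                 shifted_channel_fraction = shifted_channel_fraction,
                 instability_window = instability_window,
                 instability_gain = instability_gain,
                 ar_phi = ar_phi, noise_sd = noise_sd,
                 missing_rate_values = missing_rate_values,
                 missing_rate_entries = missing_rate_entries,
                 relapse = relapse, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a multichannel daily process series
#'
#' Per factor, draws a latent AR(1) path around the regime mean: a
#' pre-transition mean per factor, shifted by `level_shift_sd * noise_sd` on
#' a seeded subset of `shifted_channel_fraction` of the factors from the
#' transition day onward. Item values are the factor latent plus independent
#' noise, clipped to the scale. Inside the instability window the item noise
#' sd is multiplied by `instability_gain` and a day-alternating component of
#' amplitude `instability_gain / 2 * noise_sd` is added to the latent path.
#' An optional relapse pulls the latent mean against the shift direction
#' just before the transition. Values are then masked missing completely at
#' random at `missing_rate_values`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `series` (item-level [process_series()] with missing
#'   values) and `truth` (class `synthetic_truth`: planted regime means,
#'   transition day, instability window, relapse, shifted factors, seed).
#' @export
simulate_process <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  sch <- spec$schema
  n <- spec$n_days
  factors <- sch$factors
  nfac <- length(factors)
  td <- spec$transition_day

  pre_means <- stats::rnorm(nfac, 50, 10)
  pre_means <- pmin(pmax(pre_means, 20), 80)
  names(pre_means) <- factors
  n_shift <- round(spec$shifted_channel_fraction * nfac)
  shifted <- sort(sample(factors, n_shift))
  shift <- spec$level_shift_sd * spec$noise_sd
  post_means <- pre_means + ifelse(factors %in% shifted, shift, 0)
  names(post_means) <- factors

  in_window <- rep(FALSE, n)
  if (!is.null(spec$instability_window))
    in_window[spec$instability_window[1]:spec$instability_window[2]] <- TRUE
  sd_gain <- ifelse(in_window, spec$instability_gain, 1)
  alt <- ifelse(in_window, (-1)^(seq_len(n)) * spec$instability_gain / 2 *
                  spec$noise_sd, 0)

  mean_path <- function(f) {
    mu <- rep(pre_means[[f]], n)
    if (!is.null(td) && f %in% shifted) mu[td:n] <- post_means[[f]]
    if (!is.null(spec$relapse) && f %in% shifted) {
      rl <- spec$relapse
      idx <- rl$day:(rl$day + rl$duration - 1)
      mu[idx] <- mu[idx] - rl$depth_sd * spec$noise_sd
    }
    mu
  }

  # The latent factor state is the slow common component; day-to-day
  # variation is dominated by item-level noise (noise_sd), so the latent
  # innovations run at half that scale.
  latent <- matrix(0, nfac, n, dimnames = list(factors, NULL))
  for (f in factors) {
    mu <- mean_path(f)
    innov <- stats::rnorm(n, 0, spec$noise_sd / 2 * sd_gain)
    l <- numeric(n)
    l[1] <- mu[1] + innov[1]
    for (t in 2:n)
      l[t] <- mu[t] + spec$ar_phi * (l[t - 1] - mu[t - 1]) + innov[t]
    latent[f, ] <- l + alt
  }

  values <- matrix(NA_real_, length(sch$items), n,
                   dimnames = list(sch$items, NULL))
  for (it in sch$items) {
    f <- sch$factor_of[[it]]
    noise <- stats::rnorm(n, 0, spec$noise_sd * sd_gain)
    values[it, ] <- pmin(pmax(latent[f, ] + noise, sch$scale_min),
                         sch$scale_max)
  }

  missing <- matrix(stats::runif(length(values)) < spec$missing_rate_values,
                    nrow(values), ncol(values))
  # keep at least one observation per channel so imputation stays total
  all_gone <- rowSums(!missing) == 0
  missing[all_gone, 1] <- FALSE
  values[missing] <- NA

  series <- process_series(sprintf("synthetic-%d", spec$seed), seq_len(n),
                           values, missing, sch, "item")
  truth <- structure(list(pre_means = pre_means, post_means = post_means,
                          shifted_factors = shifted, transition_day = td,
                          instability_window = spec$instability_window,
                          relapse = spec$relapse, seed = spec$seed,
                          spec = spec),
                     class = "synthetic_truth")
  list(series = series, truth = truth)
}

# regime-dependent category emission weights (rows sum to 1 after / sum)
category_emissions <- function() {
  codes <- setdiff(category_vocabulary(), "no_entry")
  w <- rbind(
    stable_pre  = c(0.28, 0.28, 0.18, 0.05, 0.02, 0.10, 0.05, 0.04),
    instability = c(0.10, 0.05, 0.05, 0.05, 0.01, 0.25, 0.45, 0.04),
    transition  = c(0.03, 0.03, 0.05, 0.20, 0.07, 0.15, 0.12, 0.35),
    stable_post = c(0.04, 0.04, 0.10, 0.28, 0.33, 0.15, 0.03, 0.03)
  )
  colnames(w) <- codes
  w / rowSums(w)
}

#' Simulate a coded diary-category timeline coupled to a planted process
#'
#' Emits one or two category codes per day from regime-dependent
#' distributions: the stable pre-transition regime favors the
#' pattern-stability codes, the instability window favors
#' `critical_instability` and `broadening_perspective`, days within
#' `kairos_halfwidth` of the transition have elevated `kairos` probability,
#' and the post-transition regime favors the improvement codes. Each day is
#' then independently replaced by `no_entry` with probability
#' `missing_rate_entries`.
#'
#' @param truth the `synthetic_truth` from [simulate_process()].
#' @param spec the generating [synthetic_spec()]; defaults to the one
#'   stored in `truth`.
#' @param kairos_halfwidth half-width (days) of the elevated-Kairos window
#'   around the transition day.
#' @return A `category_timeline`.
#' @export
simulate_categories <- function(truth, spec = truth$spec, kairos_halfwidth = 3) {
  if (!inherits(truth, "synthetic_truth")) stop("missing synthetic truth")
  set.seed(spec$seed + 104729L)  # decoupled from the process stream
  n <- spec$n_days
  em <- category_emissions()
  td <- truth$transition_day
  regime <- rep("stable_pre", n)
  if (!is.null(truth$instability_window))
    regime[truth$instability_window[1]:truth$instability_window[2]] <- "instability"
  if (!is.null(td)) {
    regime[td:n] <- "stable_post"
    kw <- max(1, td - kairos_halfwidth):min(n, td + kairos_halfwidth)
    regime[kw] <- "transition"
  }
  entries <- lapply(seq_len(n), function(d) {
    p <- em[regime[d], ]
    k <- 1 + stats::rbinom(1, 1, 0.3)
    sample(colnames(em), k, prob = p)
  })
  drop <- stats::runif(n) < spec$missing_rate_entries
  entries[drop] <- list("no_entry")
  structure(list(case_id = sprintf("synthetic-%d", spec$seed),
                 days = seq_len(n), entries = entries,
                 vocabulary = category_vocabulary()),
            class = "category_timeline")
}
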