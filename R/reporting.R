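#' Render a complexity resonance diagram
#'
#' Heatmap of the significance masks (white = not significant, gray/black =
#' DC above the 1 - alpha_gray / 1 - alpha_black surrogate quantiles) with
#' the per-day exceedance histogram on top, an optional diary-category band
#' below (white frames where there is no entry), and an optional vertical
#' magenta marker at the estimated transition day. A machine-readable CSV
#' companion of the plotted values is always written next to the image
#' (same path, `.csv` extension), so the figure is never the only record.
#'
#' @param field a [build_crd()] result.
#' @param timeline optional `category_timeline` for the lower band.
#' @param transition optional `transition_estimate` for the marker.
#' @param out output image path (`.png`).
#' @return Invisibly, a list with the image and companion CSV paths.
#' @export
render_crd <- function(field, timeline = NULL, transition = NULL, out) {
  if (is.null(field$gray_mask)) stop("run build_crd() on the field first")
  csv <- sub("\\.[A-Za-z]+$", ".csv", out)
  if (identical(csv, out)) csv <- paste0(out, ".csv")
  write_crd_csv(field, csv)

  nch <- length(field$channels)
  days <- field$days
  code <- matrix(0, nch, length(days))
  code[field$gray_mask] <- 1
  code[field$black_mask] <- 2

  grDevices::png(out, width = 1000, height = 760)
  on.exit(grDevices::dev.off(), add = TRUE)
  heights <- if (is.null(timeline)) c(1.2, 4) else c(1.2, 4, 2)
  graphics::layout(matrix(seq_along(heights), ncol = 1), heights = heights)
  op <- graphics::par(mar = c(0.5, 8, 2, 1))
  on.exit(graphics::par(op), add = TRUE)

  graphics::plot(days, field$column_histogram, type = "h", lwd = 3,
                 col = "gray30", xlab = "", ylab = "cells", xaxt = "n",
                 main = sprintf("Complexity resonance diagram: %s",
                                field$case_id %||% ""))
  graphics::par(mar = c(3, 8, 0.5, 1))
  graphics::image(days, seq_len(nch), t(code[rev(seq_len(nch)), , drop = FALSE]),
                  col = c("white", "gray60", "black"), zlim = c(0, 2),
                  xlab = "day", ylab = "", yaxt = "n", useRaster = TRUE)
  graphics::axis(2, at = seq_len(nch), labels = rev(field$channels),
                 las = 2, cex.axis = 0.6)
  if (!is.null(transition))
    graphics::abline(v = transition$transition_day, col = "magenta", lwd = 2)

  if (!is.null(timeline)) {
    codes <- setdiff(category_vocabulary(), "no_entry")
    band <- matrix(0, length(codes), length(days),
                   dimnames = list(codes, NULL))
    for (i in seq_along(timeline$days)) {
      d <- match(timeline$days[i], days)
      if (is.na(d)) next
      e <- timeline$entries[[i]]
      if (identical(e, "no_entry")) band[, d] <- NA else band[e, d] <- 1
    }
    graphics::par(mar = c(3, 8, 0.5, 1))
    graphics::image(days, seq_along(codes),
                    t(band[rev(seq_along(codes)), , drop = FALSE]),
                    col = c("gray92", "steelblue4"), zlim = c(0, 1),
                    xlab = "day", ylab = "", yaxt = "n", useRaster = TRUE)
    graphics::axis(2, at = seq_along(codes), labels = rev(codes), las = 2,
                   cex.axis = 0.6)
    graphics::box(col = "white")  # no-entry days stay white-framed
    if (!is.null(transition))
      graphics::abline(v = transition$transition_day, col = "magenta", lwd = 2)
  }
  invisible(list(image = out, csv = csv,
                 marker_day = if (is.null(transition)) NA_integer_
                              else transition$transition_day))
}

#' Transition probability band
#'
#' Computes (and optionally renders) the 1 x n_days intensity band of the
#' pooled, confidence-weighted change-point histogram smoothed with a
#' triangular kernel of half-width `mode_window_w`, normalized to maximum
#' 1. The maximum intensity sits at the estimated transition day. A CSV
#' companion (`day,intensity`) is written next to the image.
#'
#' @param estimate a `transition_estimate`.
#' @param n_days series length in days.
#' @param out output image path (`.png`), or `NULL` to skip rendering.
#' @return Invisibly, a list with `band` (numeric vector over days),
#'   `image`, `csv`.
#' @export
render_transition_band <- function(estimate, n_days, out = NULL) {
  w <- estimate$mode_window_w %||% 3
  hist <- estimate$pooled_histogram
  days <- as.integer(names(hist))
  band <- vapply(seq_len(n_days), function(d) {
    k <- pmax(0, (w + 1 - abs(d - days)) / (w + 1))
    sum(k * hist)
  }, numeric(1))
  if (max(band) > 0) band <- band / max(band)

  csv <- image <- NULL
  if (!is.null(out)) {
    csv <- sub("\\.[A-Za-z]+$", ".csv", out)
    if (identical(csv, out)) csv <- paste0(out, ".csv")
    utils::write.csv(data.frame(day = seq_len(n_days), intensity = band),
                     csv, row.names = FALSE)
    grDevices::png(out, width = 1000, height = 180)
    on.exit(grDevices::dev.off(), add = TRUE)
    op <- graphics::par(mar = c(3, 4, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
    graphics::image(seq_len(n_days), 1, matrix(band, ncol = 1),
                    col = grDevices::hcl.colors(64, "Blue-Yellow"),
                    xlab = "day", yaxt = "n", ylab = "",
                    main = "Pattern transition probability band",
                    useRaster = TRUE)
    graphics::abline(v = estimate$transition_day, col = "magenta", lwd = 2)
    image <- out
  }
  invisible(list(band = band, image = image, csv = csv))
}

#' Category-indicator alignment statistics
#'
#' Quantifies how the coded diary categories line up with the quantitative
#' indicators: for each category group and each indicator window (days
#' inside a significant-DC instability period; days within `w` of the
#' estimated transition), a 2x2 contingency table of days, an odds ratio
#' (Haldane-corrected), and a permutation p value from circular shifts of
#' the timeline. Circular shifts preserve the run structure of diary
#' phases, which an i.i.d. shuffle would destroy.
#'
#' @param timeline a `category_timeline`.
#' @param periods data frame from [instability_periods()] (may have 0 rows).
#' @param estimate a `transition_estimate`, or `NULL`.
#' @param w half-width (days) of the transition indicator window.
#' @param n_perm number of circular shifts.
#' @param seed integer seed.
#' @return A data frame with one row per (group, indicator): columns
#'   `group`, `indicator`, `both`, `group_only`, `indicator_only`,
#'   `neither`, `odds_ratio`, `permutation_p`.
#' @export
align_categories <- function(timeline, periods = NULL, estimate = NULL,
                             w = 3, n_perm = 1000, seed = 1L) {
  if (is.null(periods) && is.null(estimate))
    stop("need at least one quantitative indicator")
  n <- length(timeline$days)
  if (all(vapply(timeline$entries, function(e) identical(e, "no_entry"), TRUE)))
    stop("timeline has no entries at all")
  set.seed(seed)

  indicators <- list()
  if (!is.null(periods) && nrow(periods) > 0) {
    inside <- rep(FALSE, n)
    for (r in seq_len(nrow(periods)))
      inside[timeline$days >= periods$start_day[r] &
             timeline$days <= periods$end_day[r]] <- TRUE
    indicators$instability_periods <- inside
  } else if (!is.null(periods)) {
    indicators$instability_periods <- rep(FALSE, n)
  }
  if (!is.null(estimate))
    indicators$transition_window <-
      abs(timeline$days - estimate$transition_day) <= w

  groups <- category_groups()
  present <- lapply(groups, function(codes)
    vapply(timeline$entries, function(e) any(codes %in% e), TRUE))

  shifts <- sample.int(n, n_perm, replace = TRUE) - 1L
  out <- do.call(rbind, lapply(names(groups), function(g) {
    gp <- present[[g]]
    do.call(rbind, lapply(names(indicators), function(ind) {
      iv <- indicators[[ind]]
      a <- sum(gp & iv); b <- sum(gp & !iv)
      c_ <- sum(!gp & iv); d <- sum(!gp & !iv)
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
      obs <- a
      r <- 0L
      for (s in shifts) {
        gs <- gp[((seq_len(n) - 1L + s) %% n) + 1L]
        if (sum(gs & iv) >= obs) r <- r + 1L
      }
      data.frame(group = g, indicator = ind, both = a, group_only = b,
                 indicator_only = c_, neither = d, odds_ratio = or,
                 permutation_p = (r + 1) / (n_perm + 1),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Export a full analysis report bundle
#'
#' Writes a directory with a JSON summary (`summary.json`: transition day,
#' probability, surrogate p, instability periods), the CSV companions
#' (DC/CRD values, pooled change points), the rendered diagrams, and a
#' reproducibility manifest with the full configuration and seeds. Reruns
#' from the same inputs produce byte-identical JSON.
#'
#' @param series the analyzed [process_series()].
#' @param field a [build_crd()] result.
#' @param estimate a `transition_estimate`.
#' @param periods data frame from [instability_periods()].
#' @param alignment optional [align_categories()] result.
#' @param timeline optional `category_timeline` (rendered into the CRD).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(series, field, estimate, periods, alignment = NULL,
                          timeline = NULL, out_dir) {
  if (missing(series) || missing(field) || missing(estimate) ||
      missing(periods))
    stop("series, field, estimate and periods are all required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  summary <- list(
    case_id = series$case_id,
    n_days = length(series$days),
    transition_day = estimate$transition_day,
    probability = estimate$probability,
    surrogate_p = estimate$surrogate_p,
    periods = periods
  )
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  pts <- data.frame(
    channel = rep(names(estimate$per_channel %||% list(pooled = NULL)),
                  each = 6)[seq_along(estimate$points)],
    kind = vapply(estimate$points, function(p) p$kind, character(1)),
    day = vapply(estimate$points, function(p) as.integer(p$day), integer(1)),
    confidence = vapply(estimate$points, function(p) p$confidence, numeric(1)),
    degenerate = vapply(estimate$points, function(p) p$degenerate, logical(1))
  )
  paths$points <- file.path(out_dir, "change_points.csv")
  utils::write.csv(pts, paths$points, row.names = FALSE, na = "")

  paths$crd <- file.path(out_dir, "crd.png")
  render_crd(field, timeline = timeline, transition = estimate,
             out = paths$crd)
  paths$band <- file.path(out_dir, "transition_band.png")
  render_transition_band(estimate, length(series$days), out = paths$band)

  if (!is.null(alignment)) {
    paths$alignment <- file.path(out_dir, "alignment.csv")
    utils::write.csv(alignment, paths$alignment, row.names = FALSE)
  }

  cfg <- estimate$config
  manifest <- list(
    package = "patternshift",
    version = as.character(utils::packageVersion("patternshift")),
    case_id = series$case_id,
    level = series$level,
    config = if (is.null(cfg)) NULL else list(
      level = cfg$level, pooling = cfg$pooling,
      mode_window_w = cfg$mode_window_w, n_surrogates = cfg$n_surrogates,
      cp_boot = cfg$cp_boot, seed = cfg$seed,
      complexity = unclass(cfg$complexity),
      recurrence = unclass(cfg$recurrence), tfd_window = cfg$tfd_window)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}
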