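mk_estimate <- function(days = c(65, 65, 64, 66, 63, 20), conf = 1) {
  pts <- lapply(days, function(d)
    structure(list(kind = "mean", day = as.integer(d), score = 1,
                   confidence = conf, degenerate = FALSE),
              class = "change_point"))
  pool_and_estimate(pts, ptda_config(mode_window_w = 3))
}

test_that("the transition band peaks at the pooled transition day", {
  est <- mk_estimate()
  band <- render_transition_band(est, 90)$band
  expect_length(band, 90)
  expect_equal(which.max(band), 65)
  expect_equal(max(band), 1)
  expect_true(all(band >= 0))

  # a single unanimous point gives a single-bin peak at full intensity
  est1 <- mk_estimate(days = 40)
  b1 <- render_transition_band(est1, 90)$band
  expect_equal(which.max(b1), 40)
  expect_equal(sum(b1 == 1), 1)
})

test_that("render_crd writes the image plus a faithful CSV companion", {
  set.seed(6)
  sch <- tpq_schema(list(A = c("a1", "a2")))
  v <- matrix(runif(100, 0, 100), 2, dimnames = list(c("a1", "a2"), NULL))
  sr <- make_series(v, sch)
  p <- complexity_params(n_surrogates = 100, seed = 6)
  field <- build_crd(dc_series(sr, p), surrogate_null(sr, p))
  tl <- load_categories(data.frame(day = 10, category_code = "kairos"), sr)
  est <- mk_estimate(days = rep(30, 6))

  out <- withr::local_tempfile(fileext = ".png")
  res <- render_crd(field, timeline = tl, transition = est, out = out)
  expect_true(file.exists(res$image))
  expect_true(file.exists(res$csv))
  expect_equal(res$marker_day, est$transition_day)

  back <- read.csv(res$csv)
  expect_equal(nrow(back), 2 * 50)
  got <- back$dc[back$channel == "a1"]
  expect_equal(got, as.vector(field$values["a1", ]))
  hist_csv <- tapply(back$gray | back$black, back$day, sum, na.rm = TRUE)
  expect_equal(as.vector(hist_csv), as.vector(field$column_histogram))

  # zero significant cells -> all-zero histogram in the companion
  vc <- matrix(50, 2, 50, dimnames = list(c("a1", "a2"), NULL))
  src <- make_series(vc, sch)
  fc <- build_crd(dc_series(src, p), surrogate_null(src, p))
  out2 <- withr::local_tempfile(fileext = ".png")
  res2 <- render_crd(fc, out = out2)
  back2 <- read.csv(res2$csv)
  expect_equal(sum(back2$gray, na.rm = TRUE), 0)
})

test_that("category alignment counts partition the days and detect planted coupling", {
  spec <- synthetic_spec(transition_day = NULL, instability_window = c(30, 45),
                         seed = 21)
  sim <- simulate_process(spec)
  tl <- simulate_categories(sim$truth)
  periods <- data.frame(channel = "(case mean)", start_day = 30, end_day = 45,
                        mean_dc = 0.2, p_value = 0.001)
  al <- align_categories(tl, periods = periods, estimate = NULL,
                         n_perm = 300, seed = 2)
  expect_true(all(al$both + al$group_only + al$indicator_only + al$neither == 90))
  expect_true(all(al$permutation_p > 0 & al$permutation_p <= 1))

  # Power note: the circular-shift null preserves the run structure of the
  # planted in-window cluster, so shifting the cluster across the window
  # loses only ~1 overlap per day of shift; the attainable p is floored
  # near (window span - observed overlap) / n_days. At these study
  # conditions roughly half of the seeds clear 0.05; all seeds must beat
  # the uncoupled null stochastically.
  coupled <- vapply(1:30, function(s) {
    sim_s <- simulate_process(synthetic_spec(transition_day = NULL,
                                             instability_window = c(30, 45),
                                             seed = s))
    tl_s <- simulate_categories(sim_s$truth)
    al_s <- align_categories(tl_s, periods = periods, n_perm = 200, seed = s)
    al_s$permutation_p[al_s$group == "critical_instability"]
  }, numeric(1))
  expect_gte(mean(coupled < 0.05), 0.3)

  uncoupled <- vapply(1:30, function(s) {
    sim <- simulate_process(synthetic_spec(transition_day = NULL, seed = s))
    tl <- simulate_categories(sim$truth)  # no planted window
    al <- align_categories(tl, periods = periods, n_perm = 200, seed = s)
    al$permutation_p[al$group == "critical_instability"]
  }, numeric(1))
  expect_lt(median(coupled), median(uncoupled))

  # validity under the null: conservative, never anti-conservative
  expect_lte(mean(uncoupled < 0.05), 0.1)
  expect_gt(mean(uncoupled), 0.25)
})

test_that("export_report writes a reproducible bundle with the summary contract", {
  sim <- simulate_process(synthetic_spec(seed = 31))
  sr <- locf_impute(sim$series)
  p <- complexity_params(n_surrogates = 100, seed = 31)
  field <- build_crd(dc_series(sr, p), surrogate_null(sr, p))
  cfg <- ptda_config(cp_boot = 50, n_surrogates = 100, seed = 31,
                     complexity = p)
  est <- run_ptda(sr, cfg, surrogate = FALSE)
  periods <- data.frame(channel = character(), start_day = integer(),
                        end_day = integer(), mean_dc = numeric(),
                        p_value = numeric())

  dir1 <- withr::local_tempdir()
  paths <- export_report(sr, field, est, periods, out_dir = dir1)
  summ <- jsonlite::read_json(paths$summary)
  expect_true(all(c("transition_day", "probability", "surrogate_p", "periods")
                  %in% names(summ)))
  expect_equal(summ$transition_day, est$transition_day)
  expect_true(file.exists(paths$manifest))
  expect_true(file.exists(paths$points))

  # byte-identical summary on rerun
  dir2 <- withr::local_tempdir()
  export_report(sr, field, est, periods, out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "summary.json")),
                   readLines(file.path(dir2, "summary.json")))

  expect_error(export_report(sr, field, estimate = est, out_dir = dir1),
               "required")
})
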