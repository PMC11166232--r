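test_that("closed-form windows give the known F, D and DC values", {
  alt <- c(0, 100, 0, 100, 0, 100, 0)
  expect_equal(fluctuation_intensity(alt, 0, 100), 1, tolerance = 1e-12)
  expect_equal(distribution_measure(alt, 0, 100), 0.75, tolerance = 1e-12)

  ramp <- seq(0, 100, length.out = 7)
  expect_equal(fluctuation_intensity(ramp, 0, 100), (100 / 6) / 600,
               tolerance = 1e-12)
  expect_equal(distribution_measure(ramp, 0, 100), 1, tolerance = 1e-12)

  const <- rep(50, 7)
  expect_equal(fluctuation_intensity(const, 0, 100), 0)
  expect_equal(distribution_measure(const, 0, 100), 0)
})

test_that("F and D match the brute-force oracles on every length-5 window over {0,50,100}", {
  grid <- expand.grid(rep(list(c(0, 50, 100)), 5))
  for (r in seq_len(nrow(grid))) {
    w <- as.numeric(grid[r, ])
    expect_equal(fluctuation_intensity(w, 0, 100, 5), oracle_F(w),
                 tolerance = 1e-12)
    expect_equal(distribution_measure(w, 0, 100, 5), oracle_D(w),
                 tolerance = 1e-12)
  }
})

test_that("F, D, DC lie in [0,1], vanish only on constant windows, and are affine invariant", {
  set.seed(11)
  for (i in 1:200) {
    w <- runif(7, 0, 100)
    F <- fluctuation_intensity(w, 0, 100)
    D <- distribution_measure(w, 0, 100)
    expect_true(F >= 0 && F <= 1 && D >= 0 && D <= 1)
    expect_gt(F * D, 0)  # continuous draws are never constant
    # rescale values and bounds together
    a <- runif(1, 0.1, 3)
    b <- runif(1, -50, 50)
    expect_equal(fluctuation_intensity(a * w + b, a * 0 + b, a * 100 + b), F,
                 tolerance = 1e-9)
    expect_equal(distribution_measure(a * w + b, a * 0 + b, a * 100 + b), D,
                 tolerance = 1e-9)
  }
})

test_that("D is permutation invariant while F is order sensitive", {
  alt <- c(0, 100, 0, 100, 0, 100, 0)
  srt <- sort(alt)
  expect_equal(distribution_measure(srt), distribution_measure(alt))
  expect_false(isTRUE(all.equal(fluctuation_intensity(srt),
                                fluctuation_intensity(alt))))
})

test_that("dc_series applies the right-aligned window with NA padding", {
  sch <- tpq_schema(list(A = "a1", B = "b1"))
  v <- rbind(a1 = rep(50, 30), b1 = rep(c(0, 100), 15))
  field <- dc_series(make_series(v, sch))
  expect_true(all(is.na(field$values[, 1:6])))
  expect_equal(unname(field$values["a1", 7:30]), rep(0, 24))
  expect_equal(unname(field$values["b1", 7:30]), rep(0.75, 24))

  v79 <- matrix(runif(79, 0, 100), 1, dimnames = list("a1", NULL))
  f79 <- dc_series(make_series(v79, tpq_schema(list(A = "a1"))))
  expect_equal(sum(!is.na(f79$values)), 73)
})

test_that("surrogate null is deterministic under a fixed seed and degenerate for constants", {
  sch <- tpq_schema(list(A = "a1"))
  v <- matrix(runif(40, 0, 100), 1, dimnames = list("a1", NULL))
  sr <- make_series(v, sch)
  p <- complexity_params(n_surrogates = 100, seed = 5)
  n1 <- surrogate_null(sr, p)
  n2 <- surrogate_null(sr, p)
  expect_identical(n1$q_gray, n2$q_gray)
  expect_identical(n1$samples, n2$samples)

  vc <- matrix(50, 1, 40, dimnames = list("a1", NULL))
  nc <- surrogate_null(make_series(vc, sch), p)
  expect_equal(unname(nc$mean), 0)
  expect_equal(unname(nc$sd), 0)
})

test_that("the resonance diagram masks nest and the histogram counts flagged cells", {
  set.seed(3)
  sch <- tpq_schema(list(A = c("a1", "a2")))
  v <- matrix(runif(120, 0, 100), 2, dimnames = list(c("a1", "a2"), NULL))
  sr <- make_series(v, sch)
  p <- complexity_params(n_surrogates = 150, seed = 2)
  field <- build_crd(dc_series(sr, p), surrogate_null(sr, p))
  expect_true(all(field$gray_mask[field$black_mask], na.rm = TRUE))
  expect_equal(field$column_histogram,
               colSums(field$gray_mask | field$black_mask, na.rm = TRUE))

  # constant series: no significant cells anywhere
  vc <- matrix(50, 2, 60, dimnames = list(c("a1", "a2"), NULL))
  src <- make_series(vc, sch)
  fc <- build_crd(dc_series(src, p), surrogate_null(src, p))
  expect_equal(sum(fc$column_histogram), 0)
  expect_equal(unname(fc$z[, 60]), c(0, 0))
})

test_that("instability periods bridge short gaps and carry Monte-Carlo p values", {
  set.seed(9)
  sch <- tpq_schema(list(A = c("a1", "a2", "a3")))
  n <- 70
  mk <- function(gain_window) {
    v <- t(sapply(1:3, function(i) {
      x <- rnorm(n, 50, 4)
      x[gain_window] <- 50 + rnorm(length(gain_window), 0, 12) +
        6 * (-1)^seq_along(gain_window)
      pmin(pmax(x, 0), 100)
    }))
    rownames(v) <- c("a1", "a2", "a3")
    make_series(v, sch)
  }
  sr <- mk(25:40)
  p <- complexity_params(n_surrogates = 200, seed = 31)
  field <- dc_series(sr, p)
  null <- surrogate_null(sr, p)
  per <- instability_periods(field, null, "case_mean", alpha = 0.05)
  expect_true(nrow(per) >= 1)
  # the detected period overlaps the planted window
  expect_true(any(per$start_day <= 40 & per$end_day >= 25))
  expect_true(all(per$p_value > 0 & per$p_value <= 1))

  # gap bridging: flagged runs {3,4,5} and {7} merge under max_gap = 1
  runs <- patternshift:::merge_runs(c(3, 4, 5, 7), max_gap = 1)
  expect_equal(runs, list(c(3, 7)))
  expect_equal(patternshift:::merge_runs(c(3, 4, 5, 8), max_gap = 1),
               list(c(3, 5), c(8, 8)))
})
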