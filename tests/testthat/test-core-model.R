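test_that("schema constructor enforces the item-factor mapping invariants", {
  sch <- tpq_schema(list(A = c("a1", "a2"), B = "b1"), 0, 100)
  expect_equal(sch$factor_of[["a2"]], "A")
  expect_equal(sch$factors, c("A", "B"))
  expect_error(tpq_schema(list(A = "x", B = "x")), "exactly one factor")
  expect_error(tpq_schema(list(A = "x"), 10, 10), "strictly less")
  expect_error(tpq_schema(list(A = character(0), B = "b")), "zero items")
})

test_that("default schema has 43 items under the 7 published factor labels", {
  sch <- tpq43_schema()
  expect_length(sch$items, 43)
  expect_equal(sch$factors,
               c("WPE", "RFP", "TAS", "EPI", "ICP", "MOT", "MSC"))
  expect_equal(sch$scale_min, 0)
  expect_equal(sch$scale_max, 100)
})

test_that("load_process builds a contiguous grid and flags gaps as missing", {
  sch <- tpq_schema(list(A = "a1", B = "b1"))
  tab <- data.frame(case_id = "c1", day = rep(1:3, each = 2),
                    item_id = c("a1", "b1"), value = c(40, 60))
  sr <- load_process(tab, sch)
  expect_equal(dim(sr$values), c(2L, 3L))
  expect_false(any(sr$missing))

  # a skipped day is inserted as missing for every channel
  tab2 <- data.frame(case_id = "c1", day = c(1, 3), item_id = "a1",
                     value = c(5, 9))
  sr2 <- load_process(tab2, tpq_schema(list(A = "a1")))
  expect_equal(length(sr2$days), 3)
  expect_true(sr2$missing[1, 2])
  expect_equal(sr2$values[1, c(1, 3)], c(5, 9), ignore_attr = TRUE)

  # blank strings are missing
  tab3 <- data.frame(case_id = "c1", day = 1:2, item_id = "a1",
                     value = c("41.5", ""))
  sr3 <- load_process(tab3, tpq_schema(list(A = "a1")))
  expect_true(sr3$missing[1, 2])
  expect_equal(sr3$values[1, 1], 41.5, ignore_attr = TRUE)
})

test_that("load_process rejects malformed records", {
  sch <- tpq_schema(list(A = "a1"))
  base <- data.frame(case_id = "c", day = 1:2, item_id = "a1", value = c(1, 2))
  expect_error(load_process(transform(base, item_id = "zz"), sch), "unknown item")
  expect_error(load_process(transform(base, value = c(50, 101)), sch),
               "outside")
  expect_error(load_process(rbind(base, base[1, ]), sch), "duplicate")
  expect_error(load_process(base[1, ], sch), "fewer than 2 days")
})

test_that("locf imputation carries the previous day forward and backfills leading gaps", {
  sch <- tpq_schema(list(A = "a1", B = "b1"))
  v <- rbind(a1 = c(10, NA, NA, 30), b1 = c(NA, 5, NA, NA))
  sr <- process_series("c", 1:4, v, is.na(v), sch)
  imp <- locf_impute(sr)
  expect_equal(imp$values["a1", ], c(10, 10, 10, 30))
  expect_equal(imp$values["b1", ], c(5, 5, 5, 5))
  expect_false(any(imp$missing))

  # idempotent, and observed values untouched
  imp2 <- locf_impute(imp)
  expect_identical(imp2$values, imp$values)

  v_none <- rbind(a1 = c(NA_real_, NA_real_))
  sr_none <- process_series("c", 1:2, v_none, is.na(v_none),
                            tpq_schema(list(A = "a1")))
  expect_error(locf_impute(sr_none), "zero observed")
})

test_that("locf imputation on random gap patterns stays in range and idempotent", {
  set.seed(42)
  sch <- tpq_schema(list(A = c("a1", "a2")))
  for (rep in 1:20) {
    v <- matrix(runif(40, 0, 100), 2, dimnames = list(c("a1", "a2"), NULL))
    holes <- matrix(runif(40) < 0.3, 2, 20)
    holes[, 1][rowSums(!holes) == 0] <- FALSE
    v[holes] <- NA
    sr <- process_series("c", 1:20, v, is.na(v), sch)
    imp <- locf_impute(sr)
    expect_false(anyNA(imp$values))
    expect_true(all(imp$values >= 0 & imp$values <= 100))
    obs <- !sr$missing
    expect_equal(imp$values[obs], sr$values[obs])
    expect_identical(locf_impute(imp)$values, imp$values)
  }
})

test_that("factor scores are unweighted item means and preserve structure", {
  sch <- tpq_schema(list(A = c("a1", "a2"), B = "b1"))
  v <- rbind(a1 = c(40, 0), a2 = c(60, 100), b1 = c(7, 9))
  fs <- factor_scores(make_series(v, sch))
  expect_equal(fs$level, "factor")
  expect_equal(fs$values["A", ], c(50, 50))
  expect_equal(fs$values["B", ], c(7, 9))  # single-item factor is the identity

  # identical items within a factor reproduce the common series
  v2 <- rbind(a1 = c(1, 2, 3), a2 = c(1, 2, 3), b1 = c(9, 9, 9))
  fs2 <- factor_scores(make_series(v2, sch))
  expect_equal(fs2$values["A", ], c(1, 2, 3))

  expect_error(factor_scores(fs), "item-level")
})

test_that("the default schema aggregates 43 items to exactly 7 factor channels", {
  sch <- tpq43_schema()
  v <- matrix(50, 43, 10, dimnames = list(sch$items, NULL))
  fs <- factor_scores(make_series(v, sch))
  expect_equal(nrow(fs$values), 7)
  expect_equal(rownames(fs$values), sch$factors)
})

test_that("long CSV round-trips bit-identically through write and load", {
  set.seed(7)
  sch <- tpq_schema(list(A = c("a1", "a2"), B = "b1"))
  v <- matrix(round(runif(30, 0, 100), 6), 3,
              dimnames = list(c("a1", "a2", "b1"), NULL))
  v[2, 4] <- NA
  sr <- process_series("case9", 1:10, v, is.na(v), sch)
  path <- withr::local_tempfile(fileext = ".csv")
  write_process_csv(sr, path)
  back <- load_process(path, sch)
  expect_identical(back$values, sr$values)
  expect_identical(back$missing, sr$missing)
  expect_identical(back$days, sr$days)
})

test_that("category timelines respect the vocabulary and no-entry semantics", {
  sch <- tpq_schema(list(A = "a1"))
  v <- matrix(50, 1, 79, dimnames = list("a1", NULL))
  sr <- make_series(v, sch)
  tl <- load_categories(data.frame(day = 22, category_code = "kairos"), sr)
  expect_equal(tl$entries[[22]], "kairos")
  expect_true(all(vapply(tl$entries[-22], identical, TRUE, y = "no_entry")))

  empty <- load_categories(data.frame(day = integer(), category_code = character()), sr)
  expect_true(all(vapply(empty$entries, identical, TRUE, y = "no_entry")))

  expect_error(load_categories(data.frame(day = 1, category_code = "hopeful"), sr),
               "unknown category")
  expect_error(load_categories(data.frame(day = 99, category_code = "kairos"), sr),
               "outside")
  expect_error(load_categories(
    data.frame(day = c(3, 3), category_code = c("no_entry", "kairos")), sr),
    "co-occur")

  # csv round trip drops and reconstructs no_entry days
  path <- withr::local_tempfile(fileext = ".csv")
  write_categories_csv(tl, path)
  back <- load_categories(path, sr)
  expect_identical(back$entries, tl$entries)
})
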