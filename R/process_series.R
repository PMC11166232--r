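#' Multichannel daily process series
#'
#' A `process_series` holds one case's daily ratings as a channels x days
#' matrix together with a missingness mask, the questionnaire schema and the
#' aggregation level (`"item"` or `"factor"`). Days are consecutive integers.
#'
#' @param case_id case identifier.
#' @param days integer vector of consecutive day indices.
#' @param values numeric channels x days matrix; rows named by channel.
#' @param missing logical matrix of the same shape, `TRUE` where the value
#'   is missing.
#' @param schema a [tpq_schema()].
#' @param level `"item"` or `"factor"`.
#' @return An object of class `process_series`.
#' @export
process_series <- function(case_id, days, values, missing, schema,
                           level = c("item", "factor")) {
  level <- match.arg(level)
  days <- as.integer(days)
  if (length(days) < 2) stop("a process series needs at least 2 days")
  if (any(diff(days) != 1L)) stop("days must be consecutive (step 1)")
  if (!is.matrix(values) || is.null(rownames(values)))
    stop("`values` must be a matrix with channel rownames")
  if (!identical(dim(values), dim(missing)))
    stop("`values` and `missing` must have identical dimensions")
  if (ncol(values) != length(days)) stop("column count must equal number of days")
  obs <- values[!missing]
  if (any(!is.na(obs) & (obs < schema$scale_min | obs > schema$scale_max)))
    stop("observed values outside scale bounds [",
         schema$scale_min, ", ", schema$scale_max, "]")
  structure(
    list(case_id = as.character(case_id), days = days,
         channels = rownames(values), values = values,
         missing = missing, schema = schema, level = level),
    class = "process_series"
  )
}

#' Load a long-format table into a process series
#'
#' Reads records `(case_id, day, item_id, value)` -- a data frame or a CSV
#' path (blank value = missing) -- into an item-level [process_series()].
#' Days absent from the table inside the observed day range are inserted as
#' missing, so the day grid is always contiguous.
#'
#' @param table a data frame with columns `case_id, day, item_id, value`,
#'   or the path of a CSV file with that header.
#' @param schema a [tpq_schema()]; defaults to [tpq43_schema()].
#' @return An item-level `process_series` with `missing` TRUE wherever the
#'   value was blank or the (day, item) record absent.
#' @examples
#' tab <- data.frame(case_id = "c1", day = rep(1:3, each = 2),
#'                   item_id = c("a1", "b1"), value = c(40, 60))
#' sch <- tpq_schema(list(A = "a1", B = "b1"))
#' sr <- load_process(tab, sch)
#' @export
load_process <- function(table, schema = tpq43_schema()) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.csv(table, stringsAsFactors = FALSE,
                             colClasses = c(value = "character"))
  need <- c("case_id", "day", "item_id", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (nrow(table) == 0L) stop("empty record table")
  if (length(unique(table$case_id)) > 1L)
    stop("load_process handles one case at a time")

  bad <- setdiff(unique(table$item_id), schema$items)
  if (length(bad)) stop("unknown item id(s): ", paste(bad, collapse = ", "))
  val <- table$value
  if (is.character(val)) {
    val <- trimws(val)
    val[val == ""] <- NA
    val <- as.numeric(val)
  }
  day <- as.integer(table$day)
  if (anyDuplicated(paste(day, table$item_id)))
    stop("duplicate (day, item) record")
  out_of_range <- !is.na(val) & (val < schema$scale_min | val > schema$scale_max)
  if (any(out_of_range))
    stop("value outside [", schema$scale_min, ", ", schema$scale_max,
         "] at day ", day[which(out_of_range)[1]])

  days <- seq(min(day), max(day))
  if (length(days) < 2) stop("fewer than 2 days")
  present <- schema$items[schema$items %in% unique(table$item_id)]
  values <- matrix(NA_real_, nrow = length(present), ncol = length(days),
                   dimnames = list(present, NULL))
  values[cbind(match(table$item_id, present), match(day, days))] <- val
  missing <- is.na(values)
  process_series(table$case_id[1], days, values, missing, schema, "item")
}

#' Write a process series as a long-format CSV
#'
#' Inverse of [load_process()]: emits `case_id, day, item_id, value` rows,
#' with blank values where the series is missing.
#'
#' @param series a [process_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_process_csv <- function(series, path) {
  value <- sprintf("%.17g", as.vector(series$values))  # full double precision
  value[as.vector(series$missing)] <- ""
  long <- data.frame(
    case_id = series$case_id,
    day = rep(series$days, each = length(series$channels)),
    item_id = rep(series$channels, times = length(series$days)),
    value = value,
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Last-observation-carried-forward imputation
#'
#' Replaces each missing value with the most recent prior observation in the
#' same channel. Leading gaps (no prior observation) are filled with the
#' first observed value. The operation is idempotent and never touches an
#' observed value.
#'
#' @param series a [process_series()].
#' @return The series with `missing` all `FALSE`.
#' @examples
#' sch <- tpq_schema(list(A = "a1"))
#' v <- matrix(c(10, NA, NA, 30), 1, dimnames = list("a1", NULL))
#' sr <- process_series("c", 1:4, v, is.na(v), sch)
#' locf_impute(sr)$values  # 10 10 10 30
#' @export
locf_impute <- function(series) {
  v <- series$values
  v[series$missing] <- NA
  none <- rowSums(!is.na(v)) == 0
  if (any(none))
    stop("channel(s) with zero observed values: ",
         paste(series$channels[none], collapse = ", "))
  for (i in seq_len(nrow(v))) {
    x <- zoo::na.locf(v[i, ], na.rm = FALSE)
    v[i, ] <- zoo::na.locf(x, fromLast = TRUE, na.rm = FALSE)  # leading gaps
  }
  series$values <- v
  series$missing[] <- FALSE
  series
}

#' Aggregate an item-level series to factor scores
#'
#' Each factor's daily score is the unweighted arithmetic mean of its items'
#' values on that day (the instrument's scoring rule is not published; the
#' plain mean preserves the scale bounds).
#'
#' @param series a fully imputed item-level [process_series()].
#' @return A factor-level `process_series` with one channel per factor.
#' @export
factor_scores <- function(series) {
  if (series$level != "item") stop("factor_scores requires an item-level series")
  if (any(series$missing)) stop("impute the series first (see locf_impute)")
  sch <- series$schema
  present <- sch$factors[sch$factors %in% sch$factor_of[series$channels]]
  fac <- factor(sch$factor_of[series$channels], levels = present)
  vals <- rowsum(series$values, fac, reorder = FALSE)
  vals <- vals / as.vector(table(fac)[rownames(vals)])
  vals <- vals[present, , drop = FALSE]
  process_series(series$case_id, series$days, vals,
                 matrix(FALSE, nrow(vals), ncol(vals)), sch, "factor")
}

#' @export
print.process_series <- function(x, ...) {
  cat(sprintf("process_series '%s': %d %s channel(s) x %d days (%.1f%% missing)\n",
              x$case_id, length(x$channels), x$level, length(x$days),
              100 * mean(x$missing)))
  invisible(x)
}
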