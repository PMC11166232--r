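#' Diary category vocabulary
#'
#' The fixed set of coded diary subcategories: three kinds of perceived
#' pattern stability (feeling helpless in front of a problem attractor,
#' noticing a problem attractor, regaining control), two kinds of noticed
#' improvement (a single moment vs. a lasting one), broadening the
#' perspective, critical instability, Kairos (the felt right moment for
#' change), plus the sentinel `no_entry` for days without a diary entry.
#'
#' @return Character vector of the nine category codes.
#' @export
category_vocabulary <- function() {
  c("feeling_helpless", "noticing_attractor", "regaining_control",
    "moment_of_improvement", "lasting_improvement", "broadening_perspective",
    "critical_instability", "kairos", "no_entry")
}

#' Parent groupings of the diary subcategories
#'
#' `stability` collects the three pattern-stability codes and `improvement`
#' the two improvement codes; the remaining codes are their own group.
#'
#' @return Named list of character vectors of subcategory codes.
#' @export
category_groups <- function() {
  list(
    stability = c("feeling_helpless", "noticing_attractor", "regaining_control"),
    improvement = c("moment_of_improvement", "lasting_improvement"),
    broadening_perspective = "broadening_perspective",
    critical_instability = "critical_instability",
    kairos = "kairos"
  )
}

#' Load a coded diary-category timeline
#'
#' Reads `(day, category_code)` records -- a data frame or a CSV path --
#' against the day range of a process series. Days without any record are
#' coded `no_entry`.
#'
#' @param table data frame with columns `day` and `category_code`, or a CSV
#'   path. May be empty (all days become `no_entry`).
#' @param series the [process_series()] whose day range the timeline covers.
#' @return An object of class `category_timeline`: `case_id`, `days`, and
#'   `entries`, a list (one character vector of codes per day).
#' @export
load_categories <- function(table, series) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  if (!all(c("day", "category_code") %in% names(table)))
    stop("table must have columns day, category_code")
  vocab <- category_vocabulary()
  bad <- setdiff(unique(table$category_code), vocab)
  if (length(bad)) stop("unknown category code(s): ", paste(bad, collapse = ", "))
  day <- as.integer(table$day)
  if (length(day) && (min(day) < min(series$days) || max(day) > max(series$days)))
    stop("category day outside the series' day range")
  entries <- lapply(series$days, function(d) {
    codes <- unique(table$category_code[day == d])
    if (length(codes) == 0L) return("no_entry")
    if ("no_entry" %in% codes && length(codes) > 1L)
      stop("no_entry cannot co-occur with another code (day ", d, ")")
    codes
  })
  structure(list(case_id = series$case_id, days = series$days,
                 entries = entries, vocabulary = vocab),
            class = "category_timeline")
}

#' Write a category timeline as CSV
#'
#' Emits `day, category_code` rows; `no_entry` days are omitted (they are
#' the absence of a record and are reconstructed by [load_categories()]).
#'
#' @param timeline a `category_timeline`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_categories_csv <- function(timeline, path) {
  rows <- do.call(rbind, lapply(seq_along(timeline$days), function(i) {
    codes <- setdiff(timeline$entries[[i]], "no_entry")
    if (length(codes) == 0L) return(NULL)
    data.frame(day = timeline$days[i], category_code = codes,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(day = integer(), category_code = character())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.category_timeline <- function(x, ...) {
  n_missing <- sum(vapply(x$entries, function(e) identical(e, "no_entry"), TRUE))
  cat(sprintf("category_timeline '%s': %d days, %d without entry (%.1f%%)\n",
              x$case_id, length(x$days), n_missing,
              100 * n_missing / length(x$days)))
  invisible(x)
}
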