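#' Questionnaire schema
#'
#' A schema maps item identifiers to factor labels and fixes the bounds of
#' the rating scale. The packaged default ([tpq43_schema()]) has 43 items on
#' a 0-100 visual analog scale grouped into the 7 factors WPE, RFP, TAS,
#' EPI, ICP, MOT and MSC, matching the structure of a daily therapy process
#' questionnaire.
#'
#' @param factors named list; one character vector of item identifiers per
#'   factor label, in display order.
#' @param scale_min,scale_max numeric scale bounds (visual-analog units).
#' @return An object of class `tpq_schema` with elements `items`,
#'   `factor_of` (named character vector item -> factor), `factors`,
#'   `scale_min` and `scale_max`.
#' @examples
#' sch <- tpq_schema(list(A = c("a1", "a2"), B = "b1"), 0, 100)
#' sch$factor_of[["b1"]]
#' @export
tpq_schema <- function(factors, scale_min = 0, scale_max = 100) {
  if (!is.list(factors) || is.null(names(factors)) || any(names(factors) == ""))
    stop("`factors` must be a named list of item identifier vectors")
  if (!is.numeric(scale_min) || !is.numeric(scale_max) || scale_min >= scale_max)
    stop("scale_min must be strictly less than scale_max")
  items <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(items))
    stop("every item must map to exactly one factor (duplicate item ids found)")
  if (any(lengths(factors) == 0))
    stop("factor with zero items: ", paste(names(factors)[lengths(factors) == 0], collapse = ", "))
  factor_of <- rep(names(factors), lengths(factors))
  names(factor_of) <- items
  structure(
    list(items = items, factor_of = factor_of, factors = names(factors),
         scale_min = as.numeric(scale_min), scale_max = as.numeric(scale_max)),
    class = "tpq_schema"
  )
}

#' Read a schema from a JSON document
#'
#' Expects `{scale_min, scale_max, factors: {label: [item ids]}}`.
#'
#' @param path path to a JSON schema file.
#' @return A [tpq_schema()] object.
#' @export
read_schema <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$factors)) stop("schema JSON lacks a `factors` map")
  tpq_schema(as.list(doc$factors),
             scale_min = doc$scale_min %||% 0,
             scale_max = doc$scale_max %||% 100)
}

#' The default 43-item / 7-factor schema
#'
#' @return The packaged default schema: 43 items on a 0-100 scale under the
#'   factors WPE, RFP, TAS, EPI, ICP, MOT, MSC. Item identifiers are
#'   synthetic placeholders since the instrument's item list is not public.
#' @examples
#' sch <- tpq43_schema()
#' length(sch$items)   # 43
#' sch$factors         # 7 factor labels
#' @export
tpq43_schema <- function() {
  read_schema(system.file("extdata", "tpq43.json", package = "patternshift",
                          mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tpq_schema <- function(x, ...) {
  cat("Questionnaire schema:", length(x$items), "items,",
      length(x$factors), "factors, scale [", x$scale_min, ",", x$scale_max, "]\n")
  counts <- table(factor(x$factor_of, levels = x$factors))
  cat(paste(sprintf("%s(%d)", names(counts), counts), collapse = " "), "\n")
  invisible(x)
}
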