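# Shared constants and small helpers.

# Closed category set for thesaurus concepts.
CONCEPT_CATEGORIES <- c(
  "gene", "disease", "drug", "pathway", "biological_process", "liver_pathology"
)

KEYWORD_TYPES <- c("full_name", "symbol", "alias")

#' @noRd
assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Resolve (year, month, day) with possibly missing month/day to a Date.
# Year-only records map to July 1, month-only to the 15th: midpoints keep
# mean-date arithmetic unbiased when precision is coarse.
#' @noRd
doc_date <- function(year, month = NA_integer_, day = NA_integer_) {
  n <- length(year)
  month <- rep_len(as.integer(month), n)
  day <- rep_len(as.integer(day), n)
  out_month <- ifelse(is.na(month), 7L, month)
  out_day <- ifelse(is.na(month), 1L, ifelse(is.na(day), 15L, day))
  lubridate::make_date(as.integer(year), out_month, out_day)
}

#' @noRd
decimal_year <- function(date) {
  lubridate::decimal_date(date)
}

# Canonical unordered pair: a < c lexicographically.
#' @noRd
order_pair <- function(a, b) {
  swap <- a > b
  tibble::tibble(
    a = ifelse(swap, b, a),
    b = ifelse(swap, a, b)
  )
}

#' @noRd
check_year <- function(year, doc_id) {
  bad <- is.na(year) | year < 1800 | year > 2100
  if (any(bad)) {
    abort(sprintf(
      "document(s) with unparseable or out-of-range year: %s",
      paste(utils::head(doc_id[bad], 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}
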