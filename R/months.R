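#' Calendar-month utilities
#'
#' All linkage and outcome logic in this package runs at calendar-month
#' granularity. Months are represented as canonical `"YYYY-MM"` strings;
#' these helpers validate, order and step them.
#'
#' @name months
#' @keywords internal
NULL

month_regex <- "^([0-9]{4})-(0[1-9]|1[0-2])$"

#' Validate canonical calendar months
#'
#' @param month Character vector of months in `"YYYY-MM"` form.
#' @return The input, invisibly, after validation.
#' @keywords internal
assert_month <- function(month) {
  bad <- is.na(month) | !grepl(month_regex, month)
  if (any(bad)) {
    stop("malformed calendar month(s): ",
         paste(utils::head(unique(month[bad]), 5L), collapse = ", "),
         " (expected 'YYYY-MM' with MM in 01-12)", call. = FALSE)
  }
  invisible(month)
}

#' Month arithmetic as a count of months since year 0
#' @keywords internal
month_index <- function(month) {
  assert_month(month)
  y <- as.integer(substr(month, 1L, 4L))
  m <- as.integer(substr(month, 6L, 7L))
  y * 12L + (m - 1L)
}

#' @keywords internal
month_from_index <- function(idx) {
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

#' The next calendar month
#'
#' Steps a canonical `"YYYY-MM"` month forward by one, rolling over the year
#' at December. This defines the readmission window: a readmission is any
#' admission episode whose admission month equals the next calendar month
#' after the index discharge month.
#'
#' @param month Character vector of canonical months (`"YYYY-MM"`).
#' @return Character vector of the following months.
#' @examples
#' next_calendar_month("2013-12")  # "2014-01"
#' next_calendar_month(c("2013-10", "2013-11"))
#' @export
next_calendar_month <- function(month) {
  month_from_index(month_index(month) + 1L)
}

#' Inclusive month sequence
#' @keywords internal
month_seq <- function(from, to) {
  month_from_index(seq.int(month_index(from), month_index(to)))
}

#' Canonicalize month strings from common dialects
#'
#' Accepts `"2013-12"`, `"2013/12"`, `"201312"`, `"Dec 2013"`, `"December
#' 2013"` and `"12/2013"`; returns `"YYYY-MM"` or `NA` where no dialect
#' parses.
#'
#' @param x Character vector of raw month values.
#' @return Character vector of canonical months, `NA` for unparseable input.
#' @keywords internal
canonical_month <- function(x) {
  x <- trimws(as.character(x))
  out <- rep_len(NA_character_, length(x))

  iso <- grepl(month_regex, x)
  out[iso] <- x[iso]

  slash <- grepl("^[0-9]{4}/(0[1-9]|1[0-2])$", x)
  out[slash] <- sub("/", "-", x[slash])

  compact <- grepl("^[0-9]{4}(0[1-9]|1[0-2])$", x)
  out[compact] <- paste0(substr(x[compact], 1, 4), "-", substr(x[compact], 5, 6))

  mm_yyyy <- grepl("^(0?[1-9]|1[0-2])/[0-9]{4}$", x)
  if (any(mm_yyyy)) {
    parts <- strsplit(x[mm_yyyy], "/", fixed = TRUE)
    out[mm_yyyy] <- vapply(parts, function(p) {
      sprintf("%04d-%02d", as.integer(p[2]), as.integer(p[1]))
    }, character(1))
  }

  # "Dec 2013" / "December 2013", case-insensitive
  named <- grepl("^[A-Za-z]{3,9} [0-9]{4}$", x)
  if (any(named)) {
    parts <- strsplit(x[named], " ", fixed = TRUE)
    out[named] <- vapply(parts, function(p) {
      m <- pmatch(tolower(p[1]), tolower(month.name))
      if (is.na(m)) m <- match(tolower(p[1]), tolower(month.abb))
      if (is.na(m)) NA_character_ else sprintf("%04d-%02d", as.integer(p[2]), m)
    }, character(1))
  }

  out
}
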