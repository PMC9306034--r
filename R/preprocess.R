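#' Standardize a raw survey or admissions table
#'
#' Canonicalizes the ten identifier-key fields (and any present extras):
#' whitespace is trimmed, categorical values are lower-cased with internal
#' spaces collapsed to underscores, months are coerced to `"YYYY-MM"` from
#' common dialects (`"Dec 2013"`, `"12/2013"`, `"201312"`, ...), and age and
#' length of stay to integers. Rows failing any coercion, or carrying a
#' categorical value outside the declared vocabulary, are excluded from the
#' returned table and itemized in the attached issue report -- deterministic
#' linkage needs complete, valid keys, and silent dropping would hide bias.
#'
#' @param records Data frame with the documented survey or admission columns.
#' @param key_spec Named list mapping column names to validator specs; the
#'   default [default_key_spec()] covers the ten identifier keys.
#' @param strict If `TRUE`, any validation issue raises an error instead of
#'   being collected.
#' @return The standardized tibble of valid rows, with attribute `"issues"`
#'   (a tibble: `row`, `field`, `value`, `problem`) retrievable via
#'   [validation_issues()].
#' @export
standardize <- function(records, key_spec = default_key_spec(),
                        strict = FALSE) {
  df <- tibble::as_tibble(records)
  issues <- list()
  note <- function(rows, field, values, problem) {
    if (!length(rows)) return()
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      row = as.integer(rows), field = field,
      value = as.character(values), problem = problem)
  }

  for (field in intersect(names(key_spec), names(df))) {
    spec <- key_spec[[field]]
    raw <- df[[field]]
    if (spec$type == "category") {
      val <- canonical_category(raw)
      bad <- which(!is.na(raw) & !(val %in% spec$levels))
      note(bad, field, raw[bad], "unknown category value")
      val[!(val %in% spec$levels)] <- NA_character_
    } else if (spec$type == "month") {
      val <- canonical_month(raw)
      bad <- which(!is.na(raw) & is.na(val))
      note(bad, field, raw[bad], "unparseable month")
    } else { # integer
      val <- suppressWarnings(as.integer(trimws(as.character(raw))))
      recoverable <- suppressWarnings(as.numeric(trimws(as.character(raw))))
      val[is.na(val) & !is.na(recoverable)] <-
        as.integer(recoverable[is.na(val) & !is.na(recoverable)])
      bad <- which(!is.na(raw) & is.na(val))
      note(bad, field, raw[bad], "not an integer")
      if (!is.null(spec$min)) {
        low <- which(!is.na(val) & val < spec$min)
        note(low, field, raw[low], paste("below minimum", spec$min))
        val[!is.na(val) & val < spec$min] <- NA_integer_
      }
    }
    missing <- which(is.na(raw))
    note(missing, field, NA_character_, "missing value")
    df[[field]] <- val
  }

  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(row = integer(), field = character(),
                   value = character(), problem = character())
  if (strict && nrow(issues)) {
    stop("validation failed for ", nrow(issues), " cell(s); first: row ",
         issues$row[1], " field '", issues$field[1], "' (",
         issues$problem[1], ")", call. = FALSE)
  }

  checked <- intersect(names(key_spec), names(df))
  ok <- !Reduce(`|`, lapply(df[checked], is.na), rep(FALSE, nrow(df)))
  out <- df[ok, , drop = FALSE]
  attr(out, "issues") <- issues
  attr(out, "filter_report") <- list(stage = "standardize",
                                     n_input = nrow(df),
                                     n_kept = nrow(out),
                                     n_dropped = nrow(df) - nrow(out))
  out
}

canonical_category <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ /-]+", "_", x)
}

#' Validation spec for the ten identifier keys
#'
#' @param n_hospitals,n_districts How many of the hospital / district
#'   vocabularies are in play.
#' @return Named list of per-field validator specs consumed by
#'   [standardize()].
#' @export
default_key_spec <- function(n_hospitals = 7, n_districts = 18) {
  list(
    age = list(type = "integer", min = 0),
    sex = list(type = "category", levels = vocab_sex),
    residence_district = list(type = "category",
                              levels = vocab_district[seq_len(n_districts)]),
    admission_source = list(type = "category",
                            levels = vocab_admission_source),
    admission_month = list(type = "month"),
    discharge_month = list(type = "month"),
    admission_specialty = list(type = "category", levels = vocab_specialty),
    discharge_specialty = list(type = "category", levels = vocab_specialty),
    discharge_hospital = list(type = "category",
                              levels = vocab_hospital[seq_len(n_hospitals)]),
    length_of_stay = list(type = "integer", min = 1))
}

#' Validation issues collected by standardize()
#' @param x A tibble returned by [standardize()].
#' @return Tibble of issues (`row`, `field`, `value`, `problem`).
#' @export
validation_issues <- function(x) {
  attr(x, "issues") %||%
    tibble::tibble(row = integer(), field = character(),
                   value = character(), problem = character())
}

#' Row-count report attached by a filter
#' @param x A tibble returned by [standardize()], [filter_survey_eligible()]
#'   or [filter_admission_candidates()].
#' @return List with `n_input`, `n_kept`, `n_dropped`.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report")
}

#' Restrict the survey to linkage-eligible respondents
#'
#' Keeps survey rows aged `min_age` or above (default 45, the admissions
#' dataset's coverage floor: only respondents aged 45+ can possibly link).
#' A pure row subset -- no field is modified.
#'
#' @param survey Standardized survey tibble.
#' @param min_age Inclusive age floor.
#' @return The eligible subset with a `filter_report` attribute
#'   (`n_input`, `n_kept`, `n_dropped`).
#' @export
filter_survey_eligible <- function(survey, min_age = 45) {
  out <- survey[!is.na(survey$age) & survey$age >= min_age, , drop = FALSE]
  attr(out, "filter_report") <- list(stage = "filter_survey_eligible",
                                     n_input = nrow(survey),
                                     n_kept = nrow(out),
                                     n_dropped = nrow(survey) - nrow(out))
  out
}

#' Restrict admissions to the linkage candidate pool
#'
#' Keeps episodes discharged home within the closed month `window` from one
#' of the study `hospitals`, for patients aged `min_age` or above. The full
#' admissions table must be retained separately by the caller: readmissions
#' in the month after the window close only at outcome construction, which
#' scans the unfiltered table.
#'
#' Rows lacking a `discharge_destination` column value are excluded with a
#' warning (the destination is part of the extraction rule but not of the
#' match key).
#'
#' @param admissions Standardized admissions tibble.
#' @param window Length-2 character, closed month interval of discharge.
#' @param hospitals Character vector of study hospitals (non-empty).
#' @param min_age Inclusive age floor (default 45).
#' @return The candidate subset with a `filter_report` attribute.
#' @export
filter_admission_candidates <- function(admissions,
                                        window = c("2013-10", "2013-12"),
                                        hospitals = vocab_hospital,
                                        min_age = 45) {
  if (length(hospitals) == 0) {
    stop("configuration error: the study hospital set is empty", call. = FALSE)
  }
  assert_month(window)
  months <- month_seq(window[1], window[2])

  keep <- !is.na(admissions$age) & admissions$age >= min_age &
    admissions$discharge_month %in% months &
    admissions$discharge_hospital %in% hospitals
  if ("discharge_destination" %in% names(admissions)) {
    dest <- admissions$discharge_destination
    if (anyNA(dest)) {
      warning(sum(is.na(dest)), " admission row(s) lack a discharge ",
              "destination and were excluded from the candidate pool",
              call. = FALSE)
    }
    keep <- keep & !is.na(dest) & dest == "home"
  }
  out <- admissions[keep, , drop = FALSE]
  attr(out, "filter_report") <- list(stage = "filter_admission_candidates",
                                     n_input = nrow(admissions),
                                     n_kept = nrow(out),
                                     n_dropped = nrow(admissions) - nrow(out))
  out
}
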