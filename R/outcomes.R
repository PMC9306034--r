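#' Covariate binning helpers
#'
#' Age is binned as 45-54 / 55-64 / 65-74 / 75+; length of stay as 1-3 /
#' 4-7 / 8+ days (disjoint bins, so a 7-day stay falls in the middle bin);
#' specialties map through a dictionary to medicine / surgery / oncology /
#' others.
#'
#' @param age,los Integer vectors.
#' @param specialty Character vector of specialty codes.
#' @param dictionary Named vector mapping codes to groups (default
#'   [specialty_dictionary()]).
#' @return Character vector of group labels.
#' @name covariate_bins
NULL

#' @rdname covariate_bins
#' @export
age_group_of <- function(age) {
  as.character(cut(age, breaks = c(-Inf, 54, 64, 74, Inf),
                   labels = c("45-54", "55-64", "65-74", "75+")))
}

#' @rdname covariate_bins
#' @export
los_group_of <- function(los) {
  as.character(cut(los, breaks = c(-Inf, 3, 7, Inf),
                   labels = c("1-3 days", "4-7 days", "8+ days")))
}

#' @rdname covariate_bins
#' @export
specialty_group_of <- function(specialty, dictionary = specialty_dictionary()) {
  unknown <- setdiff(unique(specialty), names(dictionary))
  if (length(unknown)) {
    stop("specialty code(s) not in the grouping dictionary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(dictionary[specialty])
}

#' Assemble the linked analysis rows
#'
#' Joins each uniquely matched survey row to its admission episode, giving
#' one analysis row per linked patient: the index episode's identifier key
#' and CSSA flag plus the two survey responses.
#'
#' @param result A `linkage_result`.
#' @param survey The standardized survey table the linkage ran on.
#' @param admission_candidates The candidate episode table it ran on.
#' @return Tibble, one row per uniquely linked patient.
#' @export
linked_patients <- function(result, survey, admission_candidates) {
  stopifnot(inherits(result, "linkage_result"))
  pairs <- result$unique_pairs
  sv <- survey[, intersect(c("survey_id", "quality_rating", "experience_score"),
                           names(survey)), drop = FALSE]
  ep <- admission_candidates[, c("episode_id", identifier_keys(), "cssa_flag"),
                             drop = FALSE]
  out <- dplyr::left_join(pairs, sv, by = "survey_id")
  out <- dplyr::left_join(out, ep, by = "episode_id")
  tibble::as_tibble(out)
}

#' Flag next-calendar-month readmissions
#'
#' For each linked patient, scans the full (unfiltered) admissions table for
#' episodes of the same pseudo patient admitted in the calendar month
#' following the index discharge month, excluding the index episode itself.
#' `readmit_any` is true if any such episode exists; `readmit_ae` /
#' `readmit_opd` if any was admitted through Accident & Emergency /
#' the outpatient department. A patient readmitted through both sources in
#' the month sets both flags, and a readmission through some other source
#' sets `readmit_any` alone -- the source classes overlap and do not
#' exhaust `readmit_any`. Multiple readmissions count once per flag
#' (patient-level binary outcomes).
#'
#' @param linked Tibble from [linked_patients()].
#' @param full_admissions The complete standardized admissions table --
#'   not the linkage-candidate subset, since readmissions in the month
#'   after the window close would otherwise be invisible.
#' @return `linked` with logical columns `readmit_any`, `readmit_ae`,
#'   `readmit_opd` appended.
#' @export
flag_readmissions <- function(linked, full_admissions) {
  missing_pid <- setdiff(linked$pseudo_id, full_admissions$pseudo_id)
  if (length(missing_pid)) {
    stop("data integrity error: linked pseudo_id(s) absent from the ",
         "admissions table: ", paste(utils::head(missing_pid, 5L),
                                     collapse = ", "), call. = FALSE)
  }
  if (nrow(linked) == 0) {
    linked$readmit_any <- logical(0)
    linked$readmit_ae <- logical(0)
    linked$readmit_opd <- logical(0)
    return(linked)
  }
  target <- next_calendar_month(linked$discharge_month)

  adm <- full_admissions[, c("pseudo_id", "episode_id", "admission_month",
                             "admission_source")]
  cand <- dplyr::inner_join(
    tibble::tibble(pseudo_id = linked$pseudo_id,
                   index_episode = linked$episode_id,
                   target_month = target,
                   .link_row = seq_len(nrow(linked))),
    adm, by = "pseudo_id", relationship = "many-to-many")
  cand <- cand[cand$admission_month == cand$target_month &
                 cand$episode_id != cand$index_episode, , drop = FALSE]

  agg <- dplyr::summarise(
    dplyr::group_by(cand, .data$.link_row),
    any = dplyr::n() > 0,
    ae = any(.data$admission_source == "ae"),
    opd = any(.data$admission_source == "opd"),
    .groups = "drop")

  linked$readmit_any <- FALSE
  linked$readmit_ae <- FALSE
  linked$readmit_opd <- FALSE
  linked$readmit_any[agg$.link_row] <- agg$any
  linked$readmit_ae[agg$.link_row] <- agg$ae
  linked$readmit_opd[agg$.link_row] <- agg$opd
  linked
}

#' Derive the grouped analysis covariates
#'
#' Adds `age_group`, `los_group` and `specialty_group` (from the discharge
#' specialty) to the linked analysis table, plus the two dichotomized
#' experience exposures: `quality_high` (rating 4-5, i.e. "Good" or better)
#' and `experience_high` (score 8 or more, the cohort median).
#'
#' @param linked Tibble from [linked_patients()] / [flag_readmissions()].
#' @param dictionary Specialty grouping dictionary.
#' @return `linked` with the derived columns appended.
#' @export
derive_covariates <- function(linked, dictionary = specialty_dictionary()) {
  linked$age_group <- age_group_of(linked$age)
  linked$los_group <- los_group_of(linked$length_of_stay)
  linked$specialty_group <- specialty_group_of(linked$discharge_specialty,
                                               dictionary)
  if ("quality_rating" %in% names(linked)) {
    linked$quality_high <- linked$quality_rating >= 4
  }
  if ("experience_score" %in% names(linked)) {
    linked$experience_high <- linked$experience_score >= 8
  }
  linked
}
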