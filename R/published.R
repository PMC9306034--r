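#' Published aggregate counts from the reference linkage study
#'
#' Aggregate results of a published territory-wide Hong Kong study that
#' linked an anonymous inpatient-experience survey (respondents aged 45+,
#' index discharges October-December 2013, seven acute public hospitals) to
#' administrative admissions by the same ten-variable deterministic key.
#' The individual-level data are confidential; these printed aggregates are
#' the only public quantities and serve as reference inputs for the
#' arithmetic this package automates.
#'
#' @return `published_linkage_counts()`: list with the survey-side class
#'   counts (`n_survey_45plus = 2811`, `n_unique = 1746`,
#'   `n_one_to_many = 996`, `n_unmatched = 69`) and the readmission count
#'   among linked patients (`n_readmitted_any = 416`).
#' @export
published_linkage_counts <- function() {
  list(n_survey_45plus = 2811L, n_unique = 1746L, n_one_to_many = 996L,
       n_unmatched = 69L, n_readmitted_any = 416L)
}

#' @rdname published_linkage_counts
#' @return `published_table1()`: tibble of the descriptive
#'   readmission-pattern table for the 1746 linked patients -- per covariate
#'   level, the respondent count `n` and the counts readmitted in the next
#'   calendar month through any department (`readmit_any`), through A&E
#'   (`readmit_ae`) and through outpatient referral (`readmit_opd`). The
#'   source counts overlap: a patient readmitted through both sources is in
#'   both source columns.
#' @export
published_table1 <- function() {
  tibble::tribble(
    ~variable,         ~level,        ~n,   ~readmit_any, ~readmit_ae, ~readmit_opd,
    "sex",             "male",        919L,  230L,  88L, 159L,
    "sex",             "female",      827L,  186L,  57L, 132L,
    "age_group",       "45-54",       368L,   84L,  15L,  70L,
    "age_group",       "55-64",       504L,  129L,  37L, 100L,
    "age_group",       "65-74",       382L,   79L,  28L,  56L,
    "age_group",       "75+",         492L,  124L,  65L,  65L,
    "los_group",       "1-3 days",    877L,  164L,  53L, 116L,
    "los_group",       "4-7 days",    479L,  130L,  42L,  95L,
    "los_group",       "8+ days",     390L,  122L,  50L,  80L,
    "cssa",            "no",          1525L, 357L, 119L, 256L,
    "cssa",            "yes",         221L,   59L,  26L,  35L,
    "specialty_group", "medicine",    661L,  174L,  74L, 113L,
    "specialty_group", "surgery",     421L,  105L,  34L,  74L,
    "specialty_group", "oncology",    85L,    55L,   8L,  47L,
    "specialty_group", "others",      579L,   82L,  29L,  57L,
    "quality_high",    "high",        1353L, 331L, 107L, 243L,
    "quality_high",    "low",         393L,   85L,  38L,  48L,
    "experience_high", ">=8",         1303L, 316L, 105L, 230L,
    "experience_high", "<8",          443L,  100L,  40L,  61L)
}

#' Expand a count table to one row per patient
#'
#' Turns one variable's rows of [published_table1()] into a patient-level
#' tibble (`level`, logical `event`) so that row-level operations like
#' [crosstab()] can run on published aggregates.
#'
#' @param variable A `variable` value of [published_table1()].
#' @param outcome One of `"readmit_any"`, `"readmit_ae"`, `"readmit_opd"`.
#' @return Tibble with one row per patient of the table's denominator.
#' @export
expand_published_counts <- function(variable, outcome = "readmit_any") {
  tab <- published_table1()
  tab <- tab[tab$variable == variable, , drop = FALSE]
  if (nrow(tab) == 0) {
    stop("unknown variable '", variable, "'", call. = FALSE)
  }
  ev <- tab[[outcome]]
  tibble::tibble(
    level = rep(tab$level, times = tab$n),
    event = unlist(lapply(seq_len(nrow(tab)), function(i) {
      rep(c(TRUE, FALSE), times = c(ev[i], tab$n[i] - ev[i]))
    })))
}
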