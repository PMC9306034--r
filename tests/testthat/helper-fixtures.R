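# Shared fixtures: all built in code, no files.

# A small, fast generator configuration for structural tests.
small_config <- function(n = 300, seed = 101, ...) {
  cohort_config(n_patients = n, seed = seed, ...)
}

# Hand-built minimal key rows: every identifier fixed except what a test
# varies. Returns one admission row (tibble) with the given overrides.
base_key <- function(...) {
  row <- tibble::tibble(
    age = 70L, sex = "male", residence_district = "eastern",
    admission_source = "ae", admission_month = "2013-11",
    discharge_month = "2013-11", admission_specialty = "general_medicine",
    discharge_specialty = "general_medicine",
    discharge_hospital = "hospital_1", length_of_stay = 4L)
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

make_admission <- function(pseudo_id, episode_id, ...) {
  dplyr::bind_cols(
    tibble::tibble(episode_id = episode_id, pseudo_id = pseudo_id),
    base_key(...),
    tibble::tibble(cssa_flag = FALSE, discharge_destination = "home",
                   diagnosis_code = "D001", procedure_code = "PR001"))
}

make_survey_row <- function(survey_id, ...) {
  dplyr::bind_cols(
    tibble::tibble(survey_id = survey_id),
    base_key(...),
    tibble::tibble(quality_rating = 4L, experience_score = 8L))
}

# Brute-force quadratic linkage oracle: compares every survey row with
# every admission row field by field. Independent of the hash-join path.
brute_force_link <- function(survey, admissions, key_fields = identifier_keys()) {
  classes <- character(nrow(survey))
  pair_pid <- rep(NA_character_, nrow(survey))
  pair_eid <- rep(NA_character_, nrow(survey))
  for (i in seq_len(nrow(survey))) {
    hits <- integer(0)
    for (j in seq_len(nrow(admissions))) {
      same <- TRUE
      for (f in key_fields) {
        if (as.character(survey[[f]][i]) != as.character(admissions[[f]][j])) {
          same <- FALSE
          break
        }
      }
      if (same) hits <- c(hits, j)
    }
    if (length(hits) == 0) classes[i] <- "unmatched"
    else if (length(hits) > 1) classes[i] <- "one_to_many"
    else {
      classes[i] <- "unique"
      pair_pid[i] <- admissions$pseudo_id[hits]
      pair_eid[i] <- admissions$episode_id[hits]
    }
  }
  # reverse multiplicity, same rule as the implementation
  uni <- which(classes == "unique")
  dup <- pair_eid[uni][duplicated(pair_eid[uni])]
  demote <- uni[pair_eid[uni] %in% dup]
  classes[demote] <- "one_to_many"
  list(classes = stats::setNames(classes, survey$survey_id),
       unique_pairs = tibble::tibble(
         survey_id = survey$survey_id[classes == "unique"],
         episode_id = pair_eid[classes == "unique"],
         pseudo_id = pair_pid[classes == "unique"]))
}

# Expand a 2x2 (exposure x event) into rows for logistic fitting.
expand_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    exposed = rep(c(1L, 1L, 0L, 0L), times = c(a, b, c, d)),
    event = rep(c(1L, 0L, 1L, 0L), times = c(a, b, c, d)))
}

# One standard linked analysis table, memoised per session for speed.
linked_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- generate_population(small_config(n = 2500, seed = 404))
      adm <- emit_admissions(pop)
      sv <- filter_survey_eligible(emit_survey(pop))
      cand <- filter_admission_candidates(adm)
      res <- link_deterministic(sv, cand)
      linked <- flag_readmissions(linked_patients(res, sv, cand), adm)
      cache <<- derive_covariates(linked)
    }
    cache
  }
})

# month comparison on canonical YYYY-MM strings
month_ge <- function(a, b) {
  peslink:::month_index(a) >= peslink:::month_index(b)
}
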