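test_that("invalid generator configurations are rejected with the field named", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(n_patients = -5), "n_patients")
  expect_error(cohort_config(study_months = c("2013-12", "2013-10")),
               "study_months")
  expect_error(cohort_config(study_months = "2013-13"), "calendar month")
  expect_error(cohort_config(survey_sampling_fraction = 1.2),
               "survey_sampling_fraction")
  expect_error(cohort_config(cssa_prevalence = -0.1), "cssa_prevalence")
  bad <- default_outcome_coefficients()
  bad$opd <- bad$opd[names(bad$opd) != "quality_high"]
  expect_error(cohort_config(outcome_coefficients = bad), "quality_high")
  expect_error(cohort_config(outcome_coefficients = bad$ae), "outcome_coefficients")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_config(n = 400, seed = 42)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$patients, p2$patients)
  expect_identical(p1$episodes, p2$episodes)
  expect_identical(emit_admissions(p1), emit_admissions(p2))
  expect_identical(emit_survey(p1), emit_survey(p2))
  # a different seed changes the draw
  p3 <- generate_population(small_config(n = 400, seed = 43))
  expect_false(identical(p1$episodes, p3$episodes))
})

test_that("admissions table conserves episodes and has complete identifiers", {
  pop <- generate_population(small_config(n = 350))
  adm <- emit_admissions(pop)
  expect_identical(nrow(adm), nrow(pop$episodes))
  expect_true(all(peslink:::admission_columns() %in% names(adm)))
  expect_false(anyNA(adm[identifier_keys()]))
  expect_false(anyNA(adm$pseudo_id))
  # every patient contributes at least one episode
  expect_true(all(pop$patients$pseudo_id %in% pop$episodes$pseudo_id))
  expect_true(all(adm$length_of_stay >= 1))
  expect_true(all(month_ge(adm$discharge_month, adm$admission_month)))
})

test_that("survey is anonymous, one row per patient, earliest eligible episode", {
  pop <- generate_population(small_config(n = 500, seed = 7))
  sv <- emit_survey(pop)
  expect_false("pseudo_id" %in% names(sv))
  expect_true(all(c("survey_id", identifier_keys(), "quality_rating",
                    "experience_score") %in% names(sv)))
  expect_true(all(sv$quality_rating %in% 1:5))
  expect_true(all(sv$experience_score %in% 0:10))

  oracle <- true_linkage_oracle(pop, sv)
  expect_identical(nrow(oracle), nrow(sv))
  expect_false(any(duplicated(oracle$pseudo_id)))

  # the surveyed episode is the patient's earliest eligible in-window
  # admission (checked against the ground-truth episode table; key-error
  # rows are excluded since their identifiers were deliberately perturbed)
  cfg <- pop$config
  win <- c("2013-10", "2013-11", "2013-12")
  eligible <- pop$episodes[pop$episodes$discharge_month %in% win &
                             pop$episodes$discharge_destination == "home", ]
  earliest <- tapply(eligible$admission_month, eligible$pseudo_id, min)
  joined <- dplyr::inner_join(sv, oracle, by = "survey_id")
  ok <- joined$admission_month == earliest[joined$pseudo_id]
  expect_gte(mean(ok), 1 - 2 * cfg$survey_key_error_rate)
})

test_that("zero sampling fraction yields an empty survey", {
  pop <- generate_population(small_config(n = 100,
                                          survey_sampling_fraction = 0))
  expect_identical(nrow(emit_survey(pop)), 0L)
})

test_that("the oracle rejects survey rows from a different population", {
  pop <- generate_population(small_config(n = 120, seed = 1))
  sv <- emit_survey(pop)
  foreign <- sv
  foreign$survey_id[1] <- "S99999"
  expect_error(true_linkage_oracle(pop, foreign), "not generated")
})

test_that("unique links from uncorrupted keys agree with the ground truth", {
  pop <- generate_population(small_config(n = 500, seed = 12,
                                          survey_key_error_rate = 0))
  sv <- filter_survey_eligible(emit_survey(pop))
  cand <- filter_admission_candidates(emit_admissions(pop))
  res <- link_deterministic(sv, cand)
  oracle <- true_linkage_oracle(pop, emit_survey(pop))
  truth <- stats::setNames(oracle$pseudo_id, oracle$survey_id)
  expect_true(all(res$unique_pairs$pseudo_id ==
                    truth[res$unique_pairs$survey_id]))
  # exact truth-copied keys always have at least their own episode
  expect_identical(length(res$unmatched_ids), 0L)
})

test_that("default generator reproduces the study-scale cohort profile", {
  pop <- generate_population(cohort_config(n_patients = 10000, seed = 20260920))
  adm <- emit_admissions(pop)
  sv <- emit_survey(pop)
  sv45 <- sv[sv$age >= 45, ]

  # collision calibration: share of 45+ survey keys matching >= 2
  # admission rows sits in the band implied by the reference cohort's
  # one-to-many share
  key <- function(d) do.call(paste, c(d[identifier_keys()], sep = "\r"))
  freq <- table(key(adm))
  coll <- mean(freq[key(sv45)] >= 2, na.rm = TRUE)
  expect_gt(coll, 0.25)
  expect_lt(coll, 0.45)

  # matched-subset summary statistics near the reference cohort's
  cand <- filter_admission_candidates(adm)
  res <- link_deterministic(sv45, cand)
  linked <- derive_covariates(
    flag_readmissions(linked_patients(res, sv45, cand), adm))
  expect_identical(as.integer(median(linked$length_of_stay)), 4L)
  expect_gt(mean(linked$sex == "male"), 0.48)
  expect_lt(mean(linked$sex == "male"), 0.58)
  expect_gt(mean(linked$quality_high), 0.72)
  expect_lt(mean(linked$quality_high), 0.83)
  expect_gt(mean(linked$experience_score), 7.9)
  expect_lt(mean(linked$experience_score), 8.3)
  med_age <- median(linked$age)
  expect_gte(med_age, 62)
  expect_lte(med_age, 68)
  # next-month readmission rate near the reference 23.8%
  expect_gt(mean(linked$readmit_any), 0.18)
  expect_lt(mean(linked$readmit_any), 0.30)
})

test_that("empirical readmission rates match the model-implied rates", {
  # binomial-error agreement between generated flags and the logistic
  # model probabilities, evaluated on the ground truth (all patients)
  cfg <- small_config(n = 4000, seed = 31, survey_sampling_fraction = 1,
                      survey_key_error_rate = 0)
  pop <- generate_population(cfg)
  sv <- emit_survey(pop)
  oracle <- true_linkage_oracle(pop, sv)
  adm <- emit_admissions(pop)
  linked <- dplyr::inner_join(sv, oracle, by = "survey_id")
  linked$episode_id <- "none"
  linked <- derive_covariates(flag_readmissions(linked, adm))

  ind <- peslink:::outcome_indicators(
    linked$age, linked$sex, linked$length_of_stay, linked$specialty_group,
    rep(FALSE, nrow(linked)), linked$quality_rating)
  # cssa is latent here; refit indicator from the patients table
  pat <- pop$patients[match(linked$pseudo_id, pop$patients$pseudo_id), ]
  ind$cssa_yes <- as.integer(pat$cssa_flag)
  oc <- cfg$outcome_coefficients
  for (model in c("ae", "opd")) {
    p <- stats::plogis(peslink:::outcome_eta(oc[[model]], ind))
    observed <- sum(linked[[paste0("readmit_", model)]])
    expected <- sum(p)
    sd_exp <- sqrt(sum(p * (1 - p)))
    expect_lt(abs(observed - expected), 4 * sd_exp)
  }
})
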