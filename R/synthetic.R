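#' Configuration for the synthetic dual-dataset generator
#'
#' Builds and validates the configuration driving [generate_population()].
#' The defaults emulate the study conditions of a territory-wide Hong Kong
#' inpatient-experience survey linked to public-hospital admissions: seven
#' acute hospitals over seven clusters, 18 residence districts, survey index
#' discharges between October and December 2013, respondents aged 18+ of
#' whom roughly 79% are 45 or above, a 45+ age distribution with median
#' about 65 (IQR about 56-76), median length of stay 4 days, CSSA welfare
#' prevalence about 13%, a 0-10 experience score with mean about 8.1 (SD
#' about 1.5) and about 77.5% of respondents in the top two of five quality
#' levels.
#'
#' Next-month readmission is generated from three independent logistic
#' models over the analysis covariates: one for admissions through the
#' Accident & Emergency department (`ae`), one for outpatient-department
#' referrals (`opd`), and a small intercept-only model for all other
#' admission sources (`other`). The any-readmission indicator is derived as
#' the union of the three, so it is not itself constrained to be logistic.
#'
#' @param n_patients Number of latent patients (positive integer).
#' @param study_months Strictly increasing canonical months covered by the
#'   admissions dataset; the last month exists so readmissions of December
#'   discharges are observable.
#' @param survey_window Closed month interval (length-2 character) of index
#'   discharges eligible for the survey.
#' @param n_hospitals,n_districts Identifier cardinalities.
#' @param specialty_vocabulary Specialty codes; must be covered by
#'   `specialty_groups`.
#' @param specialty_groups Named vector mapping codes to the four analysis
#'   groups (see [specialty_dictionary()]).
#' @param age_distribution List: `p_under45` (share of respondents below
#'   45), `shape`/`scale` of the gamma giving years beyond 45, `max_age`.
#' @param los_distribution List: negative-binomial `size` and `mu` for
#'   length-of-stay minus one (the `mu` is further scaled by specialty).
#' @param episode_rate Expected number of additional (non-index,
#'   non-readmission) in-window admission episodes per patient.
#' @param survey_sampling_fraction Probability that an eligible index
#'   admission is surveyed.
#' @param cssa_prevalence Probability of the CSSA welfare flag.
#' @param experience_model List: `quality_probs` (length-5 marginal over
#'   quality ratings 5 down to 1), `score_means` (mean experience score per
#'   quality level, 5 down to 1), `score_sd`.
#' @param outcome_coefficients List of three named log-odds vectors `ae`,
#'   `opd`, `other`; `ae` and `opd` must name `intercept` and every
#'   non-reference covariate level (reference levels male, 45-54, 1-3 days,
#'   no CSSA, others specialty, low quality are implicitly zero).
#' @param survey_key_error_rate Fraction of survey rows whose identifier key
#'   is perturbed in one field, emulating the real-world key discordance
#'   that produces unmatched records (default 2.5%).
#' @param seed Integer seed; every downstream emission is deterministic
#'   given the config.
#' @return A validated `cohort_config` object (a named list).
#' @export
cohort_config <- function(n_patients = 10000,
                          study_months = month_seq("2013-10", "2014-01"),
                          survey_window = c("2013-10", "2013-12"),
                          n_hospitals = 7,
                          n_districts = 18,
                          specialty_vocabulary = vocab_specialty,
                          specialty_groups = specialty_dictionary(),
                          age_distribution = list(p_under45 = 0.212,
                                                  shape = 2.6, scale = 8.7,
                                                  max_age = 100),
                          los_distribution = list(size = 8, mu = 3.3),
                          episode_rate = 1.8,
                          survey_sampling_fraction = 0.36,
                          cssa_prevalence = 0.13,
                          experience_model = list(
                            quality_probs = c(0.46, 0.315, 0.17, 0.04, 0.015),
                            score_means = c(9.1, 8.3, 6.6, 5.2, 3.8),
                            score_sd = 1.0),
                          outcome_coefficients = default_outcome_coefficients(),
                          survey_key_error_rate = 0.025,
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, study_months = study_months,
    survey_window = survey_window, n_hospitals = n_hospitals,
    n_districts = n_districts, specialty_vocabulary = specialty_vocabulary,
    specialty_groups = specialty_groups, age_distribution = age_distribution,
    los_distribution = los_distribution, episode_rate = episode_rate,
    survey_sampling_fraction = survey_sampling_fraction,
    cssa_prevalence = cssa_prevalence, experience_model = experience_model,
    outcome_coefficients = outcome_coefficients,
    survey_key_error_rate = survey_key_error_rate, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Default generator log-odds coefficients
#'
#' Log-odds for the three readmission-source models over the analysis
#' covariates. The `ae` and `opd` covariate effects are the natural logs of
#' adjusted odds ratios reported for a comparable Hong Kong cohort (e.g.
#' outpatient readmission OR 1.54 for high perceived quality of care, A&E
#' OR 3.25 for age 75+); the intercepts are calibrated so the marginal
#' source-specific readmission rates under the generator's covariate mix
#' land near that cohort's observed rates (about 8% through A&E, about 17%
#' through outpatient referral, about 24% through any source). `other` is a
#' small intercept-only model for the remaining admission sources.
#'
#' @return Named list of three named numeric vectors.
#' @export
default_outcome_coefficients <- function() {
  levels_ae <- c(
    intercept = -3.28,
    sex_female = log(0.71),
    age_55_64 = log(1.74), age_65_74 = log(1.63), age_75p = log(3.25),
    los_4_7 = log(1.25), los_8p = log(2.02),
    cssa_yes = log(1.38),
    spec_medicine = log(1.82), spec_oncology = log(2.07),
    spec_surgery = log(1.34),
    quality_high = log(0.75))
  levels_opd <- c(
    intercept = -2.67,
    sex_female = log(1.01),
    age_55_64 = log(0.96), age_65_74 = log(0.66), age_75p = log(0.62),
    los_4_7 = log(1.47), los_8p = log(1.81),
    cssa_yes = log(0.89),
    spec_medicine = log(2.11), spec_oncology = log(11.08),
    spec_surgery = log(2.08),
    quality_high = log(1.54))
  list(ae = levels_ae, opd = levels_opd, other = c(intercept = -4.2))
}

outcome_covariate_levels <- function() {
  c("sex_female", "age_55_64", "age_65_74", "age_75p", "los_4_7", "los_8p",
    "cssa_yes", "spec_medicine", "spec_oncology", "spec_surgery",
    "quality_high")
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid generator configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  pos_int <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
    x >= 1 && x == floor(x)
  prob <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
    x >= 0 && x <= 1

  if (!pos_int(cfg$n_patients)) fail("n_patients", "must be a positive integer")
  assert_month(cfg$study_months)
  if (length(cfg$study_months) < 2 ||
      any(diff(month_index(cfg$study_months)) <= 0)) {
    fail("study_months", "must be strictly increasing with length >= 2")
  }
  assert_month(cfg$survey_window)
  if (length(cfg$survey_window) != 2 ||
      month_index(cfg$survey_window[2]) < month_index(cfg$survey_window[1])) {
    fail("survey_window", "must be a closed month interval [from, to]")
  }
  if (!pos_int(cfg$n_hospitals)) fail("n_hospitals", "must be a positive integer")
  if (!pos_int(cfg$n_districts)) fail("n_districts", "must be a positive integer")
  if (cfg$n_hospitals > length(vocab_hospital)) {
    fail("n_hospitals", paste("exceeds the hospital vocabulary size",
                              length(vocab_hospital)))
  }
  if (cfg$n_districts > length(vocab_district)) {
    fail("n_districts", paste("exceeds the district vocabulary size",
                              length(vocab_district)))
  }
  if (!all(cfg$specialty_vocabulary %in% names(cfg$specialty_groups))) {
    fail("specialty_vocabulary", "contains codes missing from specialty_groups")
  }
  if (!(length(cfg$episode_rate) == 1 && is.numeric(cfg$episode_rate) &&
        cfg$episode_rate >= 0)) {
    fail("episode_rate", "must be a non-negative number")
  }
  if (!prob(cfg$survey_sampling_fraction)) {
    fail("survey_sampling_fraction", "must be a probability in [0,1]")
  }
  if (!prob(cfg$cssa_prevalence)) fail("cssa_prevalence", "must be in [0,1]")
  if (!prob(cfg$survey_key_error_rate)) {
    fail("survey_key_error_rate", "must be in [0,1]")
  }
  em <- cfg$experience_model
  if (length(em$quality_probs) != 5 || any(em$quality_probs < 0) ||
      abs(sum(em$quality_probs) - 1) > 1e-8) {
    fail("experience_model", "quality_probs must be 5 probabilities summing to 1")
  }
  if (length(em$score_means) != 5 || !is.numeric(em$score_sd)) {
    fail("experience_model", "needs 5 score_means and a score_sd")
  }
  oc <- cfg$outcome_coefficients
  if (!all(c("ae", "opd", "other") %in% names(oc))) {
    fail("outcome_coefficients", "must name models 'ae', 'opd' and 'other'")
  }
  needed <- c("intercept", outcome_covariate_levels())
  for (m in c("ae", "opd")) {
    missing <- setdiff(needed, names(oc[[m]]))
    if (length(missing)) {
      fail("outcome_coefficients",
           paste0("model '", m, "' is missing level(s): ",
                  paste(missing, collapse = ", ")))
    }
  }
  if (!"intercept" %in% names(oc$other)) {
    fail("outcome_coefficients", "model 'other' needs an intercept")
  }
  invisible(cfg)
}

# Linear predictor of one outcome model over derived covariate indicators.
outcome_eta <- function(beta, cov) {
  eta <- rep_len(beta[["intercept"]], nrow(cov))
  for (lev in outcome_covariate_levels()) {
    if (lev %in% names(beta)) eta <- eta + beta[[lev]] * cov[[lev]]
  }
  eta
}

# 0/1 indicator columns for the non-reference covariate levels.
outcome_indicators <- function(age, sex, los, specialty_group, cssa,
                               quality_rating) {
  ag <- age_group_of(age)
  lg <- los_group_of(los)
  tibble::tibble(
    sex_female = as.integer(sex == "female"),
    age_55_64 = as.integer(ag == "55-64"),
    age_65_74 = as.integer(ag == "65-74"),
    age_75p = as.integer(ag == "75+"),
    los_4_7 = as.integer(lg == "4-7 days"),
    los_8p = as.integer(lg == "8+ days"),
    cssa_yes = as.integer(cssa),
    spec_medicine = as.integer(specialty_group == "medicine"),
    spec_oncology = as.integer(specialty_group == "oncology"),
    spec_surgery = as.integer(specialty_group == "surgery"),
    quality_high = as.integer(quality_rating >= 4))
}

# District weights and the cluster hospital serving each district. The
# skew of these (and the other identifier marginals below) is the
# calibration surface for the composite-key collision rate: the true
# per-identifier frequency profile is not publicly known, only the
# one-to-many match share it produced, so the marginals are concentrated
# until the generated key-frequency spectrum reproduces that share.
district_weights <- function(n) {
  w <- c(40, 22, 12, 8, 6, 5, 4, 3, 2.5, 2, 1.5, 1.2, 1, 0.8, 0.7,
         0.6, 0.5, 0.4)[seq_len(n)]
  w / sum(w)
}

specialty_weights <- function(codes) {
  base <- c(
    general_medicine = 0.360, geriatrics = 0.030, cardiac_care = 0.020,
    infectious_disease = 0.010, general_surgery = 0.270, oncology = 0.050,
    cardiothoracic_surgery = 0.010, emergency_medicine = 0.090,
    ent = 0.020, gynaecology = 0.030, neurosurgery = 0.005,
    ophthalmology = 0.040, orthopaedics = 0.060, rehabilitation = 0.005)
  w <- base[codes]
  w[is.na(w)] <- mean(base)
  w / sum(w)
}

# Specialty-dependent mean stay: oncology, rehabilitation and geriatric
# admissions run long, day-case-heavy specialties short.
los_mu_factor <- c(
  general_medicine = 1.15, geriatrics = 1.5, cardiac_care = 1.1,
  infectious_disease = 1.2, general_surgery = 0.95, oncology = 1.7,
  cardiothoracic_surgery = 1.3, emergency_medicine = 0.7, ent = 0.8,
  gynaecology = 0.8, neurosurgery = 1.3, ophthalmology = 0.7,
  orthopaedics = 1.1, rehabilitation = 2.2)

draw_los <- function(n, los_distribution, specialty = NULL) {
  mu <- los_distribution$mu
  if (!is.null(specialty)) {
    f <- los_mu_factor[specialty]
    f[is.na(f)] <- 1
    mu <- mu * unname(f)
  }
  1L + stats::rnbinom(n, size = los_distribution$size, mu = mu)
}

# Admission source depends on case mix: emergency medicine is almost all
# A&E, oncology mostly planned outpatient referral.
draw_source <- function(specialty, groups) {
  probs <- rbind(medicine = c(0.85, 0.10, 0.05),
                 surgery = c(0.55, 0.30, 0.15),
                 oncology = c(0.20, 0.70, 0.10),
                 others = c(0.70, 0.20, 0.10))
  g <- groups[specialty]
  g[specialty == "emergency_medicine"] <- NA  # handled below
  out <- character(length(specialty))
  em <- specialty == "emergency_medicine"
  if (any(em)) {
    out[em] <- sample(vocab_admission_source, sum(em), replace = TRUE,
                      prob = c(0.95, 0.02, 0.03))
  }
  for (grp in rownames(probs)) {
    sel <- !em & !is.na(g) & g == grp
    if (any(sel)) {
      out[sel] <- sample(vocab_admission_source, sum(sel), replace = TRUE,
                         prob = probs[grp, ])
    }
  }
  out
}

# Month-granular discharge: longer stays are more likely to cross a month
# boundary. Bounded away from 0/1 so every (admission month, LOS) cell is
# reachable in both discharge months.
draw_spill <- function(los) {
  stats::rbinom(length(los), 1L, pmin(0.45, pmax(0.02, (los - 1) / 70)))
}

# Specialty draw, optionally tilted by hospital: each hospital has its own
# case-mix emphasis, which concentrates the joint (hospital, specialty)
# distribution the way real service allocation does.
draw_specialty <- function(n, cfg, hospital = NULL) {
  codes <- cfg$specialty_vocabulary
  base <- specialty_weights(codes)
  if (is.null(hospital)) {
    return(sample(codes, n, replace = TRUE, prob = base))
  }
  out <- character(n)
  for (h in unique(hospital)) {
    j <- match(h, vocab_hospital)
    tilt <- c(0.25, 1, 2.8)[(seq_along(codes) + j) %% 3 + 1]
    sel <- hospital == h
    out[sel] <- sample(codes, sum(sel), replace = TRUE, prob = base * tilt)
  }
  out
}

#' Generate the latent patient population
#'
#' Draws `n_patients` latent patients with demographics, an index admission
#' episode, latent experience responses and model-generated next-month
#' readmission episodes. The returned object is the generator's ground
#' truth; [emit_admissions()] and [emit_survey()] derive the two linkable
#' datasets from it, and [true_linkage_oracle()] exposes the true survey row
#' to patient mapping for validation.
#'
#' All randomness flows from `config$seed`; the same config yields a
#' byte-identical population.
#'
#' @param config A [cohort_config()].
#' @return A `pes_population`: list with `patients` (one row per patient),
#'   `episodes` (one row per admission episode, index and readmission), and
#'   the `config`.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  cfg <- config

  withr::with_seed(cfg$seed, {
    n <- cfg$n_patients
    ad <- cfg$age_distribution
    young <- stats::runif(n) < ad$p_under45
    age <- integer(n)
    age[young] <- sample(18:44, sum(young), replace = TRUE)
    age[!young] <- pmin(ad$max_age,
                        45L + as.integer(stats::rgamma(sum(!young),
                                                       shape = ad$shape,
                                                       scale = ad$scale)))
    sex <- sample(vocab_sex, n, replace = TRUE, prob = c(0.525, 0.475))
    districts <- vocab_district[seq_len(cfg$n_districts)]
    district <- sample(districts, n, replace = TRUE,
                       prob = district_weights(cfg$n_districts))
    # each district is served mainly by its cluster hospital
    cluster <- ceiling(match(district, districts) * cfg$n_hospitals /
                         cfg$n_districts)
    hosp_pool <- vocab_hospital[seq_len(cfg$n_hospitals)]
    hospital <- ifelse(stats::runif(n) < 0.97, hosp_pool[cluster],
                       sample(hosp_pool, n, replace = TRUE))
    cssa <- stats::runif(n) < cfg$cssa_prevalence

    em <- cfg$experience_model
    quality <- sample(5:1, n, replace = TRUE, prob = em$quality_probs)
    score <- pmin(10L, pmax(0L, as.integer(round(
      stats::rnorm(n, mean = em$score_means[6L - quality], sd = em$score_sd)))))

    survey_months <- month_seq(cfg$survey_window[1], cfg$survey_window[2])
    k <- length(survey_months)
    month_w <- stats::dnorm(seq_len(k), mean = (k + 1) / 2 + 0.2, sd = k / 3.5)
    adm_month <- sample(survey_months, n, replace = TRUE, prob = month_w)
    adm_spec <- draw_specialty(n, cfg, hospital)
    dis_spec <- ifelse(stats::runif(n) < 0.97, adm_spec,
                       draw_specialty(n, cfg, hospital))
    los <- draw_los(n, cfg$los_distribution, dis_spec)
    dis_month <- month_from_index(month_index(adm_month) + draw_spill(los))
    adm_source <- draw_source(adm_spec, cfg$specialty_groups)
    destination <- ifelse(stats::runif(n) < 0.93, "home", "other")

    patients <- tibble::tibble(
      pseudo_id = sprintf("P%06d", seq_len(n)),
      age = age, sex = sex, residence_district = district,
      cssa_flag = cssa, quality_rating = quality, experience_score = score)

    index <- tibble::tibble(
      pseudo_id = patients$pseudo_id,
      age = age, sex = sex, residence_district = district,
      admission_source = adm_source,
      admission_month = adm_month, discharge_month = dis_month,
      admission_specialty = adm_spec, discharge_specialty = dis_spec,
      discharge_hospital = hospital, length_of_stay = los,
      cssa_flag = cssa, discharge_destination = destination,
      .role = "index")

    # model-generated next-month readmissions
    cov <- outcome_indicators(age, sex, los,
                              specialty_group_of(dis_spec, cfg$specialty_groups),
                              cssa, quality)
    oc <- cfg$outcome_coefficients
    p_ae <- stats::plogis(outcome_eta(oc$ae, cov))
    p_opd <- stats::plogis(outcome_eta(oc$opd, cov))
    p_other <- stats::plogis(outcome_eta(oc$other, cov))
    flag_ae <- stats::runif(n) < p_ae
    flag_opd <- stats::runif(n) < p_opd
    flag_other <- stats::runif(n) < p_other

    readmit <- function(flag, source) {
      m <- sum(flag)
      if (m == 0) return(NULL)
      r_spec <- ifelse(stats::runif(m) < 0.85, dis_spec[flag],
                       draw_specialty(m, cfg, hospital[flag]))
      r_los <- draw_los(m, cfg$los_distribution, r_spec)
      r_adm <- next_calendar_month(dis_month[flag])
      tibble::tibble(
        pseudo_id = patients$pseudo_id[flag],
        age = age[flag], sex = sex[flag],
        residence_district = district[flag],
        admission_source = source,
        admission_month = r_adm,
        discharge_month = month_from_index(month_index(r_adm) +
                                             draw_spill(r_los)),
        admission_specialty = r_spec, discharge_specialty = r_spec,
        discharge_hospital = hospital[flag], length_of_stay = r_los,
        cssa_flag = cssa[flag],
        discharge_destination = ifelse(stats::runif(m) < 0.9, "home", "other"),
        .role = "readmission")
    }
    # additional in-window episodes: elderly admissions extracts are
    # episode-based, with several admissions per patient per quarter. To
    # keep the model-generated readmission signal clean, an extra episode
    # is never admitted in the month right after its patient's index
    # discharge (that slot belongs to the outcome model alone) and never
    # before the index admission (the survey samples the earliest
    # admission).
    extras <- NULL
    n_extra <- stats::rpois(n, cfg$episode_rate)
    if (sum(n_extra) > 0) {
      pat <- rep(seq_len(n), n_extra)
      idx_adm <- month_index(adm_month)[pat]
      forbidden <- month_index(dis_month)[pat] + 1L
      win_idx <- month_index(survey_months)
      x_adm <- vapply(seq_along(pat), function(i) {
        allowed <- win_idx[win_idx >= idx_adm[i] & win_idx != forbidden[i]]
        if (length(allowed) == 0) NA_integer_
        else if (length(allowed) == 1) allowed
        else sample(allowed, 1L)
      }, integer(1))
      pat <- pat[!is.na(x_adm)]
      x_adm <- x_adm[!is.na(x_adm)]
      m <- length(pat)
      if (m > 0) {
        x_spec <- draw_specialty(m, cfg, hospital[pat])
        x_dspec <- ifelse(stats::runif(m) < 0.97, x_spec,
                          draw_specialty(m, cfg, hospital[pat]))
        x_los <- draw_los(m, cfg$los_distribution, x_dspec)
        extras <- tibble::tibble(
          pseudo_id = patients$pseudo_id[pat],
          age = age[pat], sex = sex[pat],
          residence_district = district[pat],
          admission_source = draw_source(x_spec, cfg$specialty_groups),
          admission_month = month_from_index(x_adm),
          discharge_month = month_from_index(x_adm + draw_spill(x_los)),
          admission_specialty = x_spec, discharge_specialty = x_dspec,
          discharge_hospital = hospital[pat], length_of_stay = x_los,
          cssa_flag = cssa[pat],
          discharge_destination = ifelse(stats::runif(m) < 0.93,
                                         "home", "other"),
          .role = "extra")
      }
    }

    episodes <- dplyr::bind_rows(index,
                                 extras,
                                 readmit(flag_ae, "ae"),
                                 readmit(flag_opd, "opd"),
                                 readmit(flag_other, "other"))
    # the extract covers episodes admitted inside the study months
    keep <- episodes$admission_month %in% cfg$study_months
    episodes <- episodes[keep, , drop = FALSE]
    episodes <- dplyr::arrange(episodes, .data$pseudo_id,
                               month_index(.data$admission_month))
    episodes$episode_id <- sprintf("E%07d", seq_len(nrow(episodes)))
    episodes$diagnosis_code <- sprintf("D%03d", sample.int(400L, nrow(episodes),
                                                           replace = TRUE))
    episodes$procedure_code <- sprintf("PR%03d", sample.int(250L, nrow(episodes),
                                                            replace = TRUE))
  })

  structure(list(patients = patients, episodes = episodes, config = cfg),
            class = "pes_population")
}

#' @export
print.pes_population <- function(x, ...) {
  cat("<pes_population> ", nrow(x$patients), " patients, ",
      nrow(x$episodes), " episodes, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Emit the admissions dataset
#'
#' One row per admission episode carrying the pseudo patient identifier, the
#' ten matching identifiers, the CSSA flag, discharge destination and opaque
#' diagnosis/procedure codes. Row order is randomized (seeded), as an
#' administrative extract would not arrive sorted by patient.
#'
#' @param population A `pes_population`.
#' @return A tibble, CSV-writable, with the documented admission columns.
#' @export
emit_admissions <- function(population) {
  stopifnot(inherits(population, "pes_population"))
  ep <- population$episodes
  withr::with_seed(population$config$seed + 1L, {
    ep <- ep[sample.int(nrow(ep)), , drop = FALSE]
  })
  dplyr::select(ep, "episode_id", dplyr::all_of(admission_columns()))
}

# Internal: the survey frame including the generating pseudo_id. emit_survey
# and true_linkage_oracle both derive from this, under the same seed stream,
# so the anonymous survey and the oracle mapping are always consistent.
survey_frame <- function(population) {
  cfg <- population$config
  ep <- population$episodes
  win <- month_seq(cfg$survey_window[1], cfg$survey_window[2])

  eligible <- ep[ep$discharge_month %in% win &
                   ep$discharge_destination == "home", , drop = FALSE]
  # one voice per patient: the earliest in-window admission
  eligible <- dplyr::arrange(eligible, .data$pseudo_id,
                             month_index(.data$admission_month),
                             .data$episode_id)
  eligible <- eligible[!duplicated(eligible$pseudo_id), , drop = FALSE]

  withr::with_seed(cfg$seed + 2L, {
    take <- stats::runif(nrow(eligible)) < cfg$survey_sampling_fraction
    sv <- eligible[take, , drop = FALSE]
    sv <- dplyr::left_join(sv,
                           population$patients[, c("pseudo_id", "quality_rating",
                                                   "experience_score")],
                           by = "pseudo_id")
    # key discordance: perturb one identifier on a small fraction of rows
    n_err <- stats::rbinom(1L, nrow(sv), cfg$survey_key_error_rate)
    if (n_err > 0) {
      idx <- sample.int(nrow(sv), n_err)
      mode <- sample(c("age", "district", "los"), n_err, replace = TRUE)
      a <- idx[mode == "age"]
      sv$age[a] <- sv$age[a] + sample(c(-1L, 1L), length(a), replace = TRUE)
      d <- idx[mode == "district"]
      if (length(d)) {
        districts <- vocab_district[seq_len(cfg$n_districts)]
        sv$residence_district[d] <- vapply(sv$residence_district[d], function(cur) {
          sample(setdiff(districts, cur), 1L)
        }, character(1))
      }
      l <- idx[mode == "los"]
      sv$length_of_stay[l] <- pmax(1L, sv$length_of_stay[l] +
                                     sample(c(-1L, 1L), length(l), replace = TRUE))
    }
    sv <- sv[sample.int(nrow(sv)), , drop = FALSE]
    sv$survey_id <- sprintf("S%05d", seq_len(nrow(sv)))
  })
  dplyr::select(sv, "survey_id", "pseudo_id", dplyr::all_of(identifier_keys()),
                "quality_rating", "experience_score")
}

#' Emit the anonymous survey dataset
#'
#' Samples at most one eligible index admission per patient (the earliest
#' in-window admission discharged home) at the configured sampling fraction
#' and attaches the two evaluative responses. The emitted table carries NO
#' pseudo patient identifier: anonymity of the survey is the premise of the
#' linkage problem.
#'
#' @param population A `pes_population`.
#' @return A tibble with `survey_id`, the ten identifier-key columns,
#'   `quality_rating` (1-5, 5 best) and `experience_score` (0-10).
#' @export
emit_survey <- function(population) {
  stopifnot(inherits(population, "pes_population"))
  dplyr::select(survey_frame(population), -"pseudo_id")
}

#' Ground-truth linkage oracle
#'
#' Returns the generating patient of every survey row. This mapping is
#' unobservable in a real anonymous survey; it exists only to validate the
#' deterministic linkage (a unique match from an uncorrupted key must agree
#' with it).
#'
#' @param population The `pes_population` the survey was emitted from.
#' @param survey The survey tibble emitted by [emit_survey()].
#' @return Tibble with `survey_id` and true `pseudo_id`, one row per survey
#'   row, in survey order.
#' @export
true_linkage_oracle <- function(population, survey) {
  stopifnot(inherits(population, "pes_population"))
  frame <- survey_frame(population)
  unknown <- setdiff(survey$survey_id, frame$survey_id)
  if (length(unknown)) {
    stop("survey row(s) not generated from this population: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(survey["survey_id"],
                          frame[, c("survey_id", "pseudo_id")],
                          by = "survey_id")
  tibble::as_tibble(out)
}
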