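test_that("Woolf odds ratios reproduce the published crude estimates", {
  # quality of care (high vs low) against any readmission
  q <- odds_ratio_woolf(331, 1022, 85, 308)
  expect_equal(q$or, (331 * 308) / (1022 * 85), tolerance = 1e-12)
  expect_equal(round(q$or, 2), 1.17)
  expect_equal(round(q$ci_low, 2), 0.90)
  expect_equal(round(q$ci_high, 2), 1.54)

  # overall experience (>= 8 vs < 8); these cells give 1.098, reported
  # rounded to 1.09 in the reference table
  e <- odds_ratio_woolf(316, 987, 100, 343)
  expect_equal(e$or, (316 * 343) / (987 * 100), tolerance = 1e-12)
  expect_lt(abs(e$or - 1.09), 0.01)
  expect_equal(round(e$ci_low, 2), 0.85)
  expect_equal(round(e$ci_high, 2), 1.42)

  # medicine+surgery+oncology pooled vs other specialties
  s <- odds_ratio_woolf(334, 833, 82, 497)
  expect_equal(round(s$or, 2), 2.43)
  expect_equal(round(s$ci_low, 2), 1.86)
  expect_equal(round(s$ci_high, 2), 3.17)
})

test_that("odds-ratio identities: symmetry, reciprocity, zero cells", {
  for (k in c(1, 7, 250)) {
    sym <- odds_ratio_woolf(k, k, k, k)
    expect_equal(sym$or, 1)
    expect_equal(log(sym$ci_high), -log(sym$ci_low), tolerance = 1e-12)
  }
  set.seed(33)
  for (i in 1:25) {
    cells <- sample(1:400, 4)
    f <- odds_ratio_woolf(cells[1], cells[2], cells[3], cells[4])
    r <- odds_ratio_woolf(cells[3], cells[4], cells[1], cells[2])
    expect_equal(f$or * r$or, 1, tolerance = 1e-12)
    expect_true(f$ci_low <= f$or && f$or <= f$ci_high)
    expect_equal(f$or, exp(f$log_or), tolerance = 1e-12)
  }
  expect_error(odds_ratio_woolf(0, 5, 5, 5), "degenerate")
  cc <- odds_ratio_woolf(0, 5, 5, 5, continuity = TRUE)
  expect_true(cc$continuity)
  expect_equal(cc$or, (0.5 * 5.5) / (5.5 * 5.5), tolerance = 1e-12)
})

test_that("Pearson chi-square reproduces the length-of-stay association", {
  los <- rbind(readmitted = c(164, 130, 122),
               not = c(713, 349, 268))
  res <- pearson_chi2(los)
  expect_equal(round(res$statistic, 1), 27.5)
  expect_identical(res$df, 2L)
  expect_lt(res$p_value, 0.01)
})

test_that("chi-square identities: hand oracle, 2x2 z-squared, permutations, null", {
  # independent spreadsheet-style oracle: explicit sum over (O-E)^2/E
  hand_chi2 <- function(m) {
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - E)^2 / E)
  }
  set.seed(14)
  for (i in 1:20) {
    m <- matrix(sample(5:200, 6), nrow = 2)
    res <- pearson_chi2(m)
    expect_equal(res$statistic, hand_chi2(m), tolerance = 1e-10)
    expect_identical(res$df, 2L)
    # invariance under row/column permutation
    perm <- m[sample(nrow(m)), sample(ncol(m))]
    expect_equal(pearson_chi2(perm)$statistic, res$statistic,
                 tolerance = 1e-10)
  }

  # any 2x2: statistic equals the squared two-proportion z statistic
  m <- matrix(c(40, 60, 25, 90), nrow = 2, byrow = TRUE)
  p1 <- 40 / 100; p2 <- 25 / 115; pp <- 65 / 215
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 115))
  expect_equal(pearson_chi2(m)$statistic, z^2, tolerance = 1e-10)

  # a table equal to its own expected counts is exactly null
  null_tab <- outer(c(30, 70), c(20, 80)) / 100
  res0 <- pearson_chi2(null_tab)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)

  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), nrow = 2)), "degenerate")
})

test_that("linkage-bias diagnostic builds the matched-status table correctly", {
  # identical distributions (one a scaled copy) give statistic 0
  matched <- rep(1:5, times = c(2, 4, 10, 30, 54))
  unmatched <- rep(1:5, times = 3 * c(2, 4, 10, 30, 54))
  res <- linkage_bias_test(matched, unmatched)
  expect_equal(res$statistic, 0, tolerance = 1e-12)

  # all five quality levels occupied: df 4, as in the reference report
  set.seed(5)
  m <- sample(1:5, 300, replace = TRUE, prob = c(.02, .04, .17, .31, .46))
  u <- sample(1:5, 120, replace = TRUE, prob = c(.05, .05, .20, .30, .40))
  res5 <- linkage_bias_test(m, u)
  expect_identical(res5$df, 4L)
  tab <- attr(res5, "table")
  expect_identical(dim(tab), c(2L, 5L))
  expect_identical(sum(tab), 420L)
  # agrees with pearson_chi2 on the same table
  expect_equal(res5$statistic, pearson_chi2(tab)$statistic, tolerance = 1e-12)

  # configurable binning for the 0-10 score
  res_bin <- linkage_bias_test(c(0:10, 10, 10), c(0:10, 0, 0),
                               binning = c(-0.5, 7.5, 10.5))
  expect_identical(res_bin$df, 1L)
})

test_that("crosstab reproduces the published row percentages", {
  onc <- expand_published_counts("specialty_group", "readmit_any")
  tab <- crosstab(onc, "level", "event")
  row <- tab[tab$level == "oncology", ]
  expect_identical(row$n, 85L)
  expect_identical(row$n_event, 55L)
  expect_equal(round(row$pct, 1), 64.7)
  expect_error(crosstab(onc, "ward", "event"), "unknown variable")

  empty <- crosstab(onc[0, ], "level", "event")
  expect_identical(nrow(empty), 0L)
})

test_that("IRLS matches closed forms: intercept-only and saturated 2x2", {
  dat <- tibble::tibble(y = rep(c(1L, 0L), times = c(37, 163)))
  fit <- fit_logistic_irls(y ~ 1, dat)
  expect_equal(unname(fit$coefficients), qlogis(37 / 200), tolerance = 1e-10)
  expect_equal(fit$r2_mcfadden, 0, tolerance = 1e-12)

  # single binary covariate on the quality 2x2: exp(beta) is the crude OR
  # and the Wald CI equals the Woolf CI, to at least 6 significant figures
  d <- expand_2x2(331, 1022, 85, 308)
  fit2 <- fit_logistic_irls(event ~ exposed, d)
  woolf <- odds_ratio_woolf(331, 1022, 85, 308)
  expect_equal(exp(fit2$coefficients[["exposed"]]), woolf$or,
               tolerance = 1e-7)
  expect_equal(fit2$or_table$ci_low[2], woolf$ci_low, tolerance = 1e-6)
  expect_equal(fit2$or_table$ci_high[2], woolf$ci_high, tolerance = 1e-6)
})

test_that("IRLS agrees with the reference GLM fitter on a real design", {
  linked <- linked_fixture()
  fit <- readmission_model(linked, outcome = "opd", experience = "quality")
  dat <- analysis_factors(linked)
  ref <- stats::glm(readmit_opd ~ sex + age_group + los_group + cssa +
                      specialty_group + quality_high,
                    data = dat, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_true(fit$converged)
  # covariance symmetric positive definite, CIs bracket the ORs
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > 0))
  expect_true(all(fit$or_table$ci_low <= fit$or_table$or &
                    fit$or_table$or <= fit$or_table$ci_high))
  expect_gte(fit$r2_mcfadden, 0)
  expect_lt(fit$r2_mcfadden, 1)
  expect_gt(fit$r2_nagelkerke, fit$r2_mcfadden)  # holds for these data
})

test_that("IRLS refuses separation and rank deficiency", {
  sep <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                        y = c(rep(0L, 20), rep(1L, 20)))
  expect_error(fit_logistic_irls(y ~ x, sep), "separation")

  dd <- tibble::tibble(x1 = rnorm(50), y = rbinom(50, 1, 0.4))
  dd$x2 <- 2 * dd$x1
  expect_error(fit_logistic_irls(y ~ x1 + x2, dd), "x2")
})

test_that("fitted coefficients recover the generating log-odds at n = 5000", {
  cfg <- cohort_config(n_patients = 5000, survey_sampling_fraction = 1,
                       survey_key_error_rate = 0, seed = 11)
  pop <- generate_population(cfg)
  sv <- filter_survey_eligible(emit_survey(pop))
  cand <- filter_admission_candidates(emit_admissions(pop))
  res <- link_deterministic(sv, cand)
  linked <- derive_covariates(
    flag_readmissions(linked_patients(res, sv, cand), emit_admissions(pop)))

  term_map <- c("(Intercept)" = "intercept", "sexfemale" = "sex_female",
                "age_group55-64" = "age_55_64", "age_group65-74" = "age_65_74",
                "age_group75+" = "age_75p", "los_group4-7 days" = "los_4_7",
                "los_group8+ days" = "los_8p", "cssayes" = "cssa_yes",
                "specialty_groupmedicine" = "spec_medicine",
                "specialty_grouponcology" = "spec_oncology",
                "specialty_groupsurgery" = "spec_surgery",
                "quality_highhigh" = "quality_high")
  truth <- cfg$outcome_coefficients
  for (model in c("ae", "opd")) {
    fit <- readmission_model(linked, outcome = model, experience = "quality")
    beta_true <- truth[[model]][term_map[names(fit$coefficients)]]
    z <- (fit$coefficients - beta_true) / fit$se
    expect_lt(max(abs(z)), 3)
  }
})

test_that("McFadden R2 grows when a truly associated covariate is added", {
  linked <- linked_fixture()
  dat <- analysis_factors(linked)
  base <- fit_logistic_irls(readmit_any ~ sex, dat)
  fuller <- fit_logistic_irls(readmit_any ~ sex + specialty_group + los_group,
                              dat)
  expect_gt(fuller$r2_mcfadden, base$r2_mcfadden)
})

test_that("model tables mark references and star intervals excluding 1", {
  linked <- linked_fixture()
  fits <- list(any = readmission_model(linked, "any", "quality"),
               opd = readmission_model(linked, "opd", "quality"))
  tab <- model_tables(fits)

  refs <- tab[tab$level %in% c("male", "45-54", "1-3 days", "no", "others",
                               "low"), ]
  expect_true(all(refs$any == "Ref" & refs$opd == "Ref"))

  # stars exactly where the fitted interval excludes 1
  ot <- fits$opd$or_table
  onc <- tab[tab$level == "oncology", ]
  j <- match("specialty_grouponcology", ot$term)
  should_star <- ot$ci_low[j] > 1 || ot$ci_high[j] < 1
  expect_identical(grepl("\\*$", onc$opd), should_star)
  expect_match(tab$any[tab$variable == "(Intercept)"], "^[0-9.]+ \\(")
})
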