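---
title: "Linking anonymous patient-experience surveys to admissions data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking anonymous patient-experience surveys to admissions data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peslink)
```

## The problem

Patient-experience surveys are run anonymously, by design: responses must
not flow back into the clinical record. That anonymity makes it impossible
to ask, directly, whether the experience a patient reports predicts what
happens to them next — for instance whether they are back in hospital a
month later. `peslink` implements the workaround used at health-system
level in Hong Kong: deterministic record linkage. Both the survey extract
and the administrative admissions extract carry the same ten
quasi-identifiers — age, sex, residence district, admission source, month
of admission, month of discharge, admission specialty, discharge
specialty, discharge hospital and length of stay — and a survey record
that agrees *exactly* on all ten with *exactly one* admission episode can
be attached to that episode (and, through the admissions extract's pseudo
patient identifier, to the patient's longitudinal history) without any
direct identifier changing hands.

The package covers the full chain: standardization and eligibility
filtering, the exact-match linkage with its three-way classification
(unique / one-to-many / unmatched), linkage-bias diagnostics, construction
of next-calendar-month readmission outcomes by admission source, and the
crude and adjusted association analysis. Because the real datasets are
confidential, the package also ships a seeded synthetic generator that
emulates their joint structure, so every stage is exercised end-to-end by
ordinary tests.

## Linkage model and its consequences

Linkage is deterministic: a candidate set for a survey row is every
admission episode equal on all key fields after standardization, with no
fuzzy tolerance. Three outcomes partition the survey:

* exactly one candidate — a **unique (1:1) match**, carried forward to
  analysis;
* two or more — a **one-to-many (1:M) match**, excluded from analysis (no
  tie-breaking is attempted; none is defensible without extra
  information), but retained in the diagnostics denominator;
* none — **unmatched**.

One design point the classification leaves open is *reverse* multiplicity:
a single episode may be the unique candidate of two different survey rows.
One episode cannot belong to two respondents, so `link_deterministic()`
demotes all survey rows involved to the one-to-many class and reports them
separately (`reverse_demoted`) so the effect is auditable. This situation
is impossible when survey keys are faithful copies of episode keys (the
episode's own key then matches itself for only one respondent), but
becomes possible under key discordance.

Because matching is exact, any disagreement in any field — a birthday
between interview and admission, a district move, a transcription slip —
silently sends a truly-linkable record to the unmatched class. The package
therefore treats the matched/unmatched comparison of the two evaluative
scores (`linkage_bias_test()`, a Pearson chi-square on the 2 × k
matched-status × score table) as a first-class diagnostic: if linkage
success is informative about the score, the linked subset is a biased
sample.

## Outcomes

The readmission construct is *any admission episode of the same pseudo
patient admitted in the calendar month following the index discharge
month*, excluding the index episode itself; month granularity is all the
source data supports (the usual 28- or 30-day definitions are out of
reach). `readmit_ae` (Accident & Emergency — unplanned) and `readmit_opd`
(outpatient referral — planned) flag the admission source; they overlap,
and other sources (e.g. inter-hospital transfer) count toward
`readmit_any` only. The window is keyed to the index **discharge** month:
the survey samples discharges, and readmission-after-discharge is the
construct of interest. Multiple readmissions in the window count once
(patient-level binary outcomes).

Covariates are binned as in the reference analysis: age 45–54 / 55–64 /
65–74 / 75+; length of stay 1–3 / 4–7 / 8+ days (the bins must partition,
so a 7-day stay is in the middle bin); discharge specialty grouped to
Medicine / Surgery / Oncology / Others through a configurable dictionary.
The two exposures are dichotomized: quality of care at "Good" or better
(top two of five levels) and the 0–10 experience score at the cohort
median of 8.

## Statistical layer

* **Crude odds ratios** use the Woolf construction: OR = ad/bc with
  `se(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)` and 95% limits
  `exp(log OR ± 1.96 se)`. This choice is not arbitrary: re-deriving the
  published crude intervals from the published table cells reproduces them
  exactly (e.g. 331/1022 vs 85/308 gives 1.17, 0.90–1.54), which rules out
  exact or profile-likelihood intervals. Zero cells raise an error unless
  the Haldane–Anscombe 0.5 correction is explicitly requested, and the
  correction is flagged in the result.
* **Pearson chi-square** is the plain `sum((O-E)^2/E)` with no continuity
  correction for any table size — again pinned down by arithmetic: the
  published length-of-stay statistic (27.5) is only reproduced without
  correction.
* **Logistic regression** is fitted by Newton–Raphson/IRLS written out in
  the package (`fit_logistic_irls()`), not by a wrapped black box, so the
  fitting path is auditable: start at zero, solve the weighted
  least-squares step with weights `mu(1-mu)`, stop when the relative
  log-likelihood change drops below `1e-10` (default; `max_iter` 100).
  Wald 95% intervals come from the inverse observed information. The
  reference fitter (`stats::glm`) appears in the test suite as an
  independent cross-check, never in the shipped path. Two guards refuse to
  report estimates: perfect separation (detected as a diverging linear
  predictor, |eta| > 30) and rank deficiency (reported with the names of
  the collinear columns).
* **Pseudo-R²**: the reference report's "R squared" for these models
  (0.051–0.072) does not say which pseudo-R² it is, so the fit reports
  both McFadden's `1 - l/l0` and Nagelkerke's rescaled Cox–Snell rather
  than guessing.
* Significance is two-sided at 0.05, with no multiplicity correction —
  matching the analysis being reproduced, which applies none.

## The synthetic generator: what it emulates, and what it does not

`cohort_config()` defaults encode the study conditions of the reference
cohort: seven acute hospitals over seven clusters, 18 districts, index
discharges October–December 2013 with January 2014 observable for
December readmissions, about 79% of respondents aged 45+, a 45+ age
distribution with median ≈ 65 (IQR ≈ 56–76), median length of stay 4
days, CSSA welfare prevalence ≈ 13%, experience score mean ≈ 8.1 (SD ≈
1.5), and ≈ 77.5% of quality ratings in the top two levels.

Readmission is generated from three *independent* logistic models on the
analysis covariates — A&E, outpatient, and a small intercept-only
"other-source" model — and `readmit_any` is their union. Generating a
fourth, marginal "any" model as well would contradict the identity
`any = ae | opd | other`, so the union is derived instead; the covariate
log-odds of the A&E and outpatient models are the logs of the reference
cohort's adjusted odds ratios (e.g. 1.54 for high quality on outpatient
readmission, 3.25 for age 75+ on A&E readmission). The model intercepts
are calibrated so the *marginal* source-specific rates land near the
observed ones (≈ 8% A&E, ≈ 17% outpatient, ≈ 24% any): a fitted
intercept does not transport directly because averaging over the
covariate mix is not the same as evaluating at the reference level.

Two structural choices deserve emphasis:

* **Key-collision calibration.** The only public fact about the real key
  distribution is its outcome: about 35% of eligible survey records
  matched more than one episode. Per-identifier frequencies are not
  published. The generator therefore treats the identifier marginals and
  their correlations (district-to-cluster hospital allocation,
  hospital-specific case mix, specialty-dependent stay lengths and
  admission sources, multiple episodes per patient at `episode_rate`) as
  a calibration surface, concentrated until the brute-force key-frequency
  count over a default-size run (10,000 patients) puts the share of 45+
  survey keys with two or more admission candidates in the 0.25–0.45
  band. The calibrated defaults land near 0.28–0.31.
* **Key discordance.** With survey keys copied verbatim from the truth,
  the unmatched class cannot occur — every key matches at least its own
  episode. The real study saw ~2.5% unmatched, so `survey_key_error_rate`
  (default 0.025) perturbs one identifier (age ±1, a different district,
  or length of stay ±1) on that fraction of survey rows. This is also
  what makes the ground-truth oracle meaningful: unique matches from
  *uncorrupted* keys must agree with it, while corrupted rows may become
  unmatched or, rarely, mismatched — exactly the failure mode exact
  linkage has in the field.

Extra (non-index) episodes are placed so they never fall in the calendar
month right after their own patient's index discharge: that slot is
reserved for the outcome model, keeping the generative readmission signal
identifiable (parameter-recovery tests fit the generated data and expect
each coefficient within 3 standard errors of truth at 5,000 patients).
Dates exist only at month granularity throughout — a day-level field is
deliberately absent, since every downstream rule is monthly. Ward-based
exclusions (psychiatric, obstetric, …) are represented by never generating
such wards.

What the generator does **not** emulate: telephone non-response, item-level
questionnaire structure, realistic diagnosis/procedure codes (they are
opaque tokens), day-level timing, or systematic age discordance between
survey and admission records (both tables receive the same age; if the
real survey recorded age at interview rather than at admission, exact
matching would degrade in ways the synthetic tests cannot reveal). Passing
tests therefore validate the *pipeline's logic* under the stated
conditions, not the field accuracy of deterministic linkage on any real
dataset.

## Numerical and degenerate-input choices

* Months are canonical `"YYYY-MM"` strings; several common dialects are
  parsed, anything else is a reported validation issue.
* `standardize()` collects issues into a report and excludes rows with
  invalid key fields rather than aborting at the first error (linkage
  needs complete keys; silently dropping would hide bias); `strict = TRUE`
  turns issues into errors.
* Zero survey rows yield a defined empty report (`NA` percentages), not a
  division error; empty candidate tables classify everything unmatched.
* Linkage uses a composite-key hash join; results are invariant to row
  order of both inputs, and ties play no role (candidate counting is
  exact).
* The IRLS tolerance (1e-10 relative log-likelihood) is far below any
  scientific meaning; it exists so the 2×2 logistic ≡ crude-OR identity
  holds to at least six significant figures in tests.

## Problem sizes

The shipped tests run the generator at 150–2,500 patients for structural
checks, 5,000 for parameter recovery, and 10,000 (the default, matching
the calibration band) for cohort-profile and reproducibility checks; the
acceptance script runs one 10,000-patient pipeline plus the published-count
arithmetic. A full 10,000-patient run — generation, linkage, outcomes and
all six adjusted models — takes a few seconds on one CPU.

## Known limitations

* The one-to-many class is discarded, as in the reference analysis; if
  multiplicity correlates with experience, the linked subset is biased in
  ways only the score-distribution diagnostic can hint at.
* The "any readmission" category absorbs sources beyond A&E and
  outpatient; published counts do not disambiguate the overlap between
  source categories, so per-source counts are exposed for audit rather
  than resolved.
* Exact matching has no tolerance: one year of age discordance unlinks a
  record. This is a property of the method being implemented, not a bug,
  and is the reason the unmatched class and the bias diagnostic exist.
* The experience-score binning behind the published matched-vs-unmatched
  comparison is not stated; `linkage_bias_test()` takes the binning as an
  argument, with the five native quality levels as the only fixed case.
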