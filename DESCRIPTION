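Package: peslink
Title: Deterministic Linkage of Anonymous Patient-Experience Surveys to
    Hospital Admissions and Next-Month Readmission Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links anonymous patient-experience survey records to hospital
    administrative admission episodes by exact agreement on a ten-variable
    composite identifier key (age, sex, residence district, admission source,
    admission and discharge month, admission and discharge specialty,
    discharge hospital, length of stay), classifies each survey record as
    uniquely matched, one-to-many matched or unmatched, and analyses
    next-calendar-month hospital readmission by admission source for the
    uniquely linked patients. Provides linkage-bias diagnostics (chi-square
    comparison of matched and unmatched score distributions), crude odds
    ratios with Woolf confidence intervals, Pearson chi-square tests, and
    multivariable logistic regression fitted by iteratively reweighted least
    squares with Wald intervals and McFadden/Nagelkerke pseudo-R-squared.
    Includes a seeded synthetic dual-dataset generator emulating the paired
    survey/admissions structure so the whole pipeline is testable without
    confidential patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
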