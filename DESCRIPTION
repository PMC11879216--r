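Package: premicc
Title: Validation Toolkit for the PreMiCC Prognostic Score in Newly
    Diagnosed Crohn's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the PreMiCC score (a 0-6 point prediction score for a
    mild course of Crohn's disease built from age, C-reactive protein,
    endoscopic severity, perianal lesions and complications) and validates it
    against longitudinal treatment-escalation outcomes: study eligibility
    screening, week-8 escalation assessment, time-to-first-escalation
    endpoints, product-limit (Kaplan-Meier) estimation with Greenwood
    variance, the two-sample log-rank test, horizon diagnostic accuracy
    (sensitivity, specificity, predictive values), ROC analysis over the
    integer score, and baseline-table group comparisons. Includes a seeded
    synthetic inception-cohort generator with stratified covariates and
    piecewise-exponential escalation hazards so the whole pipeline can be
    exercised end to end without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
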