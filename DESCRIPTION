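Package: exadiary
Title: Symptom-Diary Detection and Analysis of COPD Exacerbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing daily smartphone symptom diaries from
    patients with chronic obstructive pulmonary disease (COPD).  Detects
    symptom-defined exacerbation events from dichotomous daily symptom
    records using a two-consecutive-day major/minor symptom criterion with
    a seven-day washout and explicit censoring rules, computes per-patient
    diary compliance metrics, classifies events as reported or unreported
    and by self-treatment category, fits a two-level (events within
    patients) random-intercept logistic regression for the probability
    that an event is reported via adaptive Gauss-Hermite quadrature, and
    quantifies health-status change (CAT score) by patient exacerbation
    category.  Includes a synthetic-cohort simulator that generates diary
    streams with injected multi-day symptom episodes, per-patient
    missingness and reporting behaviour, so that the whole pipeline can be
    exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
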