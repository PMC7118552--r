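# exadiary

Detection and analysis of COPD exacerbations from daily smartphone
symptom diaries.

Patients with chronic obstructive pulmonary disease record, every
evening, whether each of seven respiratory symptoms is worse than
their personal baseline — three **major** symptoms (dyspnea, sputum
amount, sputum colour) and four **minor** ones (cough, wheeze, sore
throat, cold) — along with medication changes and healthcare
contacts. Many exacerbations visible in such diaries are never
brought to a physician; quantifying these *unreported* events, what
predicts reporting, and what unreported events cost in health status
is the analysis this package implements, end to end and fully tested,
with a synthetic-cohort simulator standing in for patient data.

## What it computes

**Event detection.** An exacerbation begins on the first of two
consecutive recorded days that each have ≥ 1 major symptom and ≥ 2
symptoms in total, ends on the last worsened day followed by two
recorded symptom-free days, and requires ≥ 7 recorded symptom-free
days before a new onset. Missing days are never treated as
symptom-free: they censor the event (`missing_records`), as do
worsened symptoms persisting > 30 days after onset or the end of the
180-day window. Implemented twice — a linear scan
(`detect_events()`) and an exhaustive reference
(`detect_events_reference()`) — with exact agreement verified on
10,000 random streams.

**Compliance.** Overall compliance = 100 × recorded days / 180;
duration compliance = 100 × inclusive first-to-last span / 180;
30-day-block discontinuation; Wilcoxon / Kruskal–Wallis comparisons
across baseline strata.

**Classification.** Events are *reported* if a healthcare contact
falls within the event window, *treated* by medication flags with
category precedence (antibiotics + corticosteroids > antibiotics >
corticosteroids > bronchodilator increase); patients are partitioned
into no-exacerbation / unreported-only / reported-only / mixed, and
CAT score change is compared across groups among patients with ≥ 60%
compliance (deterioration ≥ 2 points = clinically significant).

**Reporting model.** A two-level random-intercept logistic
regression, events nested in patients,

    logit P(reported) = x'β + σu,  u ~ N(0, 1) per patient,

fitted by adaptive Gauss–Hermite quadrature (21 nodes, per-patient
mode/curvature centring), with Wald CIs and odds-ratio output, plus
univariate screening at p < .10. Validated against brute-force
integration, `glm()` in the zero-variance limit, and `lme4::glmer`.

## Worked example

```r
library(exadiary)

co <- generate_cohort(cohort_config(n_patients = 116), seed = 1)
events     <- detect_all_events(co$diary)
classified <- classify_events(events, co$diary)
tabulate_events(classified)
#> Exacerbation characteristics: 162 events
#>   unreported 114 (70.4%), reported 48 (29.6%)
#> Duration (completed events), median [P25-P75]:
#>   n median q25 q75     status
#>  69      5   3   6     global
#>  40      4   3   5 unreported
#>  29      5   4   7   reported
#> Treated within status:
#>      status n_treated pct_treated
#>  unreported        42    36.84211
#>    reported        44    91.66667
```

The simulated cohort shows the expected structure: most events are
unreported, reported events are longer, and nearly all reported
events are treated. Fitting the reporting model (censored events
enter with their observed, censored duration):

```r
dur <- ifelse(classified$recovery_undetermined,
              classified$censor_day - classified$onset_day + 1,
              classified$duration_days)
fit_reporting_model(classified$reported,
                    data.frame(duration = dur,
                               symptoms = classified$onset_symptom_count),
                    classified$patient_id)
#> Two-level logistic fit: 162 events in 85 patients (AGHQ, 21 nodes)
#>                 OR ci_low ci_high      p
#> (Intercept) 0.0741 0.0139  0.3940 0.0023
#> duration    1.4140 1.1800  1.6943 0.0002
#> symptoms    1.0132 0.6794  1.5110 0.9486
#> random-intercept sd: 0.7841   logLik: -88.1480   converged: TRUE
```

Each additional event day multiplies the odds of reporting (OR for
`duration`); at this cohort size the symptom-count effect is not
resolved — the generator's true values (1.15/day, 1.75/symptom) are
recovered within two standard errors at 1,000 patients, which is what
the test suite checks. A whole run — simulate, compliance, detect,
classify, model, with per-stage CSVs, a manifest and a log — is:

```r
res <- run_pipeline(run_config(simulate = cohort_config(n_patients = 116),
                               seed = 1),
                    "run_out")
res$manifest$stage_counts
```

A thin command-line wrapper with `run`, `simulate`, `detect`,
`classify`, `compliance` and `model` subcommands is installed at
`inst/cli/exadiary.R`.

## Output table schemas

Delimited outputs use stable column orders: diaries as
`patient_id, study_day, <7 symptom flags>, <3 medication flags>,
<4 contact flags>, entry_day`; events as
`patient_id, event_id, onset_day, end_day, duration_days,
recovery_undetermined, censor_reason, censor_day, <7 onset symptom
flags>, onset_symptom_count, severity_bin` (plus `reported, treated,
treatment_category, contact_types` after classification). See the
vignette in `vignettes/exacerbation-diaries.Rmd` for the full model
description, generator calibration and known limitations.
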