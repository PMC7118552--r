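# Diary-stream builders used across the test files.

all_flag_columns <- c(exadiary::symptom_columns,
                      "increased_inhaled_medication", "started_antibiotics",
                      "started_corticosteroids",
                      "contact_scheduled_visit", "contact_unscheduled_visit",
                      "contact_emergency", "contact_hospitalization")

# Build a one-patient diary from a compact day specification.
# `days`: recorded study days.  `symptoms`: named list day -> character
# vector of symptom columns flagged on that day (default none).
make_stream <- function(days, symptoms = list(), patient_id = "P1",
                        flags = list(), n_days = max(days, 0)) {
  if (!length(days)) return(exadiary::empty_diary())
  d <- data.frame(patient_id = patient_id, study_day = as.integer(days))
  for (col in all_flag_columns) d[[col]] <- 0L
  for (day in names(symptoms)) {
    i <- which(d$study_day == as.integer(day))
    d[i, symptoms[[day]]] <- 1L
  }
  for (day in names(flags)) {
    i <- which(d$study_day == as.integer(day))
    d[i, flags[[day]]] <- 1L
  }
  exadiary::as_diary(d, n_days = max(n_days, max(days)))
}

# A run of criterion days (one major + one minor) over `crit_days`,
# recorded on `days`.
criterion_stream <- function(days, crit_days, patient_id = "P1",
                             n_days = max(days)) {
  sym <- stats::setNames(
    rep(list(c("dyspnea", "cough")), length(crit_days)),
    as.character(crit_days)
  )
  make_stream(days, sym, patient_id = patient_id, n_days = n_days)
}

# Random one-patient stream: each day independently missing with
# probability p_missing, each symptom flagged with probability p_sym.
random_stream <- function(n_days, p_missing, p_sym, patient_id = "R1") {
  days <- which(stats::runif(n_days) >= p_missing)
  if (!length(days)) return(exadiary::empty_diary())
  d <- data.frame(patient_id = patient_id, study_day = days)
  for (col in all_flag_columns) d[[col]] <- 0L
  for (s in exadiary::symptom_columns) {
    d[[s]] <- stats::rbinom(length(days), 1L, p_sym)
  }
  exadiary::as_diary(d, n_days = n_days)
}
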