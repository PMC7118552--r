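# Builds a labelled classified-event table and a per-patient event-count
# vector matching the published composition of a 116-patient, 6-month
# frequent-exacerbator diary cohort (262 events).  Used as fixed input
# for arithmetic checks on the tabulation stage.

cohort_event_fixture <- function() {
  # unreported: 163 events, 76 treated (57 bronchodilator increase only,
  # 10 antibiotics only, 9 corticosteroids only), 87 untreated;
  # reported: 99 events, all treated (15 bronchodilator increase only,
  # 47 antibiotics only, 28 antibiotics + corticosteroids, 9 others
  # here coded corticosteroids only)
  spec <- rbind(
    data.frame(reported = FALSE, treatment_category = "bronchodilator_increase_only", n = 57),
    data.frame(reported = FALSE, treatment_category = "antibiotics_only", n = 10),
    data.frame(reported = FALSE, treatment_category = "corticosteroids_only", n = 9),
    data.frame(reported = FALSE, treatment_category = "none", n = 87),
    data.frame(reported = TRUE, treatment_category = "bronchodilator_increase_only", n = 15),
    data.frame(reported = TRUE, treatment_category = "antibiotics_only", n = 47),
    data.frame(reported = TRUE, treatment_category = "antibiotics_plus_corticosteroids", n = 28),
    data.frame(reported = TRUE, treatment_category = "corticosteroids_only", n = 9)
  )
  ev <- spec[rep(seq_len(nrow(spec)), spec$n), c("reported", "treatment_category")]
  n <- nrow(ev)
  ev$patient_id <- sprintf("F%03d", seq_len(n))
  ev$event_id <- 1L
  ev$onset_day <- 10L
  ev$end_day <- 15L
  ev$duration_days <- 6L
  ev$recovery_undetermined <- FALSE
  ev$censor_reason <- "none"
  ev$censor_day <- NA_integer_
  for (s in exadiary::symptom_columns) ev[[s]] <- 0L
  ev$dyspnea <- 1L
  ev$cough <- 1L
  ev$onset_symptom_count <- 2L
  ev$severity_bin <- "2"
  ev$treated <- ev$treatment_category != "none"
  ev$contact_types <- ifelse(ev$reported, "unscheduled_visit", "")
  rownames(ev) <- NULL
  ev
}

# per-patient event counts: 18 patients with none, 26 with one, 25 with
# two, 47 with more than two (2 x 3 and 45 x 4), totalling 262 events
cohort_event_counts <- function() {
  c(rep(0L, 18), rep(1L, 26), rep(2L, 25), rep(3L, 2), rep(4L, 45))
}
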