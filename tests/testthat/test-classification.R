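test_that("a healthcare contact inside the event window marks it reported", {
  st <- criterion_stream(1:15, 3:8, n_days = 15)
  st$contact_unscheduled_visit[st$study_day == 5] <- 1L
  ev <- detect_events(st, n_days = 15)
  cl <- classify_events(ev, st)
  expect_true(cl$reported)
  expect_identical(cl$contact_types, "unscheduled_visit")
})

test_that("contacts outside the event window never attach to the event", {
  st <- criterion_stream(1:20, 3:8, n_days = 20)
  st$contact_emergency[st$study_day == 15] <- 1L   # after the event ended
  ev <- detect_events(st, n_days = 20)
  cl <- classify_events(ev, st)
  expect_false(cl$reported)
  # and a contact on a non-event day never creates an event
  expect_identical(nrow(ev), 1L)
})

test_that("an event with no contact and no medication is unreported and untreated", {
  st <- criterion_stream(1:15, 3:8, n_days = 15)
  cl <- classify_events(detect_events(st, n_days = 15), st)
  expect_false(cl$reported)
  expect_false(cl$treated)
  expect_identical(cl$treatment_category, "none")
})

test_that("self-managed bronchodilator increase counts as treated but unreported", {
  st <- criterion_stream(1:15, 3:8, n_days = 15)
  st$increased_inhaled_medication[st$study_day == 4] <- 1L
  cl <- classify_events(detect_events(st, n_days = 15), st)
  expect_false(cl$reported)
  expect_true(cl$treated)
  expect_identical(cl$treatment_category, "bronchodilator_increase_only")
})

test_that("treatment categories follow the drug-combination precedence", {
  combos <- list(
    list(flags = c("started_antibiotics", "started_corticosteroids"),
         want = "antibiotics_plus_corticosteroids"),
    list(flags = c("started_antibiotics", "increased_inhaled_medication"),
         want = "antibiotics_only"),
    list(flags = c("started_corticosteroids", "increased_inhaled_medication"),
         want = "corticosteroids_only"),
    list(flags = "increased_inhaled_medication",
         want = "bronchodilator_increase_only")
  )
  for (cb in combos) {
    st <- criterion_stream(1:15, 3:8, n_days = 15)
    for (f in cb$flags) st[[f]][st$study_day == 5] <- 1L
    cl <- classify_events(detect_events(st, n_days = 15), st)
    expect_identical(cl$treatment_category, cb$want, label = paste(cb$flags, collapse = "+"))
  }
})

test_that("censored events classify over the window up to the censoring day", {
  st <- criterion_stream(setdiff(1:15, 8), 3:7, n_days = 15)
  st$contact_hospitalization[st$study_day == 6] <- 1L
  ev <- detect_events(st, n_days = 15)
  expect_true(ev$recovery_undetermined)
  cl <- classify_events(ev, st)
  expect_true(cl$reported)
})

test_that("tabulation reproduces hand-computed order statistics and shares", {
  st_list <- lapply(2:11, function(i) {
    # one clean event per patient with duration i (criterion days 3..2+i)
    criterion_stream(1:40, seq(3, 2 + i), patient_id = sprintf("P%02d", i), n_days = 40)
  })
  diary <- do.call(rbind, st_list)
  ev <- detect_all_events(diary, n_days = 40)
  cl <- classify_events(ev, diary)
  tab <- tabulate_events(cl)
  expect_identical(tab$n_events, 10L)
  expect_setequal(ev$duration_days, 2:11)
  gl <- tab$duration[tab$duration$status == "global", ]
  expect_equal(gl$median, 6.5)
  expect_equal(gl$q25, stats::quantile(2:11, 0.25, names = FALSE))
  expect_equal(tab$counts$n, c(10, 0))
})

test_that("the labelled cohort fixture reproduces the published shares", {
  ev <- cohort_event_fixture()
  tab <- tabulate_events(ev)
  expect_equal(round(tab$counts$pct_of_events[tab$counts$status == "unreported"], 1), 62.2)
  expect_equal(round(tab$treated$pct_treated[tab$treated$status == "unreported"], 1), 46.6)
  tr <- tab$treatment
  expect_equal(round(tr$pct_within_status[tr$status == "reported" &
                                            tr$category == "antibiotics_only"], 1), 47.5)
  expect_equal(round(tr$pct_within_status[tr$status == "unreported" &
                                            tr$category == "bronchodilator_increase_only"], 1), 35.0)
  counts <- cohort_event_counts()
  expect_identical(sum(counts), 262L)
  expect_equal(round(100 * mean(counts == 0), 1), 15.5)
})

test_that("patients partition into the four reporting categories", {
  ev <- cohort_event_fixture()[1:4, ]
  ev$patient_id <- c("A", "A", "B", "C")
  ev$reported <- c(TRUE, FALSE, FALSE, TRUE)  # A mixed, B unreported only, C reported only, D none
  comp <- data.frame(patient_id = c("A", "B", "C", "D"),
                     overall_compliance = c(80, 70, 50, 90))
  visits <- data.frame(patient_id = rep(c("A", "B", "C", "D"), 2),
                       visit = rep(c("inclusion", "month6"), each = 4),
                       cat = c(10, 12, 14, 16, 13, 11, 15, 15))
  res <- categorize_patients(ev, comp, visits)
  p <- res$patients
  expect_identical(p$category, c("mixed", "unreported_only", "reported_only", "no_exacerbation"))
  expect_identical(p$eligible_for_cat_analysis, c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(p$cat_change, c(3, -1, 1, -1))
  expect_identical(p$cat_deterioration_mcid, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("patients without a visit record stay categorized but drop from CAT tests", {
  ev <- cohort_event_fixture()[1, ]
  ev$patient_id <- "A"
  comp <- data.frame(patient_id = c("A", "B"), overall_compliance = c(90, 90))
  visits <- data.frame(patient_id = "A", visit = c("inclusion", "month6"), cat = c(10, 15))
  res <- categorize_patients(ev, comp, visits)
  expect_true(is.na(res$patients$cat_change[res$patients$patient_id == "B"]))
})

test_that("reported and unreported counts always sum to the total", {
  set.seed(21)
  co <- generate_cohort(cohort_config(n_patients = 25), seed = 21)
  ev <- detect_all_events(co$diary)
  cl <- classify_events(ev, co$diary)
  expect_identical(sum(cl$reported) + sum(!cl$reported), nrow(cl))
  comp <- compliance_summary(co$diary, patient_ids = co$baseline$patient_id)
  res <- categorize_patients(cl, comp, co$visits)
  expect_identical(nrow(res$patients), nrow(co$baseline))
  expect_true(all(res$patients$category %in%
                    c("no_exacerbation", "unreported_only", "reported_only", "mixed")))
  with_both <- res$patients$n_reported > 0 & res$patients$n_unreported > 0
  expect_identical(res$patients$category == "mixed", with_both)
})
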