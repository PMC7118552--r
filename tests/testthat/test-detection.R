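test_that("criterion day needs one major plus at least one other symptom", {
  cases <- list(
    list(sym = "dyspnea", want = FALSE),                      # major alone
    list(sym = c("sputum_color", "cough"), want = TRUE),      # major + minor
    list(sym = c("dyspnea", "sputum_amount"), want = TRUE),   # two majors
    list(sym = c("wheeze", "cough", "cold", "sore_throat"), want = FALSE),  # minors only
    list(sym = character(0), want = FALSE)
  )
  for (cs in cases) {
    d <- make_stream(1, stats::setNames(list(cs$sym), "1"), n_days = 1)
    expect_identical(unname(is_criterion_day(d)), cs$want, label = paste(cs$sym, collapse = "+"))
  }
})

test_that("a clean six-day episode is detected with inclusive duration", {
  st <- criterion_stream(days = 1:12, crit_days = 3:8, n_days = 12)
  ev <- detect_events(st, n_days = 12)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$onset_day, 3L)
  expect_identical(ev$end_day, 8L)
  expect_identical(ev$duration_days, 6L)
  expect_false(ev$recovery_undetermined)
  expect_identical(ev$onset_symptom_count, 2L)
  expect_identical(ev$severity_bin, "2")
})

test_that("symptom-free and empty streams yield no events", {
  expect_identical(nrow(detect_events(criterion_stream(1:20, integer(0), n_days = 20),
                                      n_days = 20)), 0L)
  expect_identical(nrow(detect_events(empty_diary(), n_days = 20)), 0L)
})

test_that("a single criterion day without a consecutive partner is no onset", {
  st <- criterion_stream(days = 1:10, crit_days = 5, n_days = 10)
  expect_identical(nrow(detect_events(st, n_days = 10)), 0L)
})

test_that("seven recorded free days allow a second event; six do not", {
  # episodes days 2-4 and 12-14: gap days 5-11 = 7 free days
  st <- criterion_stream(days = 1:20, crit_days = c(2:4, 12:14), n_days = 20)
  ev <- detect_events(st, n_days = 20)
  expect_identical(ev$onset_day, c(2L, 12L))
  # episodes days 2-4 and 11-13: gap days 5-10 = 6 free days
  st2 <- criterion_stream(days = 1:20, crit_days = c(2:4, 11:13), n_days = 20)
  ev2 <- detect_events(st2, n_days = 20)
  expect_identical(ev2$onset_day, 2L)
  expect_identical(nrow(ev2), 1L)
})

test_that("the washout requires *recorded* free days: a missing day resets it", {
  # gap of 7 days but one of them unrecorded
  days <- setdiff(1:20, 8)
  st <- criterion_stream(days = days, crit_days = c(2:4, 12:14), n_days = 20)
  ev <- detect_events(st, n_days = 20)
  expect_identical(ev$onset_day, 2L)
  expect_identical(nrow(ev), 1L)
})

test_that("a missing day before termination censors the event", {
  st <- criterion_stream(days = setdiff(1:12, 7), crit_days = 3:6, n_days = 12)
  ev <- detect_events(st, n_days = 12)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$recovery_undetermined)
  expect_identical(ev$censor_reason, "missing_records")
  expect_true(is.na(ev$end_day))
  expect_identical(ev$censor_day, 6L)
})

test_that("one interior symptom-free day does not terminate the event", {
  st <- criterion_stream(days = 1:15, crit_days = c(3:5, 7:8), n_days = 15)
  ev <- detect_events(st, n_days = 15)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$end_day, 8L)
  expect_identical(ev$duration_days, 6L)
})

test_that("single-symptom days prolong an event without meeting the onset criterion", {
  st <- make_stream(1:15, list(`3` = c("dyspnea", "cough"), `4` = c("dyspnea", "cough"),
                               `5` = "cough", `6` = "cough"), n_days = 15)
  ev <- detect_events(st, n_days = 15)
  expect_identical(ev$onset_day, 3L)
  expect_identical(ev$end_day, 6L)
})

test_that("worsened symptoms persisting beyond 30 days censor the event", {
  st <- criterion_stream(days = 1:60, crit_days = 5:45, n_days = 60)
  ev <- detect_events(st, n_days = 60)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$censor_reason, "persisted_over_30_days")
  expect_identical(ev$censor_day, 35L)
})

test_that("symptoms reaching the window end censor with window_end", {
  st <- criterion_stream(days = 1:20, crit_days = 17:20, n_days = 20)
  ev <- detect_events(st, n_days = 20)
  expect_identical(ev$censor_reason, "window_end")
  expect_identical(ev$censor_day, 20L)
})

test_that("events of one patient are disjoint, ordered and onset pairs are criterion days", {
  set.seed(7)
  for (i in 1:200) {
    st <- random_stream(60, p_missing = runif(1, 0, 0.5), p_sym = runif(1, 0.1, 0.5))
    ev <- detect_events(st, n_days = 60)
    if (nrow(ev) < 1) next
    s <- exadiary:::day_states(st, 60)
    expect_true(all(s$criterion[ev$onset_day] & s$criterion[ev$onset_day + 1L]))
    expect_true(all(ev$onset_symptom_count >= 2))
    if (nrow(ev) >= 2) {
      ends <- ifelse(ev$recovery_undetermined, ev$censor_day, ev$end_day)
      expect_true(all(ev$onset_day[-1] > ends[-nrow(ev)]))
    }
  }
})

test_that("scan detector equals the exhaustive reference on random streams", {
  set.seed(101)
  for (i in 1:1500) {
    st <- random_stream(40, p_missing = runif(1, 0, 0.6), p_sym = runif(1, 0.05, 0.5))
    a <- detect_events(st, n_days = 40)
    b <- detect_events_reference(st, n_days = 40)
    expect_equal(a, b, label = sprintf("stream %d", i))
  }
})

test_that("deleting records never creates a new completed event", {
  set.seed(55)
  for (i in 1:200) {
    st <- random_stream(50, p_missing = 0, p_sym = runif(1, 0.1, 0.4))
    full <- detect_events(st, n_days = 50)
    thin <- st[runif(nrow(st)) > 0.25, , drop = FALSE]
    sub <- detect_events(thin, n_days = 50)
    done <- sub[!sub$recovery_undetermined, , drop = FALSE]
    if (!nrow(done)) next
    for (j in seq_len(nrow(done))) {
      match_full <- full[full$onset_day == done$onset_day[j] &
                           !full$recovery_undetermined, , drop = FALSE]
      if (nrow(match_full)) {
        expect_true(done$end_day[j] <= match_full$end_day[1])
      }
    }
  }
})

test_that("multi-patient detection rejects mixed streams per patient", {
  st <- rbind(criterion_stream(1:10, 3:6, patient_id = "A", n_days = 10),
              criterion_stream(1:10, 2:5, patient_id = "B", n_days = 10))
  expect_error(detect_events(st, n_days = 10), "single patient")
  ev <- detect_all_events(st, n_days = 10)
  expect_identical(sort(unique(ev$patient_id)), c("A", "B"))
})
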