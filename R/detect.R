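#' @title Rule-based exacerbation detection
#' @description Segments a patient's daily diary stream into
#'   symptom-defined exacerbation events.  Onset requires the full
#'   symptom criterion (at least one major plus at least one further
#'   symptom) on two consecutive *recorded* days, after an eligible
#'   washout; the event then extends over worsened-symptom days (any
#'   symptom flagged) and ends on the last worsened day that is followed
#'   by two consecutive recorded symptom-free days.  A missing day before
#'   termination is established, persistence of worsened symptoms beyond
#'   30 days after onset, or the end of the observation window each
#'   censor the event (recovery undetermined) with a distinct reason.
#'   A new onset requires at least seven consecutive recorded
#'   symptom-free days after the previous event.  A missing day is never
#'   treated as symptom-free: it cannot serve in the onset pair, the
#'   termination pair, or the washout.
#' @name detection
NULL

# Per-day state vectors over 1..n_days for one patient.
day_states <- function(records, n_days) {
  if (any(duplicated(records$study_day))) {
    stop("diary has duplicate study days; run as_diary() first", call. = FALSE)
  }
  recorded <- worsened <- criterion <- logical(n_days)
  d <- records$study_day
  recorded[d] <- TRUE
  if (nrow(records)) {
    worsened[d] <- symptom_count(records) > 0
    criterion[d] <- is_criterion_day(records)
  }
  list(recorded = recorded, worsened = worsened,
       free = recorded & !worsened, criterion = criterion)
}

# Follow one event from its onset. Returns the event fields plus the day
# at which the main scan resumes.
scan_event <- function(s, onset, n_days, max_duration_days) {
  last_worsened <- onset + 1L   # onset pair days are both worsened
  free_run <- 0L
  d <- onset + 2L
  repeat {
    if (d > n_days) {
      return(list(end_day = NA_integer_, duration = NA_integer_,
                  censored = TRUE, reason = "window_end",
                  censor_day = n_days, resume = n_days + 1L))
    }
    if (!s$recorded[d]) {
      return(list(end_day = NA_integer_, duration = NA_integer_,
                  censored = TRUE, reason = "missing_records",
                  censor_day = d - 1L, resume = d))
    }
    if (s$worsened[d]) {
      if (d > onset + max_duration_days) {
        return(list(end_day = NA_integer_, duration = NA_integer_,
                    censored = TRUE, reason = "persisted_over_30_days",
                    censor_day = onset + max_duration_days, resume = d))
      }
      last_worsened <- d
      free_run <- 0L
    } else {
      free_run <- free_run + 1L
      if (free_run == 2L) {
        return(list(end_day = last_worsened,
                    duration = last_worsened - onset + 1L,
                    censored = FALSE, reason = "none",
                    censor_day = NA_integer_, resume = last_worsened + 1L))
      }
    }
    d <- d + 1L
  }
}

event_row <- function(records, patient_id, onset, ev, event_id) {
  rec <- records[records$study_day == onset, symptom_columns, drop = FALSE]
  n_sym <- symptom_count(rec)
  out <- data.frame(patient_id = patient_id, event_id = event_id,
                    onset_day = onset, end_day = ev$end_day,
                    duration_days = ev$duration,
                    recovery_undetermined = ev$censored,
                    censor_reason = ev$reason, censor_day = ev$censor_day,
                    stringsAsFactors = FALSE)
  out <- cbind(out, rec, row.names = NULL)
  out$onset_symptom_count <- n_sym
  out$severity_bin <- c("2", "3", "4plus")[pmin(n_sym - 1L, 3L)]
  out
}

#' Detect exacerbation events in one patient's diary
#'
#' Linear left-to-right scan implementing the detection rules described
#' under [detection].
#'
#' @param records one patient's deduplicated diary records (see
#'   [as_diary()]).
#' @param n_days observation window length in days.
#' @param washout_days recorded symptom-free days required between the
#'   previous event and a new onset (default 7).
#' @param max_duration_days worsened symptoms persisting beyond this many
#'   days after onset censor the event (default 30).
#' @return data frame with one row per detected event: onset and end
#'   days, duration (inclusive of onset and end days), censoring flag
#'   and reason, onset-day symptom profile, symptom count and severity
#'   bin (`"2"`, `"3"`, `"4plus"` onset symptoms).
#' @examples
#' d <- expand.grid(patient_id = "P1", study_day = 1:12)
#' for (s in symptom_columns) d[[s]] <- 0L
#' d$dyspnea[3:8] <- 1L; d$cough[3:8] <- 1L
#' for (m in c("increased_inhaled_medication", "started_antibiotics",
#'             "started_corticosteroids", "contact_scheduled_visit",
#'             "contact_unscheduled_visit", "contact_emergency",
#'             "contact_hospitalization")) d[[m]] <- 0L
#' detect_events(as_diary(d, n_days = 12), n_days = 12)
#' @export
detect_events <- function(records, n_days = 180, washout_days = 7,
                          max_duration_days = 30) {
  pid <- unique(records$patient_id)
  if (length(pid) > 1) {
    stop("detect_events() expects records from a single patient; use detect_all_events()",
         call. = FALSE)
  }
  if (nrow(records) == 0) return(empty_events())
  n_days <- as.integer(n_days)
  s <- day_states(records, n_days)
  events <- list()
  washed <- TRUE     # window start counts as an eligible washout
  free_run <- 0L
  d <- 1L
  while (d <= n_days) {
    if (!washed) {
      if (s$free[d]) {
        free_run <- free_run + 1L
        if (free_run >= washout_days) washed <- TRUE
      } else {
        free_run <- 0L
      }
    }
    if (washed && d < n_days && s$criterion[d] && s$criterion[d + 1L]) {
      ev <- scan_event(s, d, n_days, as.integer(max_duration_days))
      events[[length(events) + 1L]] <- event_row(records, pid, d, ev,
                                                 length(events) + 1L)
      washed <- FALSE
      free_run <- 0L
      d <- ev$resume
      next
    }
    d <- d + 1L
  }
  if (!length(events)) return(empty_events())
  do.call(rbind, events)
}

#' Detect events for every patient in a diary
#'
#' @param diary validated multi-patient diary (see [as_diary()]).
#' @inheritParams detect_events
#' @return combined event table over all patients, ordered by patient
#'   and onset day.
#' @export
detect_all_events <- function(diary, n_days = 180, washout_days = 7,
                              max_duration_days = 30) {
  parts <- lapply(split(diary, diary$patient_id), detect_events,
                  n_days = n_days, washout_days = washout_days,
                  max_duration_days = max_duration_days)
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) out <- empty_events()
  rownames(out) <- NULL
  out
}

# first index of a run of `len` consecutive TRUEs in x restricted to
# positions >= from; NA when none.  Returns the index at which the run
# *completes* (i.e. the run occupies (idx-len+1)..idx).
run_completion <- function(x, len, from = 1L) {
  n <- length(x)
  if (from > n) return(NA_integer_)
  run <- 0L
  for (i in from:n) {
    run <- if (x[i]) run + 1L else 0L
    if (run >= len) return(i)
  }
  NA_integer_
}

#' Reference exacerbation detector (exhaustive formulation)
#'
#' An independent re-implementation of [detect_events()] used for
#' validation.  Instead of a stateful scan it repeatedly enumerates
#' candidate onset pairs, decides each event's outcome by comparing the
#' positions of the first missing day, the first termination pair and
#' the first over-long worsened day, and recomputes washout eligibility
#' from scratch after every event.  Intended for short streams.
#'
#' @inheritParams detect_events
#' @return event table with the same schema as [detect_events()].
#' @export
detect_events_reference <- function(records, n_days = 180, washout_days = 7,
                                    max_duration_days = 30) {
  pid <- unique(records$patient_id)
  if (length(pid) > 1) stop("reference detector expects a single patient", call. = FALSE)
  if (nrow(records) == 0) return(empty_events())
  n_days <- as.integer(n_days)
  s <- day_states(records, n_days)
  days <- seq_len(n_days)
  pair_ok <- s$criterion & c(s$criterion[-1L], FALSE)   # onset candidate days
  events <- list()
  resume <- 1L            # first day available after the previous event
  had_event <- FALSE
  repeat {
    cand <- days[pair_ok & days >= resume & days < n_days]
    if (had_event) {
      wash_done <- run_completion(s$free, washout_days, from = resume)
      cand <- if (is.na(wash_done)) integer(0) else cand[cand > wash_done]
    }
    if (!length(cand)) break
    o <- cand[1L]
    after <- seq(o + 2L, length.out = max(0L, n_days - o - 1L))
    miss <- after[!s$recorded[after]]
    m <- if (length(miss)) miss[1L] else Inf
    # termination pair completes at day t when t-1 and t are both recorded
    # symptom-free; the earliest possible completion is o+3 (o, o+1 worsened)
    pairs <- after[s$free[after] & s$free[after - 1L]]
    t_done <- if (length(pairs)) pairs[1L] else Inf
    over <- after[s$worsened[after] & after > o + max_duration_days]
    x0 <- if (length(over)) over[1L] else Inf
    deciders <- c(termination = t_done, missing = m, overlong = x0)
    first <- min(deciders)
    if (is.infinite(first)) {
      ev <- list(end_day = NA_integer_, duration = NA_integer_, censored = TRUE,
                 reason = "window_end", censor_day = n_days, resume = n_days + 1L)
    } else if (first == t_done) {
      w <- days[s$worsened & days >= o & days <= t_done - 2L]
      end <- max(w)
      ev <- list(end_day = end, duration = end - o + 1L, censored = FALSE,
                 reason = "none", censor_day = NA_integer_, resume = end + 1L)
    } else if (first == m) {
      ev <- list(end_day = NA_integer_, duration = NA_integer_, censored = TRUE,
                 reason = "missing_records", censor_day = m - 1L, resume = m)
    } else {
      ev <- list(end_day = NA_integer_, duration = NA_integer_, censored = TRUE,
                 reason = "persisted_over_30_days",
                 censor_day = o + max_duration_days, resume = x0)
    }
    events[[length(events) + 1L]] <- event_row(records, pid, o, ev,
                                               length(events) + 1L)
    had_event <- TRUE
    resume <- ev$resume
    if (resume > n_days) break
  }
  if (!length(events)) return(empty_events())
  do.call(rbind, events)
}
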