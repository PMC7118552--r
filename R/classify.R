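#' @title Event classification and patient categorisation
#' @description A detected exacerbation is *reported* when medical
#'   attention was sought during the event (scheduled or unscheduled
#'   doctor visit, emergency department visit or hospital admission) and
#'   *treated* when at least one medication changed (antibiotics,
#'   corticosteroids or an increase in bronchodilators).  Contact and
#'   medication flags attach to an event by window overlap only: flags
#'   recorded outside any event never create one.  Patients are then
#'   placed in four exclusive groups -- no exacerbation, unreported
#'   only, reported only, mixed -- and health-status change (CAT score)
#'   is compared across groups among patients with at least 60% overall
#'   compliance.
#' @name classification
NULL

treatment_levels <- c("none", "bronchodilator_increase_only", "antibiotics_only",
                      "corticosteroids_only", "antibiotics_plus_corticosteroids",
                      "other_combination")

treatment_category <- function(bronch, abx, cort) {
  ifelse(abx & cort, "antibiotics_plus_corticosteroids",
  ifelse(abx, "antibiotics_only",
  ifelse(cort, "corticosteroids_only",
  ifelse(bronch, "bronchodilator_increase_only", "none"))))
}

#' Classify detected events as reported/unreported and by treatment
#'
#' For each event the classification window runs from onset day to the
#' end day, or to the censoring day for censored events.  An event is
#' reported when any healthcare-contact flag occurs on a recorded day
#' within the window, and treated according to the medication flags in
#' the same window, with precedence antibiotics+corticosteroids >
#' antibiotics only > corticosteroids only > bronchodilator increase.
#'
#' @param events event table from [detect_events()] /
#'   [detect_all_events()].
#' @param diary the diary the events were detected from.
#' @return the event table with columns `reported`, `treated`,
#'   `treatment_category` and `contact_types` (semicolon-separated set)
#'   appended.
#' @export
classify_events <- function(events, diary) {
  if (nrow(events) == 0) {
    events$reported <- logical(0); events$treated <- logical(0)
    events$treatment_category <- character(0); events$contact_types <- character(0)
    return(events)
  }
  reported <- treated <- logical(nrow(events))
  category <- contacts <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    eff_end <- if (ev$recovery_undetermined) ev$censor_day else ev$end_day
    if (is.na(eff_end)) stop("event has no usable window end", call. = FALSE)
    win <- diary[diary$patient_id == ev$patient_id &
                   diary$study_day >= ev$onset_day &
                   diary$study_day <= eff_end, , drop = FALSE]
    if (nrow(win) == 0) {
      stop(sprintf("event window [%d,%d] for patient %s has no diary records",
                   ev$onset_day, eff_end, ev$patient_id), call. = FALSE)
    }
    ct <- contact_columns[colSums(win[contact_columns]) > 0]
    reported[i] <- length(ct) > 0
    contacts[i] <- paste(sub("^contact_", "", ct), collapse = ";")
    category[i] <- treatment_category(
      any(win$increased_inhaled_medication > 0),
      any(win$started_antibiotics > 0),
      any(win$started_corticosteroids > 0)
    )
    treated[i] <- category[i] != "none"
  }
  events$reported <- reported
  events$treated <- treated
  events$treatment_category <- category
  events$contact_types <- contacts
  events
}

#' Characterise events by reporting status
#'
#' Summarises a classified event table in the shape of a
#' reported-versus-unreported characteristics table: counts and shares,
#' duration order statistics (censored events excluded from duration
#' summaries only), onset symptom count, per-symptom prevalence,
#' severity bins and treatment-category breakdown.  Percentages are
#' given both within reporting status (column-wise) and within
#' characteristic (row-wise), explicitly labelled.
#'
#' @param events classified event table from [classify_events()].
#' @return object of class `exa_event_table`: a list of data frames
#'   `counts`, `duration`, `symptom_count`, `symptoms`, `severity`,
#'   `treatment`.
#' @export
tabulate_events <- function(events) {
  if (nrow(events) == 0) stop("no events to tabulate", call. = FALSE)
  status <- ifelse(events$reported, "reported", "unreported")
  n_total <- nrow(events)
  by_status <- function(f) {
    vapply(c(unreported = "unreported", reported = "reported"),
           function(s) f(events[status == s, , drop = FALSE]), numeric(1))
  }
  counts <- data.frame(
    status = c("unreported", "reported"),
    n = as.vector(by_status(nrow)),
    pct_of_events = as.vector(by_status(nrow)) / n_total * 100,
    stringsAsFactors = FALSE
  )

  dur_stats <- function(d) {
    d <- d$duration_days[!d$recovery_undetermined]
    if (!length(d)) return(c(n = 0, median = NA, q25 = NA, q75 = NA))
    c(n = length(d), median = stats::median(d),
      q25 = unname(stats::quantile(d, 0.25)), q75 = unname(stats::quantile(d, 0.75)))
  }
  duration <- as.data.frame(rbind(
    global = dur_stats(events),
    unreported = dur_stats(events[status == "unreported", , drop = FALSE]),
    reported = dur_stats(events[status == "reported", , drop = FALSE])
  ))
  duration$status <- rownames(duration); rownames(duration) <- NULL

  sc_stats <- function(d) c(mean = mean(d$onset_symptom_count),
                            sd = stats::sd(d$onset_symptom_count))
  symptom_count_tbl <- as.data.frame(rbind(
    global = sc_stats(events),
    unreported = sc_stats(events[status == "unreported", , drop = FALSE]),
    reported = sc_stats(events[status == "reported", , drop = FALSE])
  ))
  symptom_count_tbl$status <- rownames(symptom_count_tbl)
  rownames(symptom_count_tbl) <- NULL

  symptoms <- do.call(rbind, lapply(symptom_columns, function(s) {
    present <- events[[s]] > 0
    data.frame(symptom = s,
               n_global = sum(present),
               pct_global = mean(present) * 100,
               n_unreported = sum(present & status == "unreported"),
               pct_within_unreported = 100 * sum(present & status == "unreported") /
                 max(1L, sum(status == "unreported")),
               n_reported = sum(present & status == "reported"),
               pct_within_reported = 100 * sum(present & status == "reported") /
                 max(1L, sum(status == "reported")),
               pct_of_symptom_reported = 100 * sum(present & status == "reported") /
                 max(1L, sum(present)),
               stringsAsFactors = FALSE)
  }))

  severity <- do.call(rbind, lapply(c("2", "3", "4plus"), function(b) {
    inb <- events$severity_bin == b
    data.frame(severity_bin = b,
               n_global = sum(inb),
               pct_global = mean(inb) * 100,
               n_unreported = sum(inb & status == "unreported"),
               pct_within_unreported = 100 * sum(inb & status == "unreported") /
                 max(1L, sum(status == "unreported")),
               n_reported = sum(inb & status == "reported"),
               pct_within_reported = 100 * sum(inb & status == "reported") /
                 max(1L, sum(status == "reported")),
               pct_of_bin_reported = 100 * sum(inb & status == "reported") /
                 max(1L, sum(inb)),
               stringsAsFactors = FALSE)
  }))

  treatment <- do.call(rbind, lapply(c("unreported", "reported"), function(s) {
    sub <- events[status == s, , drop = FALSE]
    data.frame(status = s,
               category = treatment_levels,
               n = vapply(treatment_levels, function(k) sum(sub$treatment_category == k),
                          numeric(1)),
               pct_within_status = vapply(treatment_levels, function(k) {
                 100 * sum(sub$treatment_category == k) / max(1L, nrow(sub))
               }, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  treated_share <- data.frame(
    status = c("unreported", "reported"),
    n_treated = c(sum(events$treated & status == "unreported"),
                  sum(events$treated & status == "reported")),
    pct_treated = c(
      100 * sum(events$treated & status == "unreported") / max(1L, sum(status == "unreported")),
      100 * sum(events$treated & status == "reported") / max(1L, sum(status == "reported"))),
    stringsAsFactors = FALSE
  )

  structure(list(counts = counts, duration = duration,
                 symptom_count = symptom_count_tbl, symptoms = symptoms,
                 severity = severity, treatment = treatment,
                 treated = treated_share, n_events = n_total),
            class = "exa_event_table")
}

#' @export
print.exa_event_table <- function(x, ...) {
  cat(sprintf("Exacerbation characteristics: %d events\n", x$n_events))
  cat(sprintf("  unreported %d (%.1f%%), reported %d (%.1f%%)\n",
              x$counts$n[1], x$counts$pct_of_events[1],
              x$counts$n[2], x$counts$pct_of_events[2]))
  cat("Duration (completed events), median [P25-P75]:\n")
  print(x$duration, row.names = FALSE)
  cat("Treated within status:\n")
  print(x$treated, row.names = FALSE)
  invisible(x)
}

#' Categorise patients by exacerbation reporting status
#'
#' Partitions patients into four exclusive groups -- `no_exacerbation`,
#' `unreported_only`, `reported_only`, `mixed` (at least one of each)
#' -- and computes the CAT score change from the inclusion to the
#' 6-month visit.  Patients with overall compliance below
#' `min_compliance` percent are flagged ineligible for the CAT impact
#' analysis; CAT deterioration of `mcid` points or more (default 2) is
#' flagged as clinically significant.  Among eligible patients with
#' both CAT scores the change is compared across groups with a
#' Kruskal-Wallis test and the deterioration proportion with a
#' chi-square test.
#'
#' @param events classified event table from [classify_events()].
#' @param compliance per-patient table from [compliance_summary()].
#' @param visits visit table with `inclusion` and `month6` CAT scores.
#' @param min_compliance eligibility threshold, percent (default 60).
#' @param mcid minimal clinically important CAT deterioration
#'   (default 2 points).
#' @return list with `patients` (per-patient category table),
#'   `cat_test` (Kruskal-Wallis on CAT change) and `mcid_test`
#'   (chi-square on the deterioration proportion); tests are `NULL`
#'   when fewer than two groups have data.
#' @export
categorize_patients <- function(events, compliance, visits,
                                min_compliance = 60, mcid = 2) {
  pts <- compliance$patient_id
  n_rep <- n_unrep <- integer(length(pts))
  if (nrow(events)) {
    tab_r <- table(factor(events$patient_id[events$reported], levels = pts))
    tab_u <- table(factor(events$patient_id[!events$reported], levels = pts))
    n_rep <- as.integer(tab_r)
    n_unrep <- as.integer(tab_u)
  }
  category <- ifelse(n_rep == 0 & n_unrep == 0, "no_exacerbation",
              ifelse(n_rep > 0 & n_unrep > 0, "mixed",
              ifelse(n_rep > 0, "reported_only", "unreported_only")))

  cat_at <- function(visit) {
    v <- visits[visits$visit == visit, , drop = FALSE]
    v$cat[match(pts, v$patient_id)]
  }
  cat_change <- cat_at("month6") - cat_at("inclusion")

  out <- data.frame(
    patient_id = pts,
    n_events = n_rep + n_unrep,
    n_reported = n_rep,
    n_unreported = n_unrep,
    category = category,
    overall_compliance = compliance$overall_compliance,
    eligible_for_cat_analysis = compliance$overall_compliance >= min_compliance,
    cat_change = cat_change,
    cat_deterioration_mcid = !is.na(cat_change) & cat_change >= mcid,
    stringsAsFactors = FALSE
  )

  use <- out$eligible_for_cat_analysis & !is.na(out$cat_change)
  cat_test <- mcid_test <- NULL
  if (length(unique(out$category[use])) >= 2) {
    cat_test <- tryCatch(compare_groups(out$cat_change[use], out$category[use]),
                         error = function(e) NULL)
    tab <- table(out$category[use], out$cat_deterioration_mcid[use])
    mcid_test <- tryCatch(chi_square_test(unclass(t(tab))), error = function(e) NULL)
  }
  list(patients = out, cat_test = cat_test, mcid_test = mcid_test)
}
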