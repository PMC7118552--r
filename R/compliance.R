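#' @title Diary compliance metrics
#' @description Two per-patient adherence measures over a fixed
#'   observation window (180 available days by default, hospitalisation
#'   days included): *overall compliance*, the percentage of available
#'   days on which a diary record exists, and *duration compliance*, the
#'   inclusive span from first to last recorded day as a percentage of
#'   available days.  Overall compliance can never exceed duration
#'   compliance.
#' @name compliance
NULL

#' Overall compliance
#'
#' @param records one patient's deduplicated diary records.
#' @param available_days number of available days in the window
#'   (default 180).
#' @return percentage in \[0, 100\]: `100 * distinct recorded days /
#'   available_days`.
#' @export
overall_compliance <- function(records, available_days = 180) {
  stopifnot(available_days > 0)
  100 * length(unique(records$study_day)) / available_days
}

#' Duration compliance
#'
#' The span is inclusive (`last - first + 1`), so a diary kept from day
#' 1 through day 180 scores exactly 100%.
#'
#' @inheritParams overall_compliance
#' @return percentage in \[0, 100\]; 0 when the patient has no records.
#' @export
duration_compliance <- function(records, available_days = 180) {
  stopifnot(available_days > 0)
  if (nrow(records) == 0) return(0)
  100 * (max(records$study_day) - min(records$study_day) + 1) / available_days
}

#' Month of diary discontinuation
#'
#' Months are consecutive 30-day blocks of study time (patients enrol on
#' different calendar dates).  A patient discontinues in the month
#' containing their last record when recording stops before the end of
#' the window; a patient whose records extend to the final day (within
#' `grace` days) is not a discontinuer.  A patient with no records at
#' all is assigned month 1 and flagged as never having started.
#'
#' @inheritParams overall_compliance
#' @param n_days window length (default 180).
#' @param grace days short of `n_days` still counted as completing the
#'   study (default 0).
#' @return list with `month` (integer 1..6 or `NA` for completers) and
#'   `never_started` flag.
#' @export
discontinuation_month <- function(records, n_days = 180, grace = 0) {
  if (nrow(records) == 0) return(list(month = 1L, never_started = TRUE))
  last <- max(records$study_day)
  if (last >= n_days - grace) return(list(month = NA_integer_, never_started = FALSE))
  list(month = as.integer(ceiling(last / 30)), never_started = FALSE)
}

#' Per-patient compliance summary table
#'
#' @param diary validated multi-patient diary.
#' @param available_days available days per patient (default 180).
#' @param patient_ids optional vector of patients to summarise;
#'   patients absent from the diary get zero-record summaries.  Defaults
#'   to the patients present in the diary.
#' @return data frame with one row per patient: days recorded, overall
#'   and duration compliance (percent), first/last recorded day,
#'   discontinuation month.
#' @export
compliance_summary <- function(diary, available_days = 180, patient_ids = NULL) {
  if (is.null(patient_ids)) patient_ids <- sort(unique(diary$patient_id))
  rows <- lapply(patient_ids, function(p) {
    rec <- diary[diary$patient_id == p, , drop = FALSE]
    disc <- discontinuation_month(rec, n_days = available_days)
    data.frame(
      patient_id = p,
      days_recorded = length(unique(rec$study_day)),
      available_days = available_days,
      overall_compliance = overall_compliance(rec, available_days),
      first_day = if (nrow(rec)) min(rec$study_day) else NA_integer_,
      last_day = if (nrow(rec)) max(rec$study_day) else NA_integer_,
      duration_compliance = duration_compliance(rec, available_days),
      discontinued_month = disc$month,
      never_started = disc$never_started,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a metric across patient strata
#'
#' Nonparametric group comparison: Wilcoxon rank-sum for two groups
#' (exact enumeration when both groups have eight or fewer tie-free
#' observations, tie-corrected normal approximation otherwise) and
#' Kruskal-Wallis for three or more groups.  Two-sided throughout.
#'
#' @param values numeric per-patient metric.
#' @param groups stratum label per patient.
#' @return list with `method`, `statistic`, `p.value` and a `summary`
#'   data frame of per-group n, median and quartiles (P25, P75).
#' @examples
#' compare_groups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
#' @export
compare_groups <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  split_vals <- split(values, groups)
  if (length(split_vals) < 2) stop("need at least two groups", call. = FALSE)
  if (any(lengths(split_vals) == 0)) stop("empty group", call. = FALSE)

  summary_df <- data.frame(
    group = names(split_vals),
    n = lengths(split_vals),
    median = vapply(split_vals, stats::median, numeric(1)),
    q25 = vapply(split_vals, stats::quantile, numeric(1), probs = 0.25, names = FALSE),
    q75 = vapply(split_vals, stats::quantile, numeric(1), probs = 0.75, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )

  if (length(split_vals) == 2) {
    x <- split_vals[[1]]; y <- split_vals[[2]]
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    ht <- stats::wilcox.test(x, y, exact = exact, correct = FALSE)
    method <- if (exact) "mann-whitney-exact" else "mann-whitney-normal"
  } else {
    ht <- stats::kruskal.test(values, factor(groups))
    method <- "kruskal-wallis"
  }
  list(method = method, statistic = unname(ht$statistic),
       df = unname(ht$parameter), p.value = ht$p.value, summary = summary_df)
}

#' Stratified compliance comparison table
#'
#' Compares overall and duration compliance across every stratification
#' column supplied, producing one block per stratum variable.
#'
#' @param summary per-patient compliance table from
#'   [compliance_summary()].
#' @param baseline baseline table with `patient_id` and the
#'   stratification columns.
#' @param strata character vector of baseline column names to stratify
#'   by; defaults to every non-`patient_id` column that has 2--5 levels.
#' @return data frame with one row per stratum level and metric:
#'   median, quartiles and the group-comparison p-value.
#' @export
compliance_by_strata <- function(summary, baseline, strata = NULL) {
  merged <- merge(summary, baseline, by = "patient_id")
  if (is.null(strata)) {
    cand <- setdiff(names(baseline), "patient_id")
    strata <- cand[vapply(cand, function(v) {
      k <- length(unique(stats::na.omit(merged[[v]])))
      k >= 2 && k <= 5
    }, logical(1))]
  }
  blocks <- list()
  for (v in strata) {
    for (metric in c("overall_compliance", "duration_compliance")) {
      res <- tryCatch(compare_groups(merged[[metric]], merged[[v]]),
                      error = function(e) NULL)
      if (is.null(res)) next
      blk <- res$summary
      blk$variable <- v
      blk$metric <- metric
      blk$p.value <- res$p.value
      blocks[[length(blocks) + 1L]] <- blk
    }
  }
  out <- do.call(rbind, blocks)
  if (is.null(out)) return(out)
  out[c("variable", "metric", "group", "n", "median", "q25", "q75", "p.value")]
}
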