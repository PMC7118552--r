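#' @title End-to-end pipeline
#' @description Runs simulate (or ingest) -> compliance -> detect ->
#'   classify -> model as one reproducible unit, writing per-stage
#'   delimited outputs, a JSON manifest (versions, seed, input digests,
#'   per-stage row counts) and a plain-text log.  Identical config and
#'   seed give byte-identical outputs.
#' @name pipeline
NULL

# Deterministic per-stage seed derivation: stage seeds are offsets of
# the run seed keyed by the stage name, so any stage can be re-run in
# isolation.  Kept below 2^31.
derive_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 7919L) %% 2147483647L
}

#' Assemble a pipeline run configuration
#'
#' Exactly one of `simulate` (a [cohort_config()]) or `inputs` (paths
#' to diary/baseline/visit files) must be given.
#'
#' @param simulate optional [cohort_config()] for a simulated run.
#' @param inputs optional named list with `diary`, `baseline`, `visits`
#'   file paths.
#' @param n_days observation window (default 180).
#' @param washout_days,max_duration_days detection options.
#' @param min_compliance CAT-analysis eligibility threshold (percent).
#' @param nodes quadrature nodes for the reporting model.
#' @param screening_alpha univariate selection threshold (default .10).
#' @param seed run seed.
#' @return list of class `exa_run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL, n_days = 180,
                       washout_days = 7, max_duration_days = 30,
                       min_compliance = 60, nodes = 21,
                       screening_alpha = 0.10, seed = 1) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of 'simulate' or 'inputs' must be supplied", call. = FALSE)
  }
  stopifnot(screening_alpha > 0, screening_alpha < 1)
  if (!is.null(inputs)) {
    need <- setdiff(c("diary", "baseline", "visits"), names(inputs))
    if (length(need)) stop(sprintf("inputs lacks: %s", paste(need, collapse = ", ")),
                           call. = FALSE)
  }
  structure(list(simulate = simulate, inputs = inputs, n_days = n_days,
                 washout_days = washout_days,
                 max_duration_days = max_duration_days,
                 min_compliance = min_compliance, nodes = nodes,
                 screening_alpha = screening_alpha, seed = as.integer(seed)),
            class = "exa_run_config")
}

#' Read a run configuration from YAML
#'
#' The file may contain a `simulate:` section (keys as in
#' [cohort_config()]) or an `inputs:` section (`diary`, `baseline`,
#' `visits` paths) plus any top-level option of [run_config()].
#'
#' @param path YAML file.
#' @return `exa_run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) sim <- do.call(cohort_config, y$simulate)
  opts <- y[setdiff(names(y), c("simulate", "inputs"))]
  do.call(run_config, c(list(simulate = sim, inputs = y$inputs), opts))
}

write_csv_stable <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' @param config an `exa_run_config` (see [run_config()]) or the path
#'   to a YAML file for [read_run_config()].
#' @param out_dir output directory, created if needed.
#' @return the run manifest (also written to `manifest.json`),
#'   invisibly a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "exa_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)  # truncate

  logf("stage=config seed=%d n_days=%d washout=%d max_duration=%d nodes=%d alpha=%.2f",
       config$seed, config$n_days, config$washout_days,
       config$max_duration_days, config$nodes, config$screening_alpha)

  ## stage 1: data
  truth <- NULL
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate, seed = derive_seed(config$seed, "simulate"))
    diary <- cohort$diary; baseline <- cohort$baseline; visits <- cohort$visits
    truth <- cohort$truth
    write_csv_stable(truth$episodes, file.path(out_dir, "truth_episodes.csv"))
    n_days <- config$simulate$n_days
  } else {
    diary <- read_diary(config$inputs$diary, n_days = config$n_days)
    baseline <- read_baseline(config$inputs$baseline)
    visits <- read_visits(config$inputs$visits)
    n_days <- config$n_days
  }
  write_diary(diary, file.path(out_dir, "diary.csv"))
  write_csv_stable(baseline, file.path(out_dir, "baseline.csv"))
  write_csv_stable(visits, file.path(out_dir, "visits.csv"))
  logf("stage=data patients=%d records=%d", length(unique(diary$patient_id)), nrow(diary))

  ## stage 2: compliance
  comp <- compliance_summary(diary, available_days = n_days,
                             patient_ids = sort(baseline$patient_id))
  comp_strata <- compliance_by_strata(comp, baseline)
  write_csv_stable(comp, file.path(out_dir, "compliance.csv"))
  if (!is.null(comp_strata)) {
    write_csv_stable(comp_strata, file.path(out_dir, "compliance_by_strata.csv"))
  }
  logf("stage=compliance patients=%d median_overall=%.1f", nrow(comp),
       stats::median(comp$overall_compliance))

  ## stage 3: detection
  events <- detect_all_events(diary, n_days = n_days,
                              washout_days = config$washout_days,
                              max_duration_days = config$max_duration_days)
  write_events(events, file.path(out_dir, "events.csv"))
  logf("stage=detect events=%d censored=%d", nrow(events),
       sum(events$recovery_undetermined))

  ## stage 4: classification
  classified <- classify_events(events, diary)
  write_events(classified, file.path(out_dir, "events_classified.csv"))
  event_table <- if (nrow(classified)) tabulate_events(classified) else NULL
  if (!is.null(event_table)) {
    write_csv_stable(event_table$symptoms, file.path(out_dir, "event_symptoms.csv"))
    write_csv_stable(event_table$severity, file.path(out_dir, "event_severity.csv"))
    write_csv_stable(event_table$treatment, file.path(out_dir, "event_treatment.csv"))
  }
  categories <- categorize_patients(classified, comp, visits,
                                    min_compliance = config$min_compliance)
  write_csv_stable(categories$patients, file.path(out_dir, "patient_categories.csv"))
  logf("stage=classify events=%d reported=%d", nrow(classified),
       sum(classified$reported))

  ## stage 5: reporting model
  model <- NULL
  if (nrow(classified) >= 10 && length(unique(classified$patient_id)) >= 2 &&
      length(unique(classified$reported)) == 2) {
    cand <- data.frame(
      duration = ifelse(classified$recovery_undetermined,
                        classified$censor_day - classified$onset_day + 1,
                        classified$duration_days),
      symptom_count = classified$onset_symptom_count
    )
    bl <- baseline[match(classified$patient_id, baseline$patient_id), , drop = FALSE]
    if ("n_comorbidities" %in% names(bl)) cand$comorbidities_ge3 <- as.integer(bl$n_comorbidities >= 3)
    if ("cat_baseline" %in% names(bl)) cand$cat_ge10 <- as.integer(bl$cat_baseline >= 10)
    if ("mmrc" %in% names(bl)) cand$mmrc_ge2 <- as.integer(bl$mmrc >= 2)
    if ("anxiety" %in% names(bl)) cand$anxiety <- as.integer(bl$anxiety)
    screen <- univariate_screen(classified$reported, cand, classified$patient_id,
                                alpha = config$screening_alpha, nodes = config$nodes)
    sel <- screen$predictor[screen$selected]
    fit <- NULL
    if (length(sel)) {
      fit <- tryCatch(
        fit_reporting_model(classified$reported, cand[sel], classified$patient_id,
                            nodes = config$nodes),
        error = function(e) { logf("stage=model error=%s", conditionMessage(e)); NULL })
    }
    model <- list(screen = screen, fit = fit)
    write_csv_stable(screen, file.path(out_dir, "model_screen.csv"))
    if (!is.null(fit)) {
      jsonlite::write_json(list(
        coefficients = as.list(fit$coefficients),
        odds_ratios = as.list(fit$odds_ratios),
        ci_95 = apply(fit$ci_95, 1, as.list),
        p_values = as.list(fit$p_values),
        random_intercept_sd = fit$random_intercept_sd,
        log_likelihood = fit$log_likelihood,
        n_events = fit$n_events, n_patients = fit$n_patients,
        converged = fit$converged
      ), file.path(out_dir, "model_fit.json"), auto_unbox = TRUE, digits = NA)
      logf("stage=model predictors=%s converged=%s",
           paste(sel, collapse = "+"), fit$converged)
    }
  } else {
    logf("stage=model skipped=insufficient_events")
  }

  ## manifest
  out_files <- sort(setdiff(list.files(out_dir), c("manifest.json", "run.log")))
  manifest <- list(
    package = "exadiary",
    version = as.character(utils::packageVersion("exadiary")),
    seed = config$seed,
    stage_counts = list(
      patients = length(unique(diary$patient_id)),
      diary_records = nrow(diary),
      events_detected = nrow(events),
      events_classified = nrow(classified),
      events_reported = sum(classified$reported),
      patients_categorized = nrow(categories$patients)
    ),
    outputs = as.list(tools::md5sum(file.path(out_dir, out_files)))
  )
  names(manifest$outputs) <- out_files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, diary = diary, baseline = baseline,
                 visits = visits, truth = truth, compliance = comp,
                 events = events, classified = classified,
                 event_table = event_table, categories = categories,
                 model = model))
}
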