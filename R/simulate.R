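#' @title Synthetic diary-cohort simulator
#' @description Generates a cohort of daily symptom diaries with the
#'   statistical structure the analysis pipeline assumes: multi-day
#'   symptom episodes injected per patient (Poisson count, shifted
#'   negative-binomial duration, fixed within-episode symptom set with
#'   at least one major symptom and two symptoms in total), separated by
#'   symptom-free washout gaps; sparse single-symptom noise days;
#'   per-patient record-keeping propensity (beta-distributed) applied as
#'   independent day-wise missingness; reporting behaviour following a
#'   two-level logistic model in which the log-odds of seeking care rise
#'   with episode duration and onset symptom count; and baseline/visit
#'   tables including CAT scores whose 6-month change depends on the
#'   patient's exacerbation category.  Ground truth for every injected
#'   episode is returned so detection and classification can be scored.
#' @name synthetic-cohort
NULL

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a 116-patient cohort of frequent exacerbators
#' followed for 180 days: an expected 2.25 episodes per patient per
#' window, episode durations `2 + NegBin(size 3, mu 4.5)` (median 6
#' days), per-symptom episode inclusion probabilities equal to observed
#' event-level symptom prevalences, mean record-keeping propensity of
#' about two thirds (Beta(1.4, 0.7)), and reporting log-odds of
#' `log(1.15)` per episode day and `log(1.75)` per onset symptom around
#' a patient random intercept with standard deviation 1.
#'
#' @param n_patients number of patients.
#' @param n_days observation window length.
#' @param episode_rate expected injected episodes per patient.
#' @param duration_size,duration_mu,duration_shift shifted
#'   negative-binomial episode-duration law: `shift + NB(size, mu)`.
#' @param symptom_inclusion_probs named probability per symptom of being
#'   active throughout an episode (resampled until the episode set has
#'   at least one major and two total symptoms).
#' @param noise_day_prob probability that an out-of-episode day carries
#'   exactly one worsened symptom.
#' @param compliance_shape1,compliance_shape2 beta law of the
#'   per-patient record propensity.
#' @param compliance_fixed if non-`NULL`, every patient gets this fixed
#'   record propensity instead of a beta draw (1 = no missingness).
#' @param reporting_intercept,beta_duration,beta_symptoms,patient_sd
#'   two-level logistic reporting model: intercept, log-odds per episode
#'   day, log-odds per onset symptom, patient random-intercept sd.
#' @param treatment_probs_reported,treatment_probs_unreported named
#'   category probabilities conditional on reported status.
#' @param contact_type_probs named probabilities of the contact type
#'   recorded for a reported episode.
#' @param cat_group_shift named 6-month CAT shift per patient category.
#' @param cat_noise_sd standard deviation of the integer CAT noise.
#' @param washout_min minimum symptom-free gap between episodes (days,
#'   must be at least 7 so injected episodes stay separable).
#' @param max_placement_tries duration redraws attempted per episode
#'   count before the count is reduced.
#' @return list of class `exa_cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 116, n_days = 180,
    episode_rate = 2.25,
    duration_size = 3, duration_mu = 4.5, duration_shift = 2,
    symptom_inclusion_probs = c(dyspnea = 0.523, sputum_amount = 0.676,
                                sputum_color = 0.347, cough = 0.656,
                                wheeze = 0.286, sore_throat = 0.218,
                                cold = 0.419),
    noise_day_prob = 0.02,
    compliance_shape1 = 1.4, compliance_shape2 = 0.7,
    compliance_fixed = NULL,
    reporting_intercept = -3.2,
    beta_duration = log(1.15), beta_symptoms = log(1.75),
    patient_sd = 1,
    treatment_probs_reported = c(none = 0, bronchodilator_increase_only = 15,
                                 antibiotics_only = 47, corticosteroids_only = 9,
                                 antibiotics_plus_corticosteroids = 28) / 99,
    treatment_probs_unreported = c(none = 87, bronchodilator_increase_only = 57,
                                   antibiotics_only = 10, corticosteroids_only = 9,
                                   antibiotics_plus_corticosteroids = 0) / 163,
    contact_type_probs = c(contact_scheduled_visit = 0,
                           contact_unscheduled_visit = 0.797,
                           contact_emergency = 0.022,
                           contact_hospitalization = 0.181),
    cat_group_shift = c(no_exacerbation = -3, unreported_only = 1,
                        reported_only = -2, mixed = 3),
    cat_noise_sd = 2,
    washout_min = 9,
    max_placement_tries = 100) {
  cfg <- as.list(environment())
  stopifnot(
    n_patients >= 1, n_days >= 2, episode_rate >= 0,
    washout_min >= 7, duration_shift >= 2,
    all(symptom_inclusion_probs >= 0 & symptom_inclusion_probs <= 1),
    noise_day_prob >= 0, noise_day_prob <= 1,
    compliance_shape1 > 0, compliance_shape2 > 0, patient_sd >= 0,
    abs(sum(treatment_probs_reported) - 1) < 1e-8,
    abs(sum(treatment_probs_unreported) - 1) < 1e-8,
    abs(sum(contact_type_probs) - 1) < 1e-8
  )
  if (!setequal(names(symptom_inclusion_probs), symptom_columns)) {
    stop("symptom_inclusion_probs must name all seven symptoms", call. = FALSE)
  }
  structure(cfg, class = "exa_cohort_config")
}

draw_duration <- function(n, cfg) {
  cfg$duration_shift + stats::rnbinom(n, size = cfg$duration_size, mu = cfg$duration_mu)
}

# place k episodes of the drawn durations into the window with gaps of at
# least washout_min between them; returns onsets or NULL when they do not fit
place_episodes <- function(durations, n_days, washout_min) {
  k <- length(durations)
  slack <- n_days - sum(durations) - (k - 1L) * washout_min
  if (slack < 0) return(NULL)
  extra <- if (slack > 0) tabulate(sample.int(k + 1L, slack, replace = TRUE),
                                   nbins = k + 1L) else integer(k + 1L)
  onsets <- integer(k)
  pos <- extra[1L] + 1L
  for (i in seq_len(k)) {
    onsets[i] <- pos
    pos <- pos + durations[i] + washout_min + extra[i + 1L]
  }
  onsets
}

draw_episode_symptoms <- function(cfg) {
  probs <- cfg$symptom_inclusion_probs[symptom_columns]
  for (try in 1:1000) {
    flags <- stats::rbinom(7L, 1L, probs)
    names(flags) <- symptom_columns
    if (sum(flags[major_symptoms]) >= 1L && sum(flags) >= 2L) return(flags)
  }
  stop("could not draw an episode symptom set meeting the criterion", call. = FALSE)
}

#' Generate a synthetic diary cohort
#'
#' @param config configuration from [cohort_config()].
#' @param seed integer RNG seed; the run is fully deterministic given
#'   the seed.
#' @return list with elements `diary` (validated diary data frame after
#'   compliance degradation), `full_diary` (before degradation),
#'   `baseline`, `visits`, `truth` (list of `episodes` and `patients`
#'   ground-truth tables) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "exa_cohort_config"))
  set.seed(seed)
  cfg <- config
  pids <- sprintf("P%03d", seq_len(cfg$n_patients))

  propensity <- if (!is.null(cfg$compliance_fixed)) {
    rep(cfg$compliance_fixed, cfg$n_patients)
  } else {
    stats::rbeta(cfg$n_patients, cfg$compliance_shape1, cfg$compliance_shape2)
  }
  u_patient <- stats::rnorm(cfg$n_patients)

  episode_rows <- list()
  diary_rows <- vector("list", cfg$n_patients)
  truth_cat <- character(cfg$n_patients)

  for (i in seq_len(cfg$n_patients)) {
    pid <- pids[i]
    k0 <- k <- stats::rpois(1L, cfg$episode_rate)
    onsets <- integer(0); durations <- integer(0)
    while (k > 0L) {
      placed <- FALSE
      for (try in seq_len(cfg$max_placement_tries)) {
        durations <- draw_duration(k, cfg)
        onsets <- place_episodes(durations, cfg$n_days, cfg$washout_min)
        if (!is.null(onsets)) { placed <- TRUE; break }
      }
      if (placed) break
      k <- k - 1L   # documented fallback: reduce the count until it fits
    }
    if (k == 0L) {
      if (k0 > 0L) {
        stop(sprintf(
          "cannot place a single episode in a %d-day window after %d draws; config infeasible",
          cfg$n_days, cfg$max_placement_tries), call. = FALSE)
      }
      onsets <- integer(0); durations <- integer(0)
    }

    sym_mat <- matrix(0L, cfg$n_days, 7L, dimnames = list(NULL, symptom_columns))
    med_mat <- matrix(0L, cfg$n_days, length(medication_columns),
                      dimnames = list(NULL, medication_columns))
    con_mat <- matrix(0L, cfg$n_days, length(contact_columns),
                      dimnames = list(NULL, contact_columns))
    in_episode <- logical(cfg$n_days)

    if (k > 0L) for (j in seq_len(k)) {
      o <- onsets[j]; e <- o + durations[j] - 1L
      flags <- draw_episode_symptoms(cfg)
      sym_mat[o:e, ] <- matrix(flags, durations[j], 7L, byrow = TRUE)
      in_episode[o:e] <- TRUE
      n_sym <- sum(flags)

      lp <- cfg$reporting_intercept + cfg$beta_duration * durations[j] +
        cfg$beta_symptoms * n_sym + cfg$patient_sd * u_patient[i]
      reported <- stats::runif(1) < stats::plogis(lp)

      probs <- if (reported) cfg$treatment_probs_reported else cfg$treatment_probs_unreported
      treat <- sample(names(probs), 1L, prob = probs)
      contact_day <- NA_integer_; contact_type <- NA_character_
      if (reported) {
        contact_day <- sample(o:e, 1L)
        contact_type <- sample(names(cfg$contact_type_probs), 1L,
                               prob = cfg$contact_type_probs)
        con_mat[contact_day, contact_type] <- 1L
      }
      med_day <- NA_integer_
      if (treat != "none") {
        med_day <- sample(o:e, 1L)
        if (treat == "bronchodilator_increase_only") {
          med_mat[med_day, "increased_inhaled_medication"] <- 1L
        } else if (treat == "antibiotics_only") {
          med_mat[med_day, "started_antibiotics"] <- 1L
        } else if (treat == "corticosteroids_only") {
          med_mat[med_day, "started_corticosteroids"] <- 1L
        } else if (treat == "antibiotics_plus_corticosteroids") {
          med_mat[med_day, c("started_antibiotics", "started_corticosteroids")] <- 1L
        }
      }
      episode_rows[[length(episode_rows) + 1L]] <- data.frame(
        patient_id = pid, episode_id = j, onset_day = o, end_day = e,
        duration_days = durations[j],
        as.list(flags),
        symptom_count = n_sym, reported = reported,
        treatment_category = treat, contact_day = contact_day,
        contact_type = contact_type, med_day = med_day,
        stringsAsFactors = FALSE
      )
    }

    # single-symptom noise days outside episodes
    noise_days <- which(!in_episode & stats::runif(cfg$n_days) < cfg$noise_day_prob)
    if (length(noise_days)) {
      probs <- cfg$symptom_inclusion_probs[symptom_columns]
      noise_sym <- sample(symptom_columns, length(noise_days), replace = TRUE,
                          prob = probs / sum(probs))
      sym_mat[cbind(noise_days, match(noise_sym, symptom_columns))] <- 1L
    }

    n_rep <- sum(vapply(episode_rows, function(r) r$patient_id == pid && r$reported,
                        logical(1)))
    n_unrep <- sum(vapply(episode_rows, function(r) r$patient_id == pid && !r$reported,
                          logical(1)))
    truth_cat[i] <- if (n_rep == 0 && n_unrep == 0) "no_exacerbation"
      else if (n_rep > 0 && n_unrep > 0) "mixed"
      else if (n_rep > 0) "reported_only" else "unreported_only"

    diary_rows[[i]] <- data.frame(
      patient_id = pid, study_day = seq_len(cfg$n_days),
      as.data.frame(sym_mat), as.data.frame(med_mat), as.data.frame(con_mat),
      entry_day = seq_len(cfg$n_days), stringsAsFactors = FALSE
    )
  }

  full_diary <- as_diary(do.call(rbind, diary_rows), n_days = cfg$n_days)
  names(propensity) <- pids
  diary <- degrade_compliance(full_diary, propensity,
                              seed = derive_seed(seed, "compliance"))

  baseline <- generate_baseline(pids, cfg)
  visits <- generate_visits(pids, baseline, truth_cat, cfg)

  episodes <- if (length(episode_rows)) {
    do.call(rbind, c(episode_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(patient_id = character(0), episode_id = integer(0),
               onset_day = integer(0), end_day = integer(0),
               duration_days = integer(0), symptom_count = integer(0),
               reported = logical(0), treatment_category = character(0),
               contact_day = integer(0), contact_type = character(0),
               med_day = integer(0), stringsAsFactors = FALSE)
  }
  truth <- list(
    episodes = episodes,
    patients = data.frame(patient_id = pids, propensity = unname(propensity),
                          random_intercept = u_patient, category = truth_cat,
                          stringsAsFactors = FALSE)
  )
  list(diary = diary, full_diary = full_diary, baseline = baseline,
       visits = visits, truth = truth, config = cfg)
}

# patient baseline table with the marginal structure of a severe,
# frequently exacerbating COPD cohort
generate_baseline <- function(pids, cfg) {
  n <- length(pids)
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  mmrc <- sample(0:4, n, replace = TRUE, prob = c(0.06, 0.17, 0.40, 0.27, 0.10))
  data.frame(
    patient_id = pids,
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.784, 0.216)),
    age = round(clip(stats::rnorm(n, 66.5, 8.1), 41, 90)),
    bmi = round(clip(stats::rnorm(n, 27.3, 5.0), 15, 45), 1),
    smoking_status = sample(c("active", "former"), n, replace = TRUE,
                            prob = c(0.138, 0.862)),
    n_comorbidities = stats::rpois(n, 2.6),
    mmrc = mmrc,
    cat_baseline = round(clip(stats::rnorm(n, 14.1, 6.1), 0, 40)),
    fev1_pct = round(clip(stats::rnorm(n, 44.6, 16.2), 12, 95), 1),
    depression = stats::rbinom(n, 1, 0.06),
    anxiety = stats::rbinom(n, 1, 0.18),
    prior_moderate_severe_exac = pmax(2L, stats::rpois(n, 3)),
    treatment_class = sample(c("lama", "lama_laba", "laba_ics", "triple"), n,
                             replace = TRUE, prob = c(0.052, 0.319, 0.052, 0.577)),
    ltot = stats::rbinom(n, 1, 0.31),
    satisfaction = pmin(10L, 7L + stats::rpois(n, 2)),
    stringsAsFactors = FALSE
  )
}

generate_visits <- function(pids, baseline, truth_cat, cfg) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  base_cat <- baseline$cat_baseline
  shift <- cfg$cat_group_shift[truth_cat]
  m3 <- clip(base_cat + round(stats::rnorm(length(pids), 0, cfg$cat_noise_sd)), 0, 40)
  m6 <- clip(base_cat + shift + round(stats::rnorm(length(pids), 0, cfg$cat_noise_sd)),
             0, 40)
  data.frame(
    patient_id = rep(pids, 3L),
    visit = rep(c("inclusion", "month3", "month6"), each = length(pids)),
    cat = c(base_cat, m3, m6),
    stringsAsFactors = FALSE
  )
}

#' Thin a diary by per-patient record-keeping propensity
#'
#' Each record is kept independently with its patient's propensity;
#' reproducible for a fixed seed.  Kept separate from generation so a
#' full stream and its degraded version can be compared.
#'
#' @param records validated diary data frame.
#' @param propensities named numeric vector (per patient_id) of keep
#'   probabilities in \[0, 1\].
#' @param seed RNG seed.
#' @return the thinned diary.
#' @export
degrade_compliance <- function(records, propensities, seed = 1) {
  stopifnot(all(propensities >= 0 & propensities <= 1))
  p <- propensities[records$patient_id]
  if (any(is.na(p))) stop("missing propensity for some patients", call. = FALSE)
  set.seed(seed)
  keep <- stats::runif(nrow(records)) < p
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- attr(records, "n_dropped")
  out
}

#' Score detected events against injected ground truth
#'
#' A truth episode is recovered when a detected event shares its
#' patient and onset day; precision is the share of detected events
#' matching a truth episode.  End-day agreement is additionally
#' reported for matched, uncensored detections.
#'
#' @param events detected event table.
#' @param truth_episodes `truth$episodes` from [generate_cohort()].
#' @return list with `recall`, `precision`, `end_agreement`,
#'   `n_truth`, `n_detected`.
#' @export
evaluate_detection <- function(events, truth_episodes) {
  key <- function(df, onset_col) paste(df$patient_id, df[[onset_col]])
  tkey <- key(truth_episodes, "onset_day")
  dkey <- key(events, "onset_day")
  matched_truth <- tkey %in% dkey
  matched_det <- dkey %in% tkey
  idx <- match(dkey, tkey)
  ok_end <- !events$recovery_undetermined & matched_det
  end_agree <- if (any(ok_end)) {
    mean(events$end_day[ok_end] == truth_episodes$end_day[idx[ok_end]])
  } else NA_real_
  list(recall = if (nrow(truth_episodes)) mean(matched_truth) else NA_real_,
       precision = if (nrow(events)) mean(matched_det) else NA_real_,
       end_agreement = end_agree,
       n_truth = nrow(truth_episodes), n_detected = nrow(events))
}
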