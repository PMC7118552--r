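#' Symptom nomenclature
#'
#' The daily diary captures seven dichotomous respiratory symptoms, each
#' coded 1 when the symptom is worse than the patient's baseline and 0
#' otherwise.  Three symptoms are *major* (dyspnea, increased sputum
#' volume, sputum purulence/colour change) and four are *minor* (cough,
#' wheeze, sore throat, cold).  This split drives the exacerbation onset
#' criterion: at least one major symptom plus at least one other symptom,
#' major or minor.
#'
#' @format `major_symptoms` and `minor_symptoms` are character vectors of
#'   diary column names; `symptom_columns` is their union in canonical
#'   column order.
#' @name symptom-sets
NULL

#' @rdname symptom-sets
#' @export
major_symptoms <- c("dyspnea", "sputum_amount", "sputum_color")

#' @rdname symptom-sets
#' @export
minor_symptoms <- c("cough", "wheeze", "sore_throat", "cold")

#' @rdname symptom-sets
#' @export
symptom_columns <- c(major_symptoms, minor_symptoms)

medication_columns <- c("increased_inhaled_medication", "started_antibiotics",
                        "started_corticosteroids")

contact_columns <- c("contact_scheduled_visit", "contact_unscheduled_visit",
                     "contact_emergency", "contact_hospitalization")

#' Count worsened symptoms per diary row
#'
#' @param symptoms a data frame (or diary subset) containing the seven
#'   symptom columns coded 0/1.
#' @return integer vector, number of worsened symptoms per row (0--7).
#' @export
symptom_count <- function(symptoms) {
  stopifnot(all(symptom_columns %in% names(symptoms)))
  as.integer(rowSums(symptoms[symptom_columns] > 0))
}

#' Does a day's symptom profile meet the exacerbation criterion?
#'
#' A diary day counts towards exacerbation onset when at least one major
#' symptom (dyspnea, sputum amount, sputum colour) is worsened and at
#' least one further symptom -- major or minor -- is worsened as well,
#' i.e. two or more symptoms in total of which one is major.
#'
#' @inheritParams symptom_count
#' @return logical vector, one element per row.
#' @examples
#' d <- data.frame(dyspnea = c(1, 1, 0), sputum_amount = 0, sputum_color = c(0, 1, 0),
#'                 cough = c(0, 0, 1), wheeze = c(0, 0, 1), sore_throat = 0, cold = 0)
#' is_criterion_day(d)  # FALSE (major alone), TRUE, FALSE (minors only)
#' @export
is_criterion_day <- function(symptoms) {
  stopifnot(all(symptom_columns %in% names(symptoms)))
  n_major <- rowSums(symptoms[major_symptoms] > 0)
  n_total <- rowSums(symptoms[symptom_columns] > 0)
  n_major >= 1 & n_total >= 2
}
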