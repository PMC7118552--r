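#' @title Diary, baseline and visit file input/output
#' @description Delimited-text readers and writers for the three study
#'   tables: the daily diary (one row per patient-day), the patient
#'   baseline table and the visit-level CAT table.  All files are
#'   UTF-8 delimited text (comma by default, tab accepted) with a header
#'   row; flags are coded 0/1.
#' @name diary-io
NULL

diary_flag_columns <- function() {
  c(symptom_columns, medication_columns, contact_columns)
}

#' Canonical diary column order
#' @return character vector of the diary schema's column names.
#' @export
diary_columns <- function() {
  c("patient_id", "study_day", diary_flag_columns(), "entry_day")
}

#' An empty diary table with the canonical schema
#' @return zero-row data frame with diary columns and types.
#' @export
empty_diary <- function() {
  cols <- diary_columns()
  out <- as.data.frame(setNames(rep(list(integer(0)), length(cols)), cols))
  out$patient_id <- character(0)
  out
}

check_flag_column <- function(x, col, file = NULL) {
  bad <- which(!(x %in% c(0L, 1L)) | is.na(x))
  if (length(bad)) {
    stop(sprintf("malformed flag value in column '%s' at data row %d%s",
                 col, bad[1],
                 if (is.null(file)) "" else sprintf(" of '%s'", file)),
         call. = FALSE)
  }
  as.integer(x)
}

#' Read a daily symptom diary
#'
#' Reads a delimited diary file, validates the schema, enforces the
#' three-day back-entry window and resolves duplicate patient-days.
#' A diary entry may be keyed in on the study day itself or up to three
#' days later (patients may back-fill the three previous days); rows
#' outside that window are dropped and counted.  When two rows describe
#' the same patient-day, the one entered closest to real time (earliest
#' `entry_day`) is kept: later entries are retrospective and less
#' reliable.
#'
#' A missing patient-day is represented by the absence of a row; a row
#' whose seven symptom flags are all zero is a recorded symptom-free
#' day.  The distinction matters for every downstream rule.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param n_days length of the observation window in days (default 180).
#' @return a data frame of diary records sorted by patient and study
#'   day, with attribute `n_dropped` counting rows removed for
#'   violating the back-entry window.
#' @seealso [write_diary()], [read_events()]
#' @export
read_diary <- function(path, sep = ",", n_days = 180) {
  if (!file.exists(path)) stop(sprintf("diary file '%s' does not exist", path), call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  as_diary(raw, n_days = n_days, file = path)
}

#' Validate an in-memory diary table
#'
#' Applies the same schema checks, back-entry filter and duplicate
#' resolution as [read_diary()], for diaries constructed in code.
#'
#' @param records data frame with the diary schema; a missing
#'   `entry_day` column defaults to same-day entry.
#' @inheritParams read_diary
#' @param file optional file name used in error messages.
#' @return validated diary data frame with attribute `n_dropped`.
#' @export
as_diary <- function(records, n_days = 180, file = NULL) {
  need <- setdiff(c("patient_id", "study_day", diary_flag_columns()), names(records))
  if (length(need)) {
    stop(sprintf("diary is missing column(s): %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  records$patient_id <- as.character(records$patient_id)
  records$study_day <- as.integer(records$study_day)
  if (!("entry_day" %in% names(records))) records$entry_day <- records$study_day
  records$entry_day <- as.integer(records$entry_day)

  bad_day <- which(is.na(records$study_day) | records$study_day < 1L |
                     records$study_day > n_days)
  if (length(bad_day)) {
    stop(sprintf("study_day out of range 1..%d at data row %d%s",
                 n_days, bad_day[1],
                 if (is.null(file)) "" else sprintf(" of '%s'", file)),
         call. = FALSE)
  }
  for (col in diary_flag_columns()) {
    records[[col]] <- check_flag_column(records[[col]], col, file)
  }

  # 3-day back-entry window: same-day through study_day + 3
  lag <- records$entry_day - records$study_day
  keep <- !is.na(lag) & lag >= 0L & lag <= 3L
  n_dropped <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  # duplicate patient-days: keep the earliest entry
  records <- records[order(records$patient_id, records$study_day, records$entry_day), ,
                     drop = FALSE]
  dup <- duplicated(records[c("patient_id", "study_day")])
  records <- records[!dup, , drop = FALSE]

  records <- records[diary_columns()]
  rownames(records) <- NULL
  attr(records, "n_dropped") <- n_dropped
  records
}

#' Write a diary table to delimited text
#' @param records validated diary data frame.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_diary <- function(records, path, sep = ",") {
  utils::write.table(records[diary_columns()], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the patient baseline table
#'
#' @param path delimited text file keyed by `patient_id`.
#' @param sep field separator.
#' @return data frame with one row per patient.
#' @export
read_baseline <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("baseline file '%s' does not exist", path), call. = FALSE)
  x <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!("patient_id" %in% names(x))) stop("baseline table lacks 'patient_id'", call. = FALSE)
  x$patient_id <- as.character(x$patient_id)
  if (anyDuplicated(x$patient_id)) stop("duplicate patient_id in baseline table", call. = FALSE)
  if ("cat_baseline" %in% names(x) &&
      any(x$cat_baseline < 0 | x$cat_baseline > 40, na.rm = TRUE)) {
    stop("cat_baseline outside 0..40", call. = FALSE)
  }
  x
}

#' Read the visit-level CAT table
#'
#' @param path delimited text file with columns `patient_id`, `visit`
#'   (one of `inclusion`, `month3`, `month6`) and `cat` (0--40).
#' @param sep field separator.
#' @return data frame of visit records.
#' @export
read_visits <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("visit file '%s' does not exist", path), call. = FALSE)
  x <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- setdiff(c("patient_id", "visit", "cat"), names(x))
  if (length(need)) stop(sprintf("visit table lacks: %s", paste(need, collapse = ", ")), call. = FALSE)
  x$patient_id <- as.character(x$patient_id)
  bad <- which(!(x$visit %in% c("inclusion", "month3", "month6")))
  if (length(bad)) stop(sprintf("unknown visit label '%s' at data row %d", x$visit[bad[1]], bad[1]), call. = FALSE)
  if (any(is.na(x$cat) | x$cat < 0 | x$cat > 40)) stop("cat score outside 0..40", call. = FALSE)
  x
}

event_columns <- function() {
  c("patient_id", "event_id", "onset_day", "end_day", "duration_days",
    "recovery_undetermined", "censor_reason", "censor_day",
    symptom_columns, "onset_symptom_count", "severity_bin")
}

#' Write detected exacerbation events to delimited text
#'
#' One row per event: onset, end (empty when recovery is undetermined),
#' duration, censoring flag and reason, the onset-day symptom profile,
#' symptom count and severity bin.  The file round-trips losslessly
#' through [read_events()].
#'
#' @param events event table from [detect_events()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, sep = ",") {
  cols <- intersect(event_columns(), names(events))
  extra <- setdiff(names(events), cols)
  out <- events[c(cols, extra)]
  out$recovery_undetermined <- as.integer(out$recovery_undetermined)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an exacerbation event table
#' @param path path written by [write_events()].
#' @param sep field separator.
#' @return event data frame with the [detect_events()] schema.
#' @export
read_events <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("event file '%s' does not exist", path), call. = FALSE)
  x <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                         na.strings = "")
  if (nrow(x) == 0) return(empty_events())
  x$patient_id <- as.character(x$patient_id)
  for (col in c("event_id", "onset_day", "end_day", "duration_days", "censor_day",
                "onset_symptom_count", symptom_columns)) {
    if (col %in% names(x)) x[[col]] <- as.integer(x[[col]])
  }
  x$recovery_undetermined <- as.logical(x$recovery_undetermined)
  x$severity_bin <- as.character(x$severity_bin)
  x
}

empty_events <- function() {
  out <- data.frame(patient_id = character(0), event_id = integer(0),
                    onset_day = integer(0), end_day = integer(0),
                    duration_days = integer(0),
                    recovery_undetermined = logical(0),
                    censor_reason = character(0), censor_day = integer(0),
                    stringsAsFactors = FALSE)
  for (col in symptom_columns) out[[col]] <- integer(0)
  out$onset_symptom_count <- integer(0)
  out$severity_bin <- character(0)
  out
}
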