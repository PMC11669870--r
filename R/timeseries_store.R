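# Data model: minute-resolution sensor series, inhaler event logs and
# medication-status timelines, plus the CSV dialects used on disk.
#
# A "minute table" is a data.frame(patient_id, time, value) holding the
# series of every patient in one long frame (class "minute_table", attribute
# "kind"), ordered by patient then time; per-patient subsets are valid
# MinuteSeries. Absent minutes mean the device was not worn -- they are never
# zero-filled for heart rate.

INHALER_TYPES <- c("SABA", "LABA", "ICS", "ICS_LABA")

.new_minute_table <- function(patient_id, time, value, kind) {
  df <- data.frame(patient_id = as.character(patient_id), time = time,
                   value = as.numeric(value), stringsAsFactors = FALSE)
  df <- df[order(df$patient_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, kind = kind, class = c("minute_table", "data.frame"))
}

.validate_minute_values <- function(value, kind, where = "") {
  if (anyNA(value) || any(value < 0))
    .stopf("negative or missing %s value%s", kind, where,
           class = "beta2hr_domain_error")
  if (kind == "heart_rate_bpm" && (any(value < 20) || any(value > 250)))
    .stopf("heart_rate_bpm values must lie in [20, 250]%s", where,
           class = "beta2hr_domain_error")
  if (kind == "steps_per_minute" && any(value != floor(value)))
    .stopf("steps_per_minute values must be non-negative integers%s", where,
           class = "beta2hr_domain_error")
  invisible(TRUE)
}

#' Minute-resolution sensor series
#'
#' Builds a validated minute-level measurement table (heart rate in bpm or
#' steps per minute) for one or more patients. Timestamps are floored to the
#' whole minute; within a patient they must be unique. Missing minutes encode
#' "device not worn" and are represented by the absence of a row.
#'
#' @param patient_id Character vector (recycled) of patient identifiers.
#' @param time Timestamps (POSIXct or ISO 8601 strings, naive local time).
#' @param value Measurements: heart rate in `[20, 250]` bpm, or non-negative
#'   integer steps.
#' @param kind `"heart_rate_bpm"` or `"steps_per_minute"`.
#' @return A `minute_table` data frame with columns `patient_id`, `time`,
#'   `value` and attribute `kind`.
#' @export
minute_series <- function(patient_id, time, value,
                          kind = c("heart_rate_bpm", "steps_per_minute")) {
  kind <- match.arg(kind)
  time <- .floor_minute(.as_naive_time(time))
  if (anyNA(time))
    .stopf("malformed timestamp in minute series",
           class = "beta2hr_parse_error")
  if (length(patient_id) == 1L) patient_id <- rep(patient_id, length(time))
  .validate_minute_values(value, kind)
  df <- .new_minute_table(patient_id, time, value, kind)
  key <- paste(df$patient_id, as.numeric(df$time))
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    .stopf("duplicate minute for patient '%s' at %s", d$patient_id,
           .fmt_time(d$time), class = "beta2hr_integrity_error")
  }
  df
}

#' Inhaler actuation log
#'
#' Timestamped inhaler actuations labelled with the inhaler type. Events are
#' floored to the minute, sorted per patient, and exact duplicates (same
#' patient, minute and type) are collapsed to a single actuation.
#'
#' @param patient_id Character vector (recycled).
#' @param time Actuation timestamps.
#' @param inhaler_type One of `"SABA"`, `"LABA"`, `"ICS"`, `"ICS_LABA"`.
#' @return An `event_table` data frame with columns `patient_id`, `time`,
#'   `inhaler_type`.
#' @export
event_log <- function(patient_id, time, inhaler_type) {
  time <- .floor_minute(.as_naive_time(time))
  if (anyNA(time))
    .stopf("malformed timestamp in event log", class = "beta2hr_parse_error")
  inhaler_type <- as.character(inhaler_type)
  bad <- !inhaler_type %in% INHALER_TYPES
  if (any(bad))
    .stopf("unknown inhaler_type '%s'; allowed: %s", inhaler_type[bad][1L],
           paste(INHALER_TYPES, collapse = ", "),
           class = "beta2hr_domain_error")
  if (length(patient_id) == 1L) patient_id <- rep(patient_id, length(time))
  df <- data.frame(patient_id = as.character(patient_id), time = time,
                   inhaler_type = inhaler_type, stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("patient_id", "time", "inhaler_type")]), ,
           drop = FALSE]
  df <- df[order(df$patient_id, df$time, df$inhaler_type), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("event_table", "data.frame"))
}

#' Medication-status timeline
#'
#' Per-patient date intervals flagging LABA use, the analogue of a weekly
#' medication questionnaire. Intervals are inclusive on both ends, must not
#' overlap within a patient, and only cover dates with known status.
#'
#' @param patient_id Character vector (recycled).
#' @param start_date,end_date Dates (or ISO date strings), `start <= end`.
#' @param laba Logical or 0/1: whether the patient used LABA in the interval.
#' @return A `medstatus_table` data frame with columns `patient_id`,
#'   `start_date`, `end_date`, `laba`.
#' @export
med_status <- function(patient_id, start_date, end_date, laba) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (anyNA(start_date) || anyNA(end_date))
    .stopf("malformed date in medication-status timeline",
           class = "beta2hr_parse_error")
  if (any(start_date > end_date))
    .stopf("start_date after end_date in medication-status interval",
           class = "beta2hr_domain_error")
  laba <- as.logical(as.integer(laba))
  if (anyNA(laba))
    .stopf("laba flag must be 0/1", class = "beta2hr_domain_error")
  if (length(patient_id) == 1L) patient_id <- rep(patient_id, length(start_date))
  df <- data.frame(patient_id = as.character(patient_id),
                   start_date = start_date, end_date = end_date, laba = laba,
                   stringsAsFactors = FALSE)
  df <- df[order(df$patient_id, df$start_date), , drop = FALSE]
  rownames(df) <- NULL
  for (pid in unique(df$patient_id)) {
    sub <- df[df$patient_id == pid, , drop = FALSE]
    if (nrow(sub) > 1L &&
        any(sub$start_date[-1L] <= sub$end_date[-nrow(sub)]))
      .stopf("overlapping medication-status intervals for patient '%s'", pid,
             class = "beta2hr_integrity_error")
  }
  structure(df, class = c("medstatus_table", "data.frame"))
}

#' Bundle the four per-cohort components
#'
#' @param hr Heart-rate `minute_table` ([minute_series()]).
#' @param steps Step-count `minute_table`.
#' @param events [event_log()] table.
#' @param medstatus [med_status()] table.
#' @return A `cohort_bundle`: a list with elements `hr`, `steps`, `events`,
#'   `medstatus` and the union of patient ids in `patients`.
#' @export
cohort_bundle <- function(hr, steps, events, medstatus) {
  stopifnot(inherits(hr, "minute_table"), inherits(steps, "minute_table"),
            inherits(events, "event_table"),
            inherits(medstatus, "medstatus_table"))
  if (!identical(attr(hr, "kind"), "heart_rate_bpm"))
    .stopf("'hr' must be a heart_rate_bpm series")
  if (!identical(attr(steps, "kind"), "steps_per_minute"))
    .stopf("'steps' must be a steps_per_minute series")
  patients <- sort(unique(c(hr$patient_id, steps$patient_id,
                            events$patient_id, medstatus$patient_id)))
  structure(list(hr = hr, steps = steps, events = events,
                 medstatus = medstatus, patients = patients),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Cohort bundle: %d patient(s)\n", length(x$patients)))
  cat(sprintf("  heart-rate minutes: %d\n", nrow(x$hr)))
  cat(sprintf("  step minutes (>0 or recorded): %d\n", nrow(x$steps)))
  if (nrow(x$events)) {
    tab <- table(x$events$inhaler_type)
    cat(sprintf("  inhaler actuations: %d (%s)\n", nrow(x$events),
                paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  } else cat("  inhaler actuations: 0\n")
  cat(sprintf("  medication-status intervals: %d\n", nrow(x$medstatus)))
  invisible(x)
}

.read_csv_checked <- function(path, columns) {
  if (!file.exists(path))
    .stopf("file not found: %s", path, class = "beta2hr_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), columns))
    .stopf("unexpected header in %s: got (%s), expected (%s)", path,
           paste(names(df), collapse = ", "),
           paste(columns, collapse = ", "), class = "beta2hr_parse_error")
  df
}

.parse_ts_column <- function(x, path) {
  t <- .as_naive_time(x)
  if (anyNA(t)) {
    line <- which(is.na(t))[1L]
    .stopf("malformed timestamp '%s' at data line %d of %s", x[line], line,
           path, class = "beta2hr_parse_error")
  }
  t
}

#' Read a minute-level sensor CSV
#'
#' Expects columns `patient_id, timestamp, value` (ISO 8601 naive local
#' timestamps), one row per worn minute. Timestamps are floored to the
#' minute; duplicate patient+minute rows are rejected.
#'
#' @param path Path to the CSV file.
#' @param kind `"heart_rate_bpm"` or `"steps_per_minute"`.
#' @return A `minute_table` covering all patients in the file.
#' @export
read_minute_csv <- function(path, kind = c("heart_rate_bpm",
                                           "steps_per_minute")) {
  kind <- match.arg(kind)
  df <- .read_csv_checked(path, c("patient_id", "timestamp", "value"))
  if (nrow(df) == 0L)
    return(.new_minute_table(character(), .as_naive_time(character()),
                             numeric(), kind))
  t <- .parse_ts_column(df$timestamp, path)
  value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(value)) {
    line <- which(is.na(value))[1L]
    .stopf("non-numeric value '%s' at data line %d of %s", df$value[line],
           line, path, class = "beta2hr_parse_error")
  }
  if (any(value < 0)) {
    line <- which(value < 0)[1L]
    .stopf("negative value at data line %d of %s", line, path,
           class = "beta2hr_domain_error")
  }
  minute_series(df$patient_id, t, value, kind)
}

#' Read an inhaler actuation CSV
#'
#' Expects columns `patient_id, timestamp, inhaler_type` with inhaler types in
#' `SABA, LABA, ICS, ICS_LABA`. Rows are floored to the minute, deduplicated
#' and sorted per patient.
#'
#' @param path Path to the CSV file.
#' @return An `event_table`.
#' @export
read_event_csv <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "timestamp", "inhaler_type"))
  if (nrow(df) == 0L)
    return(event_log(character(), .as_naive_time(character()), character()))
  t <- .parse_ts_column(df$timestamp, path)
  event_log(df$patient_id, t, df$inhaler_type)
}

#' Read a medication-status CSV
#'
#' Expects columns `patient_id, start_date, end_date, laba` (inclusive ISO
#' dates, laba 0/1). Overlapping intervals within a patient are an error.
#'
#' @param path Path to the CSV file.
#' @return A `medstatus_table`.
#' @export
read_medstatus_csv <- function(path) {
  df <- .read_csv_checked(path,
                          c("patient_id", "start_date", "end_date", "laba"))
  if (nrow(df) == 0L)
    return(med_status(character(), as.Date(character()),
                      as.Date(character()), logical()))
  med_status(df$patient_id, df$start_date, df$end_date, df$laba)
}

#' Write / read a cohort bundle as four CSV files
#'
#' `write_bundle()` emits `hr.csv`, `steps.csv`, `events.csv` and
#' `medstatus.csv` in the dialects accepted by the readers; gaps (missing
#' minutes) are preserved, no zero rows are invented. `read_bundle()` is its
#' inverse: `read_bundle(write_bundle(b)) == b`.
#'
#' @param bundle A [cohort_bundle()].
#' @param dir Directory to write to (created if missing).
#' @return `write_bundle()` the directory path, invisibly; `read_bundle()` a
#'   `cohort_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE,
                                      quote = FALSE); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      .stopf("failed writing %s: %s", path, conditionMessage(ok),
             class = "beta2hr_io_error")
  }
  num <- function(x) sprintf("%.10g", x)
  wr(data.frame(patient_id = bundle$hr$patient_id,
                timestamp = .fmt_time(bundle$hr$time),
                value = num(bundle$hr$value)), "hr.csv")
  wr(data.frame(patient_id = bundle$steps$patient_id,
                timestamp = .fmt_time(bundle$steps$time),
                value = num(bundle$steps$value)), "steps.csv")
  wr(data.frame(patient_id = bundle$events$patient_id,
                timestamp = .fmt_time(bundle$events$time),
                inhaler_type = bundle$events$inhaler_type), "events.csv")
  wr(data.frame(patient_id = bundle$medstatus$patient_id,
                start_date = format(bundle$medstatus$start_date),
                end_date = format(bundle$medstatus$end_date),
                laba = as.integer(bundle$medstatus$laba)), "medstatus.csv")
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  cohort_bundle(
    hr = read_minute_csv(file.path(dir, "hr.csv"), "heart_rate_bpm"),
    steps = read_minute_csv(file.path(dir, "steps.csv"), "steps_per_minute"),
    events = read_event_csv(file.path(dir, "events.csv")),
    medstatus = read_medstatus_csv(file.path(dir, "medstatus.csv")))
}

# Empty data.frame helpers used when writing header-only CSVs.
# (write.csv of a zero-row frame already emits just the header.)
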