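# Wear-time accounting, low-wear exclusion, LABA person-time splitting and
# patient-first hourly aggregation.

#' Wear-time accounting
#'
#' Counts the minutes with a recorded heart-rate value, overall and per ISO
#' week, for every patient of a bundle (or a heart-rate `minute_table`).
#'
#' @param x A [cohort_bundle()] or a heart-rate `minute_table`.
#' @return A list with `total` (data frame `patient_id`, `worn_minutes`) and
#'   `weekly` (data frame `patient_id`, `iso_week`, `worn_minutes`). Patients
#'   present in the bundle but without any heart-rate minute appear with 0.
#' @export
compute_wear_minutes <- function(x) {
  patients <- NULL
  if (inherits(x, "cohort_bundle")) {
    patients <- x$patients
    x <- x$hr
  }
  stopifnot(inherits(x, "minute_table"))
  patients <- patients %||% sort(unique(x$patient_id))
  if (nrow(x)) {
    tot <- as.data.frame(table(factor(x$patient_id, levels = patients)),
                         stringsAsFactors = FALSE)
    names(tot) <- c("patient_id", "worn_minutes")
    wk <- format(.naive_date(x$time), "%G-W%V")
    weekly <- aggregate(list(worn_minutes = rep(1L, nrow(x))),
                        by = list(patient_id = x$patient_id, iso_week = wk),
                        FUN = sum)
    weekly <- weekly[order(weekly$patient_id, weekly$iso_week), ,
                     drop = FALSE]
    rownames(weekly) <- NULL
  } else {
    tot <- data.frame(patient_id = patients,
                      worn_minutes = integer(length(patients)),
                      stringsAsFactors = FALSE)
    weekly <- data.frame(patient_id = character(), iso_week = character(),
                         worn_minutes = integer(), stringsAsFactors = FALSE)
  }
  list(total = tot, weekly = weekly)
}

#' Remove patients with insufficient wear time
#'
#' A patient is removed when their total worn minutes over the whole
#' follow-up fall strictly below `min_total_minutes`. The default, 10,080
#' minutes, is one full week of continuous wear; 25,200 (a week of 12-hour
#' days) is available through the argument for a stricter reading.
#'
#' @param bundle A [cohort_bundle()].
#' @param min_total_minutes Wear threshold in minutes (default `7 * 24 * 60`).
#' @return A list with `bundle` (the kept patients) and `report`: a data
#'   frame `patient_id`, `worn_minutes`, `removed`, `reason` covering every
#'   patient.
#' @export
filter_low_wear <- function(bundle, min_total_minutes = 10080) {
  stopifnot(inherits(bundle, "cohort_bundle"), min_total_minutes >= 0)
  tot <- table(factor(bundle$hr$patient_id, levels = bundle$patients))
  wear <- data.frame(patient_id = bundle$patients,
                     worn_minutes = as.integer(tot),
                     stringsAsFactors = FALSE)
  removed <- wear$worn_minutes < min_total_minutes
  report <- data.frame(patient_id = wear$patient_id,
                       worn_minutes = wear$worn_minutes,
                       removed = removed,
                       reason = ifelse(removed,
                                       sprintf("worn %d < %d minutes",
                                               wear$worn_minutes,
                                               round(min_total_minutes)), ""),
                       stringsAsFactors = FALSE)
  keep <- wear$patient_id[!removed]
  if (!any(removed)) return(list(bundle = bundle, report = report))
  sub <- function(df) {
    out <- df[df$patient_id %in% keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  kept <- bundle
  kept$hr <- sub(bundle$hr); kept$steps <- sub(bundle$steps)
  kept$events <- sub(bundle$events); kept$medstatus <- sub(bundle$medstatus)
  kept$patients <- keep
  list(bundle = kept, report = report)
}

#' Split heart-rate person-time by LABA status
#'
#' Assigns every worn heart-rate minute to the medication-status interval its
#' calendar date falls in: `laba`, `non_laba`, or `unknown` when the date is
#' outside all intervals. A status switch takes effect at the interval
#' boundary date. Unknown-status minutes are excluded from the group
#' comparison downstream.
#'
#' @param bundle A [cohort_bundle()].
#' @return An object of class `person_time`: list with `hr` (the heart-rate
#'   table plus `laba_status` column) and `segments` (per patient and status,
#'   date range and minute count; unknown person-time included for
#'   accounting).
#' @export
split_laba_person_time <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  hr <- bundle$hr
  dnum <- as.integer(as.numeric(hr$time) %/% 86400)  # days since epoch
  date <- as.Date(dnum, origin = "1970-01-01")
  status <- rep("unknown", nrow(hr))
  ms <- bundle$medstatus
  rows_by_patient <- split(seq_len(nrow(hr)), hr$patient_id)
  for (pid in names(rows_by_patient)) {
    rows <- rows_by_patient[[pid]]
    ivs <- ms[ms$patient_id == pid, , drop = FALSE]
    if (!nrow(ivs)) next
    d <- dnum[rows]
    for (k in seq_len(nrow(ivs))) {
      inside <- d >= as.integer(ivs$start_date[k]) &
        d <= as.integer(ivs$end_date[k])
      if (any(inside))
        status[rows[inside]] <- if (ivs$laba[k]) "laba" else "non_laba"
    }
  }
  hr$laba_status <- status
  hr$date <- date
  pidf <- factor(hr$patient_id)
  stf <- factor(status, levels = c("laba", "non_laba", "unknown"))
  key <- (as.integer(pidf) - 1L) * 3L + as.integer(stf)
  cnt <- tabulate(key, nbins = nlevels(pidf) * 3L)
  present <- which(cnt > 0L)
  d_by_key <- split(dnum, key)  # names are the sorted unique keys
  mins <- vapply(d_by_key, min, integer(1))
  maxs <- vapply(d_by_key, max, integer(1))
  seg <- data.frame(
    patient_id = levels(pidf)[(present - 1L) %/% 3L + 1L],
    laba_status = levels(stf)[(present - 1L) %% 3L + 1L],
    start_date = as.Date(mins[as.character(present)], origin = "1970-01-01"),
    end_date = as.Date(maxs[as.character(present)], origin = "1970-01-01"),
    n_minutes = cnt[present], stringsAsFactors = FALSE)
  rownames(seg) <- NULL
  structure(list(hr = hr, segments = seg), class = "person_time")
}

#' Patient-first hourly heart-rate profiles
#'
#' For each patient and LABA status, the unweighted mean heart rate of all
#' worn minutes falling in each clock hour (minute `m` belongs to hour
#' `floor(m / 60)`, half-open `[h:00, h+1:00)`). Hours without data are
#' absent, never zero. Unknown-status person-time is dropped.
#'
#' @param pt A `person_time` object from [split_laba_person_time()].
#' @return A data frame of class `hourly_profiles`: `patient_id`,
#'   `laba_status` (`laba` / `non_laba`), `hour` (0-23), `mean_bpm`,
#'   `n_minutes`.
#' @export
hourly_patient_means <- function(pt) {
  stopifnot(inherits(pt, "person_time"))
  hr <- pt$hr[pt$hr$laba_status != "unknown", , drop = FALSE]
  if (!nrow(hr)) {
    out <- data.frame(patient_id = character(), laba_status = character(),
                      hour = integer(), mean_bpm = numeric(),
                      n_minutes = integer(), stringsAsFactors = FALSE)
    class(out) <- c("hourly_profiles", "data.frame")
    return(out)
  }
  pid <- factor(hr$patient_id)
  st <- factor(hr$laba_status, levels = c("laba", "non_laba"))
  hour <- .hour_of_day(hr$time)
  key <- (as.integer(pid) - 1L) * 48L + (as.integer(st) - 1L) * 24L + hour
  sums <- rowsum(hr$value, key)
  cnts <- rowsum(rep(1L, nrow(hr)), key)
  k <- as.integer(rownames(sums))
  out <- data.frame(
    patient_id = levels(pid)[k %/% 48L + 1L],
    laba_status = c("laba", "non_laba")[(k %% 48L) %/% 24L + 1L],
    hour = k %% 24L,
    mean_bpm = as.numeric(sums) / as.numeric(cnts),
    n_minutes = as.integer(cnts),
    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$laba_status, out$hour), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hourly_profiles", "data.frame")
  out
}
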