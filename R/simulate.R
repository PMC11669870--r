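# Synthetic wearable-cohort generator. Each patient gets:
#   heart rate  = circadian cosinor + LABA offset (while a LABA user)
#               + sum of active drug-effect kernels
#               + activity gain x smoothed step rate + Gaussian noise,
#   clipped to [35, 220] bpm and quantised to 0.1 bpm,
#   steps       from a bout process (background exercise bouts plus bouts
#               coupled to SABA actuations spanning -30..+90 min),
#   actuations  from a routine reliever-use schedule (morning-peaked, with an
#               occasional second, well-separated evening use) and a
#               twice-daily maintenance schedule,
#   wear mask   combining reduced night retention and charging gaps.

#' Generator configuration for a synthetic wearable cohort
#'
#' Collects and validates every parameter of the data-generating process the
#' analysis assumes. Defaults encode the study conditions the package's
#' estimators are meant to recover: a circadian heart-rate rhythm (mesor 70
#' bpm, amplitude 5 bpm, acrophase mid-afternoon), minute-level noise of 6
#' bpm, a constant +0.8 bpm offset while a patient is a LABA user, the
#' reference SABA effect kernel, roughly one SABA use per day peaking near
#' 8 AM, half of SABA uses coupled to an exercise bout spanning -30..+90
#' minutes, twice-daily maintenance inhalations with 84% per-dose adherence,
#' and a wear model whose night retention yields an 18.7% nighttime data
#' share.
#'
#' @param n_patients Number of patients.
#' @param days_per_patient Follow-up length in days.
#' @param start_date First calendar date of follow-up.
#' @param mesor,amplitude,acrophase_min Cosinor parameters: mean heart-rate
#'   level (bpm), half peak-to-trough amplitude (bpm), and minute-of-day of
#'   the circadian peak.
#' @param hr_noise_sd Per-minute Gaussian noise SD in bpm (i.i.d.; see
#'   `ar1_phi`).
#' @param ar1_phi Optional AR(1) coefficient for the noise process; 0 (the
#'   default) keeps noise independent so test tolerances stay closed-form.
#' @param laba_offset Added bpm while the patient is a LABA user: a single
#'   number or a length-24 hour-of-day profile.
#' @param laba_frac Fraction of patients assigned a LABA-user timeline.
#' @param laba_switch_prob Probability that a patient switches LABA status
#'   once, at a uniformly drawn day of follow-up.
#' @param saba_kernel [drug_kernel()] added at each SABA actuation, or `NULL`
#'   for no acute SABA effect.
#' @param laba_acute_kernel Optional [drug_kernel()] added at each
#'   LABA/ICS_LABA actuation (default `NULL`: maintenance inhalations leave
#'   no acute heart-rate signature).
#' @param saba_day_prob Length-2 probabilities `c(P(1 use), P(2 uses))` for
#'   the number of SABA uses on a day (remainder: none). The default
#'   `c(0.765, 0.105)` gives a mean just under one actuation per day with a
#'   morning-routine first use and an occasional second use 8-12 h later.
#' @param saba_peak_minute Minute-of-day of the diurnal SABA usage peak
#'   (default 480 = 8 AM).
#' @param exercise_coupling_prob Fraction of SABA actuations accompanied by
#'   an exercise bout spanning -30..+90 minutes around the actuation.
#' @param coupled_intensity Mean steps/minute of such coupled bouts.
#' @param laba_morning_minute,laba_evening_minute Scheduled maintenance dose
#'   times (minute of day).
#' @param laba_adherence Per-dose probability the maintenance dose is taken.
#' @param dose_jitter_sd SD (minutes) of the normal jitter on dose times.
#' @param bout_rate Mean number of background exercise bouts per day.
#' @param bout_duration_mean Mean bout duration in minutes.
#' @param bout_intensity_mean,bout_intensity_sd Steps/minute level of a bout.
#' @param activity_gain Added bpm per smoothed step/minute.
#' @param activity_window Width (minutes) of the trailing moving average of
#'   steps that drives the activity heart-rate response.
#' @param day_retention Per-minute wear probability outside 00:00-06:00.
#' @param night_share_target Desired share of recorded minutes at night; used
#'   to solve `night_retention` when the latter is `NULL`.
#' @param night_retention Per-minute wear probability for 00:00-06:00, or
#'   `NULL` to solve it from `night_share_target` via
#'   [night_retention_for_fraction()].
#' @param gap_prob Probability per day of a charging gap.
#' @param gap_minutes Charging gap length in minutes (placed at a uniform
#'   clock minute, so gaps remove night and day minutes proportionally).
#' @param hr_round Decimals the simulated heart rate is rounded to
#'   (device quantisation).
#' @param clip Physiological clipping bounds in bpm.
#' @return A validated list of class `cohort_config`.
#' @seealso [simulate_cohort()], [simulate_patient()]
#' @export
cohort_config <- function(n_patients = 40L,
                          days_per_patient = 60L,
                          start_date = "2016-01-01",
                          mesor = 70, amplitude = 5, acrophase_min = 900,
                          hr_noise_sd = 6, ar1_phi = 0,
                          laba_offset = 0.8, laba_frac = 0.7,
                          laba_switch_prob = 0,
                          saba_kernel = saba_profile_kernel(),
                          laba_acute_kernel = NULL,
                          saba_day_prob = c(0.765, 0.105),
                          saba_peak_minute = 480,
                          exercise_coupling_prob = 0.5,
                          coupled_intensity = 60,
                          laba_morning_minute = 480,
                          laba_evening_minute = 1230,
                          laba_adherence = 0.84,
                          dose_jitter_sd = 20,
                          bout_rate = 3, bout_duration_mean = 20,
                          bout_intensity_mean = 80, bout_intensity_sd = 15,
                          activity_gain = 0.3, activity_window = 10L,
                          day_retention = 0.95,
                          night_share_target = 0.187,
                          night_retention = NULL,
                          gap_prob = 0.3, gap_minutes = 120L,
                          hr_round = 1L, clip = c(35, 220)) {
  if (!.is_count(n_patients))
    .stopf("n_patients must be a non-negative integer",
           class = "beta2hr_parameter_error")
  if (!.is_count(days_per_patient) || days_per_patient < 1)
    .stopf("days_per_patient must be a positive integer",
           class = "beta2hr_parameter_error")
  for (nm in c("laba_frac", "laba_switch_prob", "exercise_coupling_prob",
               "laba_adherence", "day_retention", "gap_prob")) {
    if (!.is_prob(get(nm)))
      .stopf("%s must be a probability in [0, 1]", nm,
             class = "beta2hr_parameter_error")
  }
  if (!is.numeric(saba_day_prob) || length(saba_day_prob) != 2L ||
      any(saba_day_prob < 0) || sum(saba_day_prob) > 1)
    .stopf("saba_day_prob must be c(P(1 use), P(2 uses)) with sum <= 1",
           class = "beta2hr_parameter_error")
  if (!is.numeric(laba_offset) || !length(laba_offset) %in% c(1L, 24L))
    .stopf("laba_offset must be a scalar or a length-24 hour profile",
           class = "beta2hr_parameter_error")
  if (any(c(amplitude, hr_noise_sd, bout_rate, bout_intensity_mean,
            activity_gain, coupled_intensity) < 0))
    .stopf("amplitudes, rates and gains must be non-negative",
           class = "beta2hr_parameter_error")
  if (!is.null(saba_kernel)) stopifnot(inherits(saba_kernel, "drug_kernel"))
  if (!is.null(laba_acute_kernel))
    stopifnot(inherits(laba_acute_kernel, "drug_kernel"))
  if (is.null(night_retention))
    night_retention <- night_retention_for_fraction(night_share_target,
                                                    day_retention)
  if (!.is_prob(night_retention))
    .stopf("night_retention must be a probability in [0, 1]",
           class = "beta2hr_parameter_error")
  cfg <- list(n_patients = as.integer(n_patients),
              days_per_patient = as.integer(days_per_patient),
              start_date = as.Date(start_date),
              mesor = mesor, amplitude = amplitude,
              acrophase_min = acrophase_min,
              hr_noise_sd = hr_noise_sd, ar1_phi = ar1_phi,
              laba_offset = laba_offset, laba_frac = laba_frac,
              laba_switch_prob = laba_switch_prob,
              saba_kernel = saba_kernel,
              laba_acute_kernel = laba_acute_kernel,
              saba_day_prob = saba_day_prob,
              saba_peak_minute = saba_peak_minute,
              exercise_coupling_prob = exercise_coupling_prob,
              coupled_intensity = coupled_intensity,
              laba_morning_minute = laba_morning_minute,
              laba_evening_minute = laba_evening_minute,
              laba_adherence = laba_adherence,
              dose_jitter_sd = dose_jitter_sd,
              bout_rate = bout_rate,
              bout_duration_mean = bout_duration_mean,
              bout_intensity_mean = bout_intensity_mean,
              bout_intensity_sd = bout_intensity_sd,
              activity_gain = activity_gain,
              activity_window = as.integer(activity_window),
              day_retention = day_retention,
              night_retention = night_retention,
              gap_prob = gap_prob, gap_minutes = as.integer(gap_minutes),
              hr_round = hr_round, clip = clip)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d patients x %d days from %s\n",
              x$n_patients, x$days_per_patient, format(x$start_date)))
  cat(sprintf("  circadian: mesor %.1f, amplitude %.1f bpm, acrophase %02d:%02d; noise SD %.1f bpm\n",
              x$mesor, x$amplitude, x$acrophase_min %/% 60,
              x$acrophase_min %% 60, x$hr_noise_sd))
  off <- if (length(x$laba_offset) == 1L) sprintf("%.2f bpm", x$laba_offset)
         else sprintf("hourly profile, max %.2f bpm", max(x$laba_offset))
  cat(sprintf("  LABA: %.0f%% users, offset %s\n", 100 * x$laba_frac, off))
  cat(sprintf("  SABA kernel: %s; ~%.2f uses/day, exercise coupling %.0f%%\n",
              if (is.null(x$saba_kernel)) "none" else
                sprintf("peak %.1f bpm at +%g min", x$saba_kernel$peak_amp,
                        x$saba_kernel$peak_lag),
              sum(x$saba_day_prob * c(1, 2)),
              100 * x$exercise_coupling_prob))
  cat(sprintf("  wear: day retention %.2f, night retention %.2f, gap prob %.2f\n",
              x$day_retention, x$night_retention, x$gap_prob))
  invisible(x)
}

# Diurnal weight profile (length 1440) for SABA first-use times: quiet at
# night, uniform during the day, with a Gaussian bump at the morning peak.
.saba_time_weights <- function(peak_minute) {
  m <- 0:1439
  w <- ifelse(m >= 360 & m < 1320, 1, 0.05)
  w + 1.5 * exp(-((m - peak_minute)^2) / (2 * 50^2))
}

# Trailing moving average of width w with partial means at the start.
.trailing_ma <- function(x, w) {
  if (w <= 1L) return(x)
  cs <- c(0, cumsum(x))
  n <- length(x)
  lo <- pmax(seq_len(n) - w, 0L)
  (cs[seq_len(n) + 1L] - cs[lo + 1L]) / (seq_len(n) - lo)
}

#' Simulate one patient of a synthetic wearable cohort
#'
#' Draws a single patient's heart-rate and step series, inhaler log and
#' medication-status timeline under a [cohort_config()]. All randomness is
#' governed by `seed`, so equal seeds give bit-identical output.
#'
#' @param config A [cohort_config()].
#' @param patient_id Identifier for the patient.
#' @param seed Integer RNG seed for this patient.
#' @param laba_user Logical: is the patient a LABA user (before any switch)?
#' @return A list with elements `hr`, `steps` (`minute_table`s), `events`
#'   (`event_table`) and `medstatus` (`medstatus_table`).
#' @export
simulate_patient <- function(config, patient_id, seed, laba_user = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  nd <- config$days_per_patient
  n <- nd * 1440L
  idx <- seq_len(n) - 1L                 # absolute minute, 0-based
  mod <- idx %% 1440L                    # minute of day
  day <- idx %/% 1440L                   # day of follow-up, 0-based
  t0 <- .midnight(config$start_date)

  # LABA status per day (optionally one switch at a uniform day)
  status <- rep(laba_user, nd)
  switch_day <- NA_integer_
  if (config$laba_switch_prob > 0 && nd > 1L &&
      stats::runif(1) < config$laba_switch_prob) {
    switch_day <- sample.int(nd - 1L, 1L)  # first day of the new status
    status[(switch_day + 1L):nd] <- !laba_user
  }

  # --- inhaler actuations -------------------------------------------------
  w <- .saba_time_weights(config$saba_peak_minute)
  u <- stats::runif(nd)
  p1 <- config$saba_day_prob[1L]; p2 <- config$saba_day_prob[2L]
  n_saba <- ifelse(u < p2, 2L, ifelse(u < p1 + p2, 1L, 0L))
  saba_min <- integer(0)
  first_use <- sample(0:1439, nd, replace = TRUE, prob = w)
  second_gap <- round(stats::runif(nd, 480, 720))
  for (d in which(n_saba > 0L)) {
    mins <- first_use[d]
    if (n_saba[d] == 2L) {
      s2 <- first_use[d] + second_gap[d]
      if (s2 <= 1439) mins <- c(mins, s2)
    }
    saba_min <- c(saba_min, (d - 1L) * 1440L + mins)
  }
  saba_min <- sort(unique(saba_min))

  dose_minute <- function(sched) {
    taken <- stats::runif(nd) < config$laba_adherence
    m <- round(stats::rnorm(nd, sched, config$dose_jitter_sd))
    m <- pmin(pmax(m, 0L), 1439L)
    (which(taken) - 1L) * 1440L + m[taken]
  }
  maint_min <- sort(unique(c(dose_minute(config$laba_morning_minute),
                             dose_minute(config$laba_evening_minute))))
  maint_type <- ifelse(status[maint_min %/% 1440L + 1L], "ICS_LABA", "ICS")

  ev_min <- c(saba_min, maint_min)
  ev_type <- c(rep("SABA", length(saba_min)), maint_type)

  # --- steps --------------------------------------------------------------
  nb <- stats::rpois(nd, config$bout_rate)
  bout_start <- bout_dur <- integer(0); bout_int <- numeric(0)
  for (d in seq_len(nd)) {
    if (nb[d] == 0L) next
    bout_start <- c(bout_start,
                    (d - 1L) * 1440L + sample(360:1319, nb[d], replace = TRUE))
    bout_dur <- c(bout_dur,
                  5L + stats::rpois(nb[d], max(config$bout_duration_mean - 5, 0)))
    bout_int <- c(bout_int,
                  pmax(stats::rnorm(nb[d], config$bout_intensity_mean,
                                    config$bout_intensity_sd), 0))
  }
  coupled <- stats::runif(length(saba_min)) < config$exercise_coupling_prob
  if (any(coupled)) {
    bout_start <- c(bout_start, saba_min[coupled] - 30L)
    bout_dur <- c(bout_dur, rep(121L, sum(coupled)))
    bout_int <- c(bout_int,
                  pmax(stats::rnorm(sum(coupled), config$coupled_intensity, 10),
                       0))
  }
  steps <- integer(n)
  for (b in seq_along(bout_start)) {
    if (bout_int[b] <= 0 || bout_dur[b] < 1L) next
    lo <- max(bout_start[b], 0L); hi <- min(bout_start[b] + bout_dur[b] - 1L,
                                            n - 1L)
    if (lo > hi) next
    seg <- (lo:hi) + 1L
    steps[seg] <- steps[seg] + stats::rpois(length(seg), bout_int[b])
  }

  # --- heart rate ---------------------------------------------------------
  hr <- config$mesor + config$amplitude *
    cos(2 * pi * (mod - config$acrophase_min) / 1440)
  if (length(config$laba_offset) == 1L) {
    hr <- hr + config$laba_offset * status[day + 1L]
  } else {
    hr <- hr + config$laba_offset[mod %/% 60L + 1L] * status[day + 1L]
  }
  kernel_track <- function(kernel, at) {
    contrib <- numeric(n)
    if (is.null(kernel) || !length(at)) return(contrib)
    rel <- seq.int(floor(kernel$t_min), ceiling(kernel$t_max))
    kv <- kernel_values(kernel, rel)
    for (e in at) {
      pos <- e + rel
      keep <- pos >= 0L & pos < n
      contrib[pos[keep] + 1L] <- contrib[pos[keep] + 1L] + kv[keep]
    }
    contrib
  }
  hr <- hr + kernel_track(config$saba_kernel, saba_min)
  if (!is.null(config$laba_acute_kernel))
    hr <- hr + kernel_track(config$laba_acute_kernel,
                            maint_min[maint_type == "ICS_LABA"])
  hr <- hr + config$activity_gain * .trailing_ma(steps, config$activity_window)
  noise <- stats::rnorm(n, 0, config$hr_noise_sd)
  if (config$ar1_phi != 0)
    noise <- as.numeric(stats::filter(noise, config$ar1_phi,
                                      method = "recursive"))
  hr <- hr + noise
  hr <- pmin(pmax(hr, config$clip[1L]), config$clip[2L])
  hr <- round(hr, config$hr_round)

  # --- wear mask ----------------------------------------------------------
  p_wear <- ifelse(mod < 360L, config$night_retention, config$day_retention)
  worn <- stats::runif(n) < p_wear
  gap_days <- which(stats::runif(nd) < config$gap_prob)
  if (length(gap_days)) {
    gs <- sample(0:1439, length(gap_days), replace = TRUE)
    for (i in seq_along(gap_days)) {
      lo <- (gap_days[i] - 1L) * 1440L + gs[i]
      hi <- min(lo + config$gap_minutes - 1L, n - 1L)
      worn[(lo:hi) + 1L] <- FALSE
    }
  }

  times <- t0 + 60 * idx
  hr_tab <- .new_minute_table(rep(patient_id, sum(worn)), times[worn],
                              hr[worn], "heart_rate_bpm")
  st_keep <- worn & steps > 0L
  st_tab <- .new_minute_table(rep(patient_id, sum(st_keep)), times[st_keep],
                              steps[st_keep], "steps_per_minute")
  ev_tab <- if (length(ev_min)) {
    event_log(patient_id, t0 + 60 * ev_min, ev_type)
  } else event_log(character(), .as_naive_time(character()), character())

  d0 <- config$start_date
  ms <- if (is.na(switch_day)) {
    med_status(patient_id, d0, d0 + nd - 1L, laba_user)
  } else {
    med_status(rep(patient_id, 2L),
               c(d0, d0 + switch_day),
               c(d0 + switch_day - 1L, d0 + nd - 1L),
               c(laba_user, !laba_user))
  }
  list(hr = hr_tab, steps = st_tab, events = ev_tab, medstatus = ms)
}

#' Simulate a full synthetic cohort
#'
#' Generates `config$n_patients` independent patients, assigning the first
#' `floor(laba_frac * n)` of a seeded random ordering a LABA-user timeline.
#' Per-patient seeds are derived deterministically from `seed`, so the whole
#' bundle is bit-identical for equal seeds.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return A [cohort_bundle()].
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  empty_min <- function(kind)
    .new_minute_table(character(), .as_naive_time(character()), numeric(),
                      kind)
  if (n == 0L)
    return(cohort_bundle(empty_min("heart_rate_bpm"),
                         empty_min("steps_per_minute"),
                         event_log(character(), .as_naive_time(character()),
                                   character()),
                         med_status(character(), as.Date(character()),
                                    as.Date(character()), logical())))
  set.seed(as.integer(seed))
  pat_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_laba <- floor(config$laba_frac * n)
  laba_users <- logical(n)
  laba_users[sample.int(n, n_laba)] <- TRUE
  ids <- sprintf("p%03d", seq_len(n))
  parts <- vector("list", n)
  for (i in seq_len(n))
    parts[[i]] <- simulate_patient(config, ids[i], pat_seeds[i],
                                   laba_users[i])
  # concatenate on numeric time to avoid repeated POSIXct method dispatch
  bind_minutes <- function(comp, kind) {
    pid <- unlist(lapply(parts, function(p) p[[comp]]$patient_id),
                  use.names = FALSE)
    tm <- unlist(lapply(parts, function(p) as.numeric(p[[comp]]$time)),
                 use.names = FALSE)
    val <- unlist(lapply(parts, function(p) p[[comp]]$value),
                  use.names = FALSE)
    df <- data.frame(patient_id = pid %||% character(),
                     time = as.POSIXct(tm %||% numeric(), tz = "UTC",
                                       origin = "1970-01-01"),
                     value = val %||% numeric(), stringsAsFactors = FALSE)
    structure(df, kind = kind, class = c("minute_table", "data.frame"))
  }
  hr <- bind_minutes("hr", "heart_rate_bpm")
  steps <- bind_minutes("steps", "steps_per_minute")
  ev <- do.call(rbind, lapply(parts, `[[`, "events"))
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ms <- do.call(rbind, lapply(parts, `[[`, "medstatus"))
  rownames(ms) <- NULL
  class(ms) <- c("medstatus_table", "data.frame")
  cohort_bundle(hr, steps, ev, ms)
}

#' Simulate cohorts from a generator configuration
#'
#' `simulate()` method for [cohort_config()] objects, returning a list of
#' `nsim` independent [cohort_bundle()]s with seeds derived from `seed`.
#'
#' @param object A `cohort_config`.
#' @param nsim Number of cohorts.
#' @param seed Integer master seed.
#' @param ... Unused.
#' @return A list of `cohort_bundle`s (length `nsim`).
#' @export
simulate.cohort_config <- function(object, nsim = 1, seed = 1L, ...) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  lapply(seeds, function(s) simulate_cohort(object, s))
}
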