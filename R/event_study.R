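# Self-controlled event study around inhaler actuations: control-day
# matching at the same clock minute, step-activity exclusion, minute-level
# difference curves, smoothing, and threshold-crossing summaries.
#
# Internally each patient's series are expanded onto an absolute minute grid
# (1-based index from midnight of the patient's first observed date), so
# control references, event windows and step-window sums are plain vector
# operations shared between the exported building blocks and the fitter.

.series_env <- function(hr, steps = NULL, extra_times = NULL,
                        extra_dates = NULL) {
  dates <- c(if (nrow(hr)) .naive_date(hr$time),
             if (!is.null(steps) && nrow(steps)) .naive_date(steps$time),
             if (length(extra_times)) .naive_date(extra_times),
             extra_dates)
  if (!length(dates))
    .stopf("no data to index for this patient",
           class = "beta2hr_analysis_error")
  day0 <- min(dates)
  nmin <- (as.integer(max(dates) - day0) + 1L) * 1440L
  base <- as.numeric(.midnight(day0))
  hrv <- rep(NA_real_, nmin)
  if (nrow(hr))
    hrv[round((as.numeric(hr$time) - base) / 60) + 1L] <- hr$value
  stv <- numeric(nmin)
  if (!is.null(steps) && nrow(steps))
    stv[round((as.numeric(steps$time) - base) / 60) + 1L] <- steps$value
  pres <- !is.na(hrv) | stv > 0
  list(day0 = day0, nmin = nmin, base = base, hrv = hrv, stv = stv,
       cs_st = c(0, cumsum(stv)), cs_pres = c(0L, cumsum(pres)),
       wear_days = sort(unique((which(!is.na(hrv)) - 1L) %/% 1440L)))
}

.day_index <- function(env, dates) as.integer(as.Date(dates) - env$day0)

.minute_index <- function(env, times)
  as.integer(round((as.numeric(times) - env$base) / 60)) + 1L

.pick_controls <- function(elig, event_day, n_each) {
  elig <- elig[elig != event_day]
  c(utils::tail(elig[elig < event_day], n_each),
    utils::head(elig[elig > event_day], n_each))
}

.window_count <- function(cs, lo, hi, nmin) {
  lo <- pmax(lo, 1L); hi <- pmin(hi, nmin)
  out <- cs[hi + 1L] - cs[lo]
  out[hi < lo] <- 0
  out
}

.control_ref <- function(hrv, nmin, control_days, m0, rel, min_days) {
  base1 <- control_days * 1440L + m0 + 1L
  idx <- outer(base1, rel, `+`)
  idx[idx < 1L | idx > nmin] <- NA_integer_
  vm <- matrix(hrv[idx], nrow = length(base1))
  cnt <- colSums(!is.na(vm))
  cm <- colSums(vm, na.rm = TRUE) / cnt
  cm[cnt < min_days] <- NA_real_
  list(mean = cm, n_days = cnt)
}

.steps_ref <- function(stv, nmin, control_days, m0, rel) {
  base1 <- control_days * 1440L + m0 + 1L
  idx <- outer(base1, rel, `+`)
  idx[idx < 1L | idx > nmin] <- NA_integer_
  vm <- matrix(stv[idx], nrow = length(base1))
  cnt <- colSums(!is.na(vm))
  list(mean = colSums(vm, na.rm = TRUE) / pmax(cnt, 1L), n_days = cnt)
}

#' Select clock-matched control days for an actuation
#'
#' Control days are calendar dates on which the patient recorded no SABA
#' actuation but did wear the device: the nearest `n_each` such dates before
#' the event date and the nearest `n_each` after (no topping-up across sides
#' when one side is short), at most `2 * n_each` in total.
#'
#' @param event_date Date of the actuation.
#' @param saba_dates Dates with at least one SABA actuation by this patient.
#' @param coverage_dates Dates with at least one worn heart-rate minute.
#' @param n_each Maximum control days per side (default 50).
#' @return Sorted vector of control `Date`s (possibly empty).
#' @export
select_control_days <- function(event_date, saba_dates, coverage_dates,
                                n_each = 50L) {
  event_date <- as.Date(event_date)
  elig <- sort(setdiff(as.Date(coverage_dates), as.Date(saba_dates)))
  picked <- .pick_controls(as.integer(elig), as.integer(event_date), n_each)
  as.Date(picked, origin = "1970-01-01")
}

#' Control-day reference heart rate on the relative-minute grid
#'
#' For each relative minute `r` in `-pre..post`, the mean over control dates
#' of the heart rate at clock minute `event_minute + r`, spilling into the
#' adjacent calendar date when the shifted minute crosses midnight. Minutes
#' covered by fewer than `min_control_days` control-day values are undefined
#' (`NA`).
#'
#' @param hr Heart-rate `minute_table` of a single patient.
#' @param control_days Control dates (see [select_control_days()]).
#' @param event_minute Minute-of-day (0-1439) of the actuation.
#' @param pre,post Window extent in minutes (defaults 180 and 600).
#' @param min_control_days Minimum control-day values per minute (default 10).
#' @return Data frame `relative_minute`, `control_mean`, `n_control_days`.
#' @export
control_reference <- function(hr, control_days, event_minute, pre = 180L,
                              post = 600L, min_control_days = 10L) {
  stopifnot(inherits(hr, "minute_table"),
            length(unique(hr$patient_id)) <= 1L)
  if (!length(control_days))
    .stopf("empty control-day set", class = "beta2hr_analysis_error")
  env <- .series_env(hr, extra_dates = as.Date(control_days))
  rel <- seq.int(-pre, post)
  ref <- .control_ref(env$hrv, env$nmin, .day_index(env, control_days),
                      as.integer(event_minute), rel, min_control_days)
  data.frame(relative_minute = rel, control_mean = ref$mean,
             n_control_days = ref$n_days)
}

#' Step-activity exclusion decision for one actuation
#'
#' Compares the steps taken in the inhalation period (one hour before to one
#' hour after the actuation) with the same clock window on the control days:
#' the event is kept when its step total is at most the control mean plus two
#' control SDs (sample SD; strictly exceeding excludes). Step minutes without
#' a recorded value count as zero while the device was worn; if the entire
#' window holds no wear at all the event is excluded, as it is when fewer
#' than `min_step_days` control days cover the window.
#'
#' @param steps Step-count `minute_table` of a single patient.
#' @param hr Heart-rate `minute_table` of the same patient (wear indicator).
#' @param event_time Actuation timestamp.
#' @param control_days Control dates.
#' @param halfwidth Window half-width in minutes (default 60).
#' @param min_step_days Minimum control days with wear in the window.
#' @return A one-row data frame: `event_window_steps`, `control_mean`,
#'   `control_sd`, `n_control_days`, `included`, `reason`.
#' @export
step_activity_filter <- function(steps, hr, event_time, control_days,
                                 halfwidth = 60L, min_step_days = 2L) {
  stopifnot(inherits(steps, "minute_table"))
  env <- .series_env(hr, steps, extra_times = event_time,
                     extra_dates = as.Date(control_days))
  ek <- .minute_index(env, event_time)
  dec <- .step_decision(env, ek, .day_index(env, control_days),
                        halfwidth, min_step_days)
  data.frame(event_window_steps = dec$event_steps,
             control_mean = dec$mean, control_sd = dec$sd,
             n_control_days = dec$n_days,
             included = dec$included, reason = dec$reason)
}

.step_decision <- function(env, ek, control_days, halfwidth, min_step_days) {
  out <- list(event_steps = NA_real_, mean = NA_real_, sd = NA_real_,
              n_days = NA_integer_, included = FALSE, reason = "")
  wear <- .window_count(env$cs_pres, ek - halfwidth, ek + halfwidth, env$nmin)
  if (wear == 0) { out$reason <- "no_wear"; return(out) }
  out$event_steps <- .window_count(env$cs_st, ek - halfwidth, ek + halfwidth,
                                   env$nmin)
  m0 <- (ek - 1L) %% 1440L
  centers <- control_days * 1440L + m0 + 1L
  covered <- .window_count(env$cs_pres, centers - halfwidth,
                           centers + halfwidth, env$nmin) > 0
  if (sum(covered) < min_step_days) {
    out$reason <- "no_controls"
    return(out)
  }
  tot <- .window_count(env$cs_st, centers[covered] - halfwidth,
                       centers[covered] + halfwidth, env$nmin)
  out$mean <- mean(tot); out$sd <- stats::sd(tot)
  out$n_days <- sum(covered)
  if (out$event_steps > out$mean + 2 * out$sd) {
    out$reason <- "steps"
  } else {
    out$included <- TRUE; out$reason <- "included"
  }
  out
}

#' Self-controlled event study around inhaler actuations
#'
#' Fits the minute-level difference curve between event days and
#' clock-time-matched control days around every actuation of the requested
#' inhaler type. For SABA the analysis is self-controlled: each actuation is
#' compared with the heart rate at the exact same clock minutes on up to 50
#' SABA-free days before and 50 after, optionally after excluding actuations
#' whose surrounding step count betrays physical exercise
#' ([step_activity_filter()]). For LABA (pooled with ICS_LABA) no SABA-free
#' reference is defined and the raw event-aligned mean heart-rate curve is
#' returned instead, since maintenance inhalations follow the clock and any
#' subtraction would itself be circadian-confounded.
#'
#' At each relative minute the event mean and control mean are taken over the
#' included actuations that have both an event-day value and a defined
#' control reference at that minute, so the difference is a paired contrast;
#' minutes failing the coverage rules are undefined, never zero.
#'
#' @param bundle A [cohort_bundle()].
#' @param inhaler `"SABA"` or `"LABA"` (the latter pools LABA and ICS_LABA
#'   actuations).
#' @param pre,post Window extent in minutes before/after the actuation
#'   (defaults 180 and 600; minute 0 is the actuation minute).
#' @param n_control Maximum control days on each side (default 50).
#' @param min_control_days Minimum control-day values per relative minute for
#'   the control mean to be defined (default 10).
#' @param step_filter Apply the step-activity exclusion (default TRUE;
#'   ignored for the LABA alignment).
#' @param threshold Clinical-relevance threshold in bpm for the crossing
#'   summary (default 5).
#' @param span Smoothing span passed to [smooth_curve()].
#' @param refractory_min Optionally drop actuations occurring within this
#'   many minutes after a previous actuation of the same type (default 0 =
#'   keep every actuation).
#' @param min_step_days Minimum control days with wear for the step filter's
#'   SD to be defined (default 2).
#' @return An object of class `event_study` with components `curve`
#'   (relative_minute, event_mean, control_mean, difference, n_events,
#'   n_control_days), `crossings` (a [crossing_summary()], SABA only),
#'   `smooth`, `steps_curve` (mean steps around the actuation on event vs
#'   control days), `events` (per-actuation decisions), `accounting`
#'   (inclusion/exclusion counts) and the fitting parameters.
#' @export
event_study <- function(bundle, inhaler = c("SABA", "LABA"), pre = 180L,
                        post = 600L, n_control = 50L, min_control_days = 10L,
                        step_filter = TRUE, threshold = 5, span = 0.15,
                        refractory_min = 0L, min_step_days = 2L) {
  inhaler <- match.arg(inhaler)
  stopifnot(inherits(bundle, "cohort_bundle"))
  matched <- inhaler == "SABA"
  types <- if (matched) "SABA" else c("LABA", "ICS_LABA")
  ev_all <- bundle$events[bundle$events$inhaler_type %in% types, ,
                          drop = FALSE]
  if (!nrow(ev_all))
    .stopf("no %s actuations in the bundle", inhaler,
           class = "beta2hr_no_events")

  rel <- seq.int(-pre, post)
  nrel <- length(rel)
  acc <- list(ev = numeric(nrel), ct = numeric(nrel), n = integer(nrel),
              ncd = numeric(nrel),
              sev = numeric(nrel), sev_n = integer(nrel),
              sct = numeric(nrel), sct_n = integer(nrel))
  ev_rows <- list()

  for (pid in unique(ev_all$patient_id)) {
    times <- ev_all$time[ev_all$patient_id == pid]
    if (refractory_min > 0L && length(times) > 1L) {
      keep <- c(TRUE, diff(as.numeric(times)) / 60 > refractory_min)
      times <- times[keep]
    }
    hr_pat <- bundle$hr[bundle$hr$patient_id == pid, , drop = FALSE]
    st_pat <- bundle$steps[bundle$steps$patient_id == pid, , drop = FALSE]
    saba_times <- bundle$events$time[bundle$events$patient_id == pid &
                                       bundle$events$inhaler_type == "SABA"]
    env <- .series_env(hr_pat, st_pat, extra_times = c(times, saba_times))
    saba_days <- unique((.minute_index(env, saba_times) - 1L) %/% 1440L)
    elig <- setdiff(env$wear_days, saba_days)

    for (tt in seq_along(times)) {
      et <- times[tt]
      ek <- .minute_index(env, et)
      ed <- (ek - 1L) %/% 1440L
      m0 <- (ek - 1L) %% 1440L
      row <- data.frame(patient_id = pid, time = et, included = FALSE,
                        reason = "", n_control_days = 0L,
                        event_window_steps = NA_real_,
                        control_steps_mean = NA_real_,
                        control_steps_sd = NA_real_)
      if (!matched) {
        # raw event-aligned mean; every actuation contributes
        idx <- ek + rel
        idx[idx < 1L | idx > env$nmin] <- NA_integer_
        v <- env$hrv[idx]
        ok <- !is.na(v)
        acc$ev[ok] <- acc$ev[ok] + v[ok]
        acc$n[ok] <- acc$n[ok] + 1L
        row$included <- TRUE; row$reason <- "included"
        ev_rows[[length(ev_rows) + 1L]] <- row
        next
      }
      cd <- .pick_controls(elig, ed, n_control)
      if (!length(cd)) {
        row$reason <- "no_controls"
        ev_rows[[length(ev_rows) + 1L]] <- row
        next
      }
      row$n_control_days <- length(cd)
      # steps around the actuation, event vs control days (activity figure);
      # accumulated before the step filter so the exercise confound is visible
      idx <- ek + rel
      idx[idx < 1L | idx > env$nmin] <- NA_integer_
      sv <- env$stv[idx]
      sok <- !is.na(sv)
      acc$sev[sok] <- acc$sev[sok] + sv[sok]
      acc$sev_n[sok] <- acc$sev_n[sok] + 1L
      sref <- .steps_ref(env$stv, env$nmin, cd, m0, rel)
      cok <- sref$n_days > 0
      acc$sct[cok] <- acc$sct[cok] + sref$mean[cok]
      acc$sct_n[cok] <- acc$sct_n[cok] + 1L
      if (step_filter) {
        dec <- .step_decision(env, ek, cd, 60L, min_step_days)
        row$event_window_steps <- dec$event_steps
        row$control_steps_mean <- dec$mean
        row$control_steps_sd <- dec$sd
        if (!dec$included) {
          row$reason <- dec$reason
          ev_rows[[length(ev_rows) + 1L]] <- row
          next
        }
      }
      ref <- .control_ref(env$hrv, env$nmin, cd, m0, rel, min_control_days)
      v <- env$hrv[idx]
      ok <- !is.na(v) & !is.na(ref$mean)
      acc$ev[ok] <- acc$ev[ok] + v[ok]
      acc$ct[ok] <- acc$ct[ok] + ref$mean[ok]
      acc$n[ok] <- acc$n[ok] + 1L
      acc$ncd[ok] <- acc$ncd[ok] + ref$n_days[ok]
      row$included <- TRUE; row$reason <- "included"
      ev_rows[[length(ev_rows) + 1L]] <- row
    }
  }

  events <- do.call(rbind, ev_rows)
  rownames(events) <- NULL
  counts <- table(factor(events$reason,
                         levels = c("included", "steps", "no_controls",
                                    "no_wear")))
  accounting <- data.frame(
    category = c("total", "included", "excluded_by_steps",
                 "excluded_no_controls", "excluded_no_wear"),
    n_events = c(nrow(events), as.integer(counts)))
  if (counts[["included"]] == 0L) {
    excl <- counts[-1L]
    .stopf("all %d %s events excluded (dominant reason: %s)", nrow(events),
           inhaler, names(excl)[which.max(excl)],
           class = "beta2hr_analysis_error")
  }

  event_mean <- ifelse(acc$n > 0L, acc$ev / acc$n, NA_real_)
  if (matched) {
    control_mean <- ifelse(acc$n > 0L, acc$ct / acc$n, NA_real_)
    difference <- event_mean - control_mean
  } else {
    control_mean <- rep(NA_real_, nrel)
    difference <- rep(NA_real_, nrel)
  }
  curve <- data.frame(relative_minute = rel, event_mean = event_mean,
                      control_mean = control_mean, difference = difference,
                      n_events = acc$n, n_control_days = acc$ncd)
  steps_curve <- if (matched) {
    data.frame(relative_minute = rel,
               event_steps = ifelse(acc$sev_n > 0L, acc$sev / acc$sev_n,
                                    NA_real_),
               control_steps = ifelse(acc$sct_n > 0L, acc$sct / acc$sct_n,
                                      NA_real_))
  } else NULL

  crossings <- if (matched) crossing_summary(curve, threshold) else NULL
  smooth <- tryCatch(
    smooth_curve(curve, span,
                 column = if (matched) "difference" else "event_mean"),
    error = function(e) NULL)

  structure(list(curve = curve, crossings = crossings, smooth = smooth,
                 steps_curve = steps_curve, events = events,
                 accounting = accounting, inhaler = inhaler,
                 threshold = threshold,
                 params = list(pre = pre, post = post, n_control = n_control,
                               min_control_days = min_control_days,
                               step_filter = step_filter, span = span,
                               refractory_min = refractory_min,
                               min_step_days = min_step_days),
                 call = match.call()),
            class = "event_study")
}

#' Threshold-crossing summary of a difference curve
#'
#' Summarises where the (unsmoothed) event-minus-control heart-rate
#' difference reaches the clinical-relevance threshold: the earliest
#' pre-event minute at or above the threshold (scanning forward from the
#' start of the window), the value at the actuation minute, the location and
#' size of the maximum, and the return time, reported as the first minute
#' after which no further exceedance occurs (last exceeding minute + 1).
#' Fields are `NA` when the curve never qualifies (absent, not an error).
#'
#' @param curve An [event_study()] fit or a data frame with columns
#'   `relative_minute` and `difference`.
#' @param threshold Threshold in bpm (default 5).
#' @return An object of class `crossing_summary`: list with `threshold`,
#'   `first_exceed_pre`, `value_at_t0`, `peak_lag`, `peak_diff`,
#'   `return_min`, `n_defined`.
#' @export
crossing_summary <- function(curve, threshold = 5) {
  if (inherits(curve, "event_study")) curve <- curve$curve
  stopifnot(all(c("relative_minute", "difference") %in% names(curve)))
  r <- curve$relative_minute
  d <- curve$difference
  o <- order(r); r <- r[o]; d <- d[o]
  def <- !is.na(d)
  pre_hits <- r[def & r < 0 & d >= threshold]
  post_hits <- r[def & r > 0 & d >= threshold]
  peak_lag <- NA_integer_; peak_diff <- NA_real_
  if (any(def)) {
    peak_diff <- max(d[def])
    peak_lag <- r[def][which.max(d[def])]
  }
  structure(list(
    threshold = threshold,
    first_exceed_pre = if (length(pre_hits)) pre_hits[1L] else NA_integer_,
    value_at_t0 = if (any(def & r == 0)) d[r == 0] else NA_real_,
    peak_lag = peak_lag, peak_diff = peak_diff,
    return_min = if (length(post_hits)) max(post_hits) + 1L else NA_integer_,
    n_defined = sum(def)), class = "crossing_summary")
}

#' @export
print.crossing_summary <- function(x, ...) {
  cat(sprintf("Threshold-crossing summary (threshold %.1f bpm, %d defined minutes)\n",
              x$threshold, x$n_defined))
  cat(sprintf("  first pre-event exceedance: %s min\n",
              format(x$first_exceed_pre)))
  cat(sprintf("  value at actuation minute: %s bpm\n",
              format(round(x$value_at_t0, 2))))
  cat(sprintf("  peak: %s bpm at +%s min\n", format(round(x$peak_diff, 2)),
              format(x$peak_lag)))
  cat(sprintf("  return below threshold after: %s min\n",
              format(x$return_min)))
  invisible(x)
}

#' Locally weighted smoothing of a minute-level curve
#'
#' Degree-1 locally weighted regression (tricube weights) over the defined
#' relative minutes, with the span expressed as a fraction of the defined
#' points. Undefined minutes are skipped, not interpolated into existence.
#'
#' @param curve An [event_study()] fit or a data frame with
#'   `relative_minute` and the column to smooth.
#' @param span Span as a fraction of the defined minutes (default 0.15).
#' @param column Column to smooth (default `"difference"`).
#' @return Data frame `relative_minute`, `smooth` at the defined minutes.
#' @export
smooth_curve <- function(curve, span = 0.15, column = "difference") {
  if (inherits(curve, "event_study")) curve <- curve$curve
  stopifnot(column %in% names(curve))
  def <- !is.na(curve[[column]])
  if (sum(def) < 10L)
    .stopf("too few defined minutes (%d) to smooth", sum(def),
           class = "beta2hr_analysis_error")
  r <- curve$relative_minute[def]
  y <- curve[[column]][def]
  fit <- stats::loess(y ~ r, span = span, degree = 1, family = "gaussian",
                      surface = "direct")
  data.frame(relative_minute = r, smooth = stats::fitted(fit))
}

#' @export
print.event_study <- function(x, ...) {
  cat(sprintf("Event study around %s actuations\n", x$inhaler))
  a <- stats::setNames(x$accounting$n_events, x$accounting$category)
  cat(sprintf("  events: %d total, %d included (%d step-excluded, %d without controls, %d without wear)\n",
              a[["total"]], a[["included"]], a[["excluded_by_steps"]],
              a[["excluded_no_controls"]], a[["excluded_no_wear"]]))
  if (!is.null(x$crossings)) print(x$crossings)
  invisible(x)
}

#' @export
summary.event_study <- function(object, ...) {
  print(object)
  cur <- object$curve
  def <- !is.na(cur$difference)
  if (any(def))
    cat(sprintf("  difference defined at %d/%d minutes; mean over window %.2f bpm\n",
                sum(def), nrow(cur), mean(cur$difference[def])))
  invisible(object)
}

#' @export
coef.event_study <- function(object, ...) {
  if (is.null(object$crossings)) return(NULL)
  x <- object$crossings
  c(first_exceed_pre = as.numeric(x$first_exceed_pre),
    value_at_t0 = x$value_at_t0, peak_lag = as.numeric(x$peak_lag),
    peak_diff = x$peak_diff, return_min = as.numeric(x$return_min))
}

#' @export
plot.event_study <- function(x, ...) {
  cur <- x$curve
  if (x$inhaler == "SABA") {
    graphics::plot(cur$relative_minute, cur$difference, pch = ".",
                   col = "darkgreen", xlab = "minutes from actuation",
                   ylab = "HR difference, event - control (bpm)", ...)
    if (!is.null(x$smooth))
      graphics::lines(x$smooth$relative_minute, x$smooth$smooth,
                      col = "blue", lwd = 2)
    graphics::abline(h = c(0, x$threshold), lty = c(1, 3))
    graphics::abline(v = 0, lty = 3)
  } else {
    graphics::plot(cur$relative_minute, cur$event_mean, pch = ".",
                   col = "darkgreen", xlab = "minutes from actuation",
                   ylab = "mean heart rate (bpm)", ...)
    if (!is.null(x$smooth))
      graphics::lines(x$smooth$relative_minute, x$smooth$smooth,
                      col = "blue", lwd = 2)
    graphics::abline(v = 0, lty = 3)
  }
  invisible(x)
}
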