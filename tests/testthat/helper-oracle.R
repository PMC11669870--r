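# Independent brute-force oracles. These re-derive the analyses with plain
# nested loops and data-frame lookups, sharing no code with the package
# internals, and are only run on tiny inputs.

oracle_hourly_means <- function(hr_with_status) {
  sub <- hr_with_status[hr_with_status$laba_status != "unknown", ]
  out <- NULL
  for (pid in sort(unique(sub$patient_id))) {
    for (st in sort(unique(sub$laba_status[sub$patient_id == pid]))) {
      rows <- sub[sub$patient_id == pid & sub$laba_status == st, ]
      for (h in 0:23) {
        v <- rows$value[as.integer(format(rows$time, "%H", tz = "UTC")) == h]
        if (length(v))
          out <- rbind(out, data.frame(patient_id = pid, laba_status = st,
                                       hour = h, mean_bpm = mean(v),
                                       n_minutes = length(v)))
      }
    }
  }
  out
}

# Mean heart rate of one patient at one exact minute, NA when not worn.
.olook <- function(df, time) {
  j <- which(as.numeric(df$time) == as.numeric(time))
  if (length(j)) df$value[j] else NA_real_
}

oracle_event_study <- function(bundle, pre = 180, post = 600,
                               n_control = 50, min_control_days = 10,
                               step_filter = TRUE, min_step_days = 2,
                               threshold = 5) {
  rel <- -pre:post
  ev_sum <- ct_sum <- numeric(length(rel))
  n_ev <- integer(length(rel))
  events <- bundle$events[bundle$events$inhaler_type == "SABA", ]
  reasons <- character(0)
  for (i in seq_len(nrow(events))) {
    pid <- events$patient_id[i]
    et <- events$time[i]
    hr <- bundle$hr[bundle$hr$patient_id == pid, ]
    st <- bundle$steps[bundle$steps$patient_id == pid, ]
    saba_dates <- unique(as.Date(
      bundle$events$time[bundle$events$patient_id == pid &
                           bundle$events$inhaler_type == "SABA"],
      tz = "UTC"))
    wear_dates <- sort(unique(as.Date(hr$time, tz = "UTC")))
    ed <- as.Date(et, tz = "UTC")
    elig <- wear_dates[!wear_dates %in% saba_dates & wear_dates != ed]
    before <- elig[elig < ed]
    after <- elig[elig > ed]
    cd <- c(utils::tail(before, n_control), utils::head(after, n_control))
    if (!length(cd)) { reasons <- c(reasons, "no_controls"); next }
    worn_at <- function(tt) {
      !is.na(.olook(hr, tt)) ||
        (!is.na(v <- .olook(st, tt)) && v > 0)
    }
    steps_at <- function(tt) {
      v <- .olook(st, tt)
      if (is.na(v)) 0 else v
    }
    if (step_filter) {
      win <- et + 60 * (-60:60)
      if (!any(vapply(win, worn_at, logical(1)))) {
        reasons <- c(reasons, "no_wear"); next
      }
      ev_tot <- sum(vapply(win, steps_at, numeric(1)))
      m0 <- as.numeric(et) %% 86400 / 60
      ctot <- numeric(0)
      for (d in seq_along(cd)) {
        c0 <- as.POSIXct(paste(format(cd[d]), "00:00:00"), tz = "UTC") +
          60 * m0
        cwin <- c0 + 60 * (-60:60)
        if (any(vapply(cwin, worn_at, logical(1))))
          ctot <- c(ctot, sum(vapply(cwin, steps_at, numeric(1))))
      }
      if (length(ctot) < min_step_days) {
        reasons <- c(reasons, "no_controls"); next
      }
      if (ev_tot > mean(ctot) + 2 * stats::sd(ctot)) {
        reasons <- c(reasons, "steps"); next
      }
    }
    reasons <- c(reasons, "included")
    m0 <- as.numeric(et) %% 86400 / 60
    for (k in seq_along(rel)) {
      evv <- .olook(hr, et + 60 * rel[k])
      if (is.na(evv)) next
      cv <- numeric(0)
      for (d in seq_along(cd)) {
        c0 <- as.POSIXct(paste(format(cd[d]), "00:00:00"), tz = "UTC") +
          60 * m0
        x <- .olook(hr, c0 + 60 * rel[k])
        if (!is.na(x)) cv <- c(cv, x)
      }
      if (length(cv) < min_control_days) next
      ev_sum[k] <- ev_sum[k] + evv
      ct_sum[k] <- ct_sum[k] + mean(cv)
      n_ev[k] <- n_ev[k] + 1L
    }
  }
  event_mean <- ifelse(n_ev > 0, ev_sum / n_ev, NA_real_)
  control_mean <- ifelse(n_ev > 0, ct_sum / n_ev, NA_real_)
  list(curve = data.frame(relative_minute = rel, event_mean = event_mean,
                          control_mean = control_mean,
                          difference = event_mean - control_mean,
                          n_events = n_ev),
       reasons = reasons)
}

oracle_boot_ci <- function(profiles, boot, conf = 0.95) {
  ids1 <- unique(profiles$patient_id[profiles$laba_status == "laba"])
  ids0 <- unique(profiles$patient_id[profiles$laba_status == "non_laba"])
  one <- function() {
    s1 <- sample(ids1, replace = TRUE)
    s0 <- sample(ids0, replace = TRUE)
    gm <- function(ids, st) {
      rows <- do.call(rbind, lapply(ids, function(id)
        profiles[profiles$patient_id == id & profiles$laba_status == st, ]))
      sapply(0:23, function(h) {
        v <- rows$mean_bpm[rows$hour == h]
        if (length(v)) mean(v) else NA_real_
      })
    }
    d <- gm(s1, "laba") - gm(s0, "non_laba")
    mean(d[is.finite(d)])
  }
  reps <- replicate(boot, one())
  stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
}
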