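# Small construction helpers for hand-built bundles.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# A minute grid of `n` minutes starting at `from` (inclusive).
minute_grid <- function(from, n) ts(from) + 60 * (seq_len(n) - 1L)

hr_series <- function(pid, time, value)
  minute_series(pid, time, value, "heart_rate_bpm")

step_series <- function(pid, time, value)
  minute_series(pid, time, value, "steps_per_minute")

empty_hr <- function() hr_series(character(), ts(character()), numeric())
empty_steps <- function() step_series(character(), ts(character()), numeric())
empty_events <- function() event_log(character(), ts(character()), character())
empty_medstatus <- function()
  med_status(character(), as.Date(character()), as.Date(character()),
             logical())

# Bundle with a single patient holding constant heart rate over `days` full
# days (all 1440 minutes worn), optional events and steps.
constant_bundle <- function(pid = "p1", days = 10, hr = 70,
                            start = "2016-03-01", events = NULL,
                            steps = NULL, laba = FALSE) {
  n <- days * 1440L
  tm <- minute_grid(paste(start, "00:00:00"), n)
  hr_tab <- hr_series(pid, tm, rep(hr, n))
  ev <- events %||% empty_events()
  st <- steps %||% empty_steps()
  ms <- med_status(pid, as.Date(start), as.Date(start) + days - 1, laba)
  cohort_bundle(hr_tab, st, ev, ms)
}

merge_bundles <- function(...) {
  parts <- list(...)
  bind <- function(comp, cls, kind = NULL) {
    df <- do.call(rbind, lapply(parts, function(b) as.data.frame(b[[comp]])))
    rownames(df) <- NULL
    if (!is.null(kind)) attr(df, "kind") <- kind
    class(df) <- c(cls, "data.frame")
    df
  }
  cohort_bundle(bind("hr", "minute_table", "heart_rate_bpm"),
                bind("steps", "minute_table", "steps_per_minute"),
                bind("events", "event_table"),
                bind("medstatus", "medstatus_table"))
}
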