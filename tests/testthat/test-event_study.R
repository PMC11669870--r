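# Deterministic building-block checks plus oracle equivalence of the full
# event study on small bundles.

test_that("control-day selection caps each side at 50 without topping up", {
  cov_dates <- as.Date("2016-01-01") + 0:364
  saba_dates <- as.Date("2016-06-15")
  cd <- select_control_days(as.Date("2016-06-15"), saba_dates, cov_dates)
  expect_equal(length(cd), 100L)
  expect_equal(sum(cd < as.Date("2016-06-15")), 50L)
  expect_equal(max(abs(as.integer(cd - as.Date("2016-06-15")))), 50L)
  # 30 eligible before, plenty after: 30 + 50, no topping up
  cd2 <- select_control_days(as.Date("2016-01-31"),
                             saba_dates = as.Date("2015-12-31"),
                             coverage_dates = as.Date("2016-01-01") + 0:364)
  expect_equal(length(cd2), 80L)
  # daily SABA user: nothing eligible
  cd3 <- select_control_days(as.Date("2016-01-10"),
                             saba_dates = cov_dates, coverage_dates = cov_dates)
  expect_equal(length(cd3), 0L)
})

test_that("control reference matches clock minutes and spills over midnight", {
  # value encodes absolute minute index so lookups are verifiable
  days <- as.Date("2016-04-01") + 0:9
  tm <- minute_grid("2016-04-01 00:00:00", 10 * 1440)
  val <- 40 + (seq_along(tm) - 1) %% 1440 / 100   # 40.00 .. 54.39 by clock
  hr <- hr_series("p1", tm, val)
  ref <- control_reference(hr, days[2:6], event_minute = 23 * 60 + 30,
                           min_control_days = 2)
  expect_equal(nrow(ref), 781L)
  # +120 min from 23:30 is 01:30 next day: clock minute 90
  expect_equal(ref$control_mean[ref$relative_minute == 120], 40 + 90 / 100)
  expect_equal(ref$control_mean[ref$relative_minute == 0], 40 + 1410 / 100)
  expect_equal(ref$n_control_days[ref$relative_minute == 120], 5L)
  # constant patient: 70 everywhere
  hr70 <- hr_series("p2", tm, rep(70, length(tm)))
  ref70 <- control_reference(hr70, days[2:6], 600, min_control_days = 2)
  expect_true(all(ref70$control_mean == 70))
})

test_that("minutes with too few control days are undefined", {
  tm <- minute_grid("2016-04-01 08:00:00", 60)  # one hour on one day only
  hr <- hr_series("p1", tm, rep(70, 60))
  ref <- control_reference(hr, as.Date("2016-04-01"), 8 * 60,
                           min_control_days = 2)
  expect_true(all(is.na(ref$control_mean)))
})

test_that("step filter applies the mean + 2 SD rule with sample SD", {
  mk_steps <- function(day_totals, event_steps) {
    # each control day gets its total as a single minute at 12:00
    days <- as.Date("2016-04-02") + seq_along(day_totals) - 1
    st_tm <- ts(paste(format(days), "12:00:00"))
    st <- step_series("p1", c(st_tm, ts("2016-04-01 12:00:00")),
                      c(day_totals, event_steps))
    hr_tm <- unlist(lapply(c(as.Date("2016-04-01"), days), function(d)
      as.numeric(ts(paste(format(d), "11:00:00"))) + 60 * (0:119)))
    hr <- hr_series("p1", as.POSIXct(hr_tm, tz = "UTC",
                                     origin = "1970-01-01"),
                    rep(70, length(hr_tm)))
    list(st = st, hr = hr, days = days)
  }
  x <- mk_steps(c(100, 100, 100), 101)
  d <- step_activity_filter(x$st, x$hr, ts("2016-04-01 12:00:00"), x$days)
  expect_equal(d$control_mean, 100)
  expect_equal(d$control_sd, 0)
  expect_false(d$included)            # 101 > 100 + 0, strict exceedance
  expect_equal(d$reason, "steps")

  x <- mk_steps(c(100, 100, 100), 100)
  d <- step_activity_filter(x$st, x$hr, ts("2016-04-01 12:00:00"), x$days)
  expect_true(d$included)             # equality includes

  x <- mk_steps(c(0, 200), 300)
  d <- step_activity_filter(x$st, x$hr, ts("2016-04-01 12:00:00"), x$days)
  expect_equal(d$control_mean, 100)
  expect_equal(d$control_sd, 141.4214, tolerance = 1e-6)
  expect_true(d$included)             # 300 <= 382.84

  # zero steps everywhere: included (0 <= 0 + 0)
  x <- mk_steps(c(0, 0, 0), 0)
  d <- step_activity_filter(x$st, x$hr, ts("2016-04-01 12:00:00"), x$days)
  expect_true(d$included)
})

test_that("step filter excludes events without wear or control coverage", {
  # wear exists only on control days, not around the event
  days <- as.Date("2016-04-02") + 0:2
  hr_tm <- unlist(lapply(days, function(d)
    as.numeric(ts(paste(format(d), "11:30:00"))) + 60 * (0:59)))
  hr <- hr_series("p1", as.POSIXct(hr_tm, tz = "UTC", origin = "1970-01-01"),
                  rep(70, length(hr_tm)))
  d <- step_activity_filter(empty_steps(), hr, ts("2016-04-01 12:00:00"),
                            days)
  expect_false(d$included)
  expect_equal(d$reason, "no_wear")
  # wear around the event but fewer than 2 control days covered
  hr2_tm <- c(as.numeric(ts("2016-04-01 12:00:00")) + 60 * (0:30),
              as.numeric(ts("2016-04-02 12:00:00")) + 60 * (0:30))
  hr2 <- hr_series("p1", as.POSIXct(hr2_tm, tz = "UTC",
                                    origin = "1970-01-01"),
                   rep(70, length(hr2_tm)))
  d2 <- step_activity_filter(empty_steps(), hr2, ts("2016-04-01 12:00:00"),
                             days)
  expect_false(d2$included)
  expect_equal(d2$reason, "no_controls")
})

test_that("crossing summary reads the landmark geometry off a curve", {
  flat <- data.frame(relative_minute = -180:600, difference = 0)
  cs <- crossing_summary(flat)
  expect_true(is.na(cs$first_exceed_pre))
  expect_true(is.na(cs$return_min))
  expect_equal(cs$peak_diff, 0)
  expect_equal(cs$value_at_t0, 0)

  # curve equal to the reference kernel evaluated on the grid: landmarks
  # frozen from direct evaluation (kernel(138) = 5 counts as an exceedance,
  # so the reported return time is 139 = last exceedance + 1)
  k <- saba_profile_kernel()
  kcurve <- data.frame(relative_minute = -180:600,
                       difference = kernel_values(k, -180:600))
  cs2 <- crossing_summary(kcurve, threshold = 5)
  expect_equal(cs2$first_exceed_pre, -17)
  expect_equal(cs2$value_at_t0, 9)
  expect_equal(cs2$peak_lag, 9)
  expect_equal(cs2$peak_diff, 10)
  expect_equal(cs2$return_min, 139)

  # undefined minutes stay undefined; curve defined only after t0
  part <- data.frame(relative_minute = -180:600,
                     difference = ifelse(-180:600 >= 0,
                                         kernel_values(k, -180:600),
                                         NA_real_))
  cs3 <- crossing_summary(part)
  expect_true(is.na(cs3$first_exceed_pre))
  expect_equal(cs3$peak_lag, 9)
})

test_that("the smoother reproduces constants and straight lines", {
  r <- -180:600
  const <- data.frame(relative_minute = r, difference = rep(3, length(r)))
  s1 <- smooth_curve(const, span = 0.15)
  expect_equal(s1$smooth, rep(3, length(r)), tolerance = 1e-8)
  lin <- data.frame(relative_minute = r, difference = 1 + 0.01 * r)
  s2 <- smooth_curve(lin, span = 0.15)
  expect_equal(s2$smooth, 1 + 0.01 * r, tolerance = 1e-6)
  tiny <- data.frame(relative_minute = 1:5, difference = rnorm(5))
  expect_error(smooth_curve(tiny), class = "beta2hr_analysis_error")
})

test_that("smoothing reduces the error against the underlying kernel", {
  k <- saba_profile_kernel()
  r <- -180:600
  truth <- kernel_values(k, r)
  set.seed(123)
  wins <- 0L
  for (i in 1:50) {
    noisy <- truth + rnorm(length(r), 0, 1.5)
    sm <- smooth_curve(data.frame(relative_minute = r, difference = noisy),
                       span = 0.15)$smooth
    if (max(abs(sm - truth)) < max(abs(noisy - truth))) wins <- wins + 1L
  }
  expect_gte(wins, 48L)   # >= 95% of 50 seeded runs
})

test_that("event study equals the nested-loop oracle exactly on toy bundles", {
  # 3 patients x 10 days with noise, gaps, activity and frequent events
  cfg <- cohort_config(n_patients = 3, days_per_patient = 10,
                       hr_noise_sd = 4, saba_day_prob = c(0.6, 0.2),
                       bout_rate = 2, exercise_coupling_prob = 0.5,
                       day_retention = 0.9)
  b <- simulate_cohort(cfg, 17)
  got <- event_study(b, "SABA", n_control = 3, min_control_days = 2,
                     step_filter = TRUE)
  want <- oracle_event_study(b, n_control = 3, min_control_days = 2,
                             step_filter = TRUE)
  expect_equal(got$curve$event_mean, want$curve$event_mean, tolerance = 1e-10)
  expect_equal(got$curve$control_mean, want$curve$control_mean,
               tolerance = 1e-10)
  expect_equal(got$curve$difference, want$curve$difference, tolerance = 1e-10)
  expect_equal(got$curve$n_events, want$curve$n_events)
  expect_equal(sort(got$events$reason), sort(want$reasons))

  # and with the step filter off
  got2 <- event_study(b, "SABA", n_control = 3, min_control_days = 2,
                      step_filter = FALSE)
  want2 <- oracle_event_study(b, n_control = 3, min_control_days = 2,
                              step_filter = FALSE)
  expect_equal(got2$curve$difference, want2$curve$difference,
               tolerance = 1e-10)
})

test_that("event accounting partitions the actuations exactly", {
  cfg <- cohort_config(n_patients = 4, days_per_patient = 12,
                       saba_day_prob = c(0.5, 0.2),
                       exercise_coupling_prob = 0.6)
  b <- simulate_cohort(cfg, 23)
  fit <- event_study(b, "SABA", n_control = 5, min_control_days = 2)
  a <- setNames(fit$accounting$n_events, fit$accounting$category)
  expect_equal(a[["total"]], sum(b$events$inhaler_type == "SABA"))
  expect_equal(a[["total"]],
               a[["included"]] + a[["excluded_by_steps"]] +
                 a[["excluded_no_controls"]] + a[["excluded_no_wear"]])
  expect_equal(nrow(fit$events), a[["total"]])
})

test_that("degenerate inputs fail with informative conditions", {
  b <- constant_bundle("p1", days = 3)
  expect_error(event_study(b, "SABA"), class = "beta2hr_no_events")
  # daily SABA user: every event lacks control days
  ev <- event_log("p1", ts(paste("2016-03-0", 1:3, " 10:00:00", sep = "")),
                  "SABA")
  b2 <- constant_bundle("p1", days = 3, events = ev)
  expect_error(event_study(b2, "SABA"), "no_controls")
})

test_that("LABA alignment returns the raw event-aligned curve", {
  ev <- event_log("p1", ts("2016-03-02 08:00:00"), "ICS_LABA")
  b <- constant_bundle("p1", days = 3, hr = 72, events = ev)
  fit <- event_study(b, "LABA")
  expect_true(all(fit$curve$event_mean == 72))
  expect_true(all(is.na(fit$curve$difference)))
  expect_null(fit$crossings)
  expect_null(coef(fit))
})
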