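# Generator checks against closed-form expectations.

quiet_config <- function(...) {
  # no noise, no activity, no events, full wear unless overridden
  args <- list(n_patients = 1, days_per_patient = 3, amplitude = 0,
               hr_noise_sd = 0, bout_rate = 0, saba_day_prob = c(0, 0),
               laba_adherence = 0, exercise_coupling_prob = 0,
               saba_kernel = NULL, day_retention = 1, night_retention = 1,
               gap_prob = 0, laba_offset = 0.8)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

test_that("flat quiet patient reproduces the mesor exactly", {
  cfg <- quiet_config()
  p <- simulate_patient(cfg, "p1", 1, laba_user = FALSE)
  expect_equal(nrow(p$hr), 3 * 1440)
  expect_true(all(p$hr$value == 70))
  expect_equal(nrow(p$events), 0L)
  p2 <- simulate_patient(cfg, "p1", 1, laba_user = TRUE)
  expect_true(all(p2$hr$value == 70.8))   # constant LABA offset
})

test_that("equal seeds give bit-identical bundles", {
  cfg <- cohort_config(n_patients = 3, days_per_patient = 5)
  b1 <- simulate_cohort(cfg, 99)
  b2 <- simulate_cohort(cfg, 99)
  expect_identical(b1$hr, b2$hr)
  expect_identical(b1$steps, b2$steps)
  expect_identical(b1$events, b2$events)
  expect_identical(b1$medstatus, b2$medstatus)
  b3 <- simulate_cohort(cfg, 100)
  expect_false(identical(b1$hr, b3$hr))
})

test_that("cohort size contracts hold", {
  cfg <- cohort_config(n_patients = 0, days_per_patient = 5)
  b0 <- simulate_cohort(cfg, 1)
  expect_equal(length(b0$patients), 0L)
  expect_equal(nrow(b0$hr), 0L)
  cfg <- cohort_config(n_patients = 4, days_per_patient = 6)
  b <- simulate_cohort(cfg, 1)
  expect_equal(length(b$patients), 4L)
  wear <- table(b$hr$patient_id)
  expect_true(all(wear <= 6 * 1440))
  expect_equal(sum(b$medstatus$laba), 2L)  # floor(0.7 * 4)
})

test_that("injected kernels add exactly onto the deterministic baseline", {
  k <- saba_profile_kernel()
  cfg <- quiet_config(days_per_patient = 4,
                      saba_kernel = k, saba_day_prob = c(1, 0))
  p <- simulate_patient(cfg, "p1", 5, laba_user = FALSE)
  saba <- p$events[p$events$inhaler_type == "SABA", ]
  expect_equal(nrow(saba), 4L)
  rel_all <- seq(floor(k$t_min), ceiling(k$t_max))
  expected <- rep(70, 4 * 1440)
  for (e in as.numeric(saba$time)) {
    e_idx <- (e - as.numeric(p$hr$time[1])) / 60
    pos <- e_idx + rel_all
    keep <- pos >= 0 & pos < length(expected)
    expected[pos[keep] + 1] <- expected[pos[keep] + 1] +
      kernel_values(k, rel_all[keep])
  }
  expected <- round(pmin(expected, 220), 1)
  expect_equal(p$hr$value, expected)
})

test_that("per-minute mean converges to the circadian curve without effects", {
  cfg <- quiet_config(days_per_patient = 40, amplitude = 5, hr_noise_sd = 3,
                      laba_offset = 0)
  p <- simulate_patient(cfg, "p1", 7, laba_user = FALSE)
  mod <- as.numeric(p$hr$time) %/% 60 %% 1440
  daily_mean <- tapply(p$hr$value, mod, mean)
  minute <- as.numeric(names(daily_mean))
  circ <- 70 + 5 * cos(2 * pi * (minute - 900) / 1440)
  # noise tolerance ~ 4 * sd / sqrt(n days), plus 0.05 quantisation
  expect_lt(max(abs(daily_mean - circ)), 4 * 3 / sqrt(40) + 0.05)
})

test_that("exercise bouts accompany the configured share of SABA events", {
  cfg <- cohort_config(n_patients = 6, days_per_patient = 40,
                       hr_noise_sd = 0, saba_kernel = NULL,
                       bout_rate = 0, exercise_coupling_prob = 0.5,
                       day_retention = 1, night_retention = 1, gap_prob = 0)
  b <- simulate_cohort(cfg, 3)
  saba <- b$events[b$events$inhaler_type == "SABA", ]
  overlapped <- vapply(seq_len(nrow(saba)), function(i) {
    st <- b$steps[b$steps$patient_id == saba$patient_id[i], ]
    win <- as.numeric(saba$time[i]) + 60 * (-30:90)
    sum(st$value[as.numeric(st$time) %in% win]) > 0
  }, logical(1))
  phat <- mean(overlapped)
  se <- sqrt(0.5 * 0.5 / length(overlapped))
  expect_lt(abs(phat - 0.5), 4 * se)
})

test_that("night share of worn minutes matches the wear model target", {
  cfg <- cohort_config(n_patients = 4, days_per_patient = 40,
                       day_retention = 1,
                       night_retention = night_retention_for_fraction(0.187, 1))
  b <- simulate_cohort(cfg, 21)
  mod <- as.numeric(b$hr$time) %/% 60 %% 1440
  share <- mean(mod < 360)
  expect_lt(abs(share - 0.187), 0.01)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(cohort_config(laba_frac = 1.2),
               class = "beta2hr_parameter_error")
  expect_error(cohort_config(saba_day_prob = c(0.9, 0.2)),
               class = "beta2hr_parameter_error")
  expect_error(cohort_config(laba_offset = rep(1, 5)),
               class = "beta2hr_parameter_error")
  expect_error(cohort_config(n_patients = -1),
               class = "beta2hr_parameter_error")
})
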