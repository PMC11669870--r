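test_that("minute CSV reading floors timestamps and validates rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,value",
               "p1,2016-05-01T10:15:42,72",
               "p1,2016-05-01T10:16:00,74.5",
               "p1,2016-05-01T10:18:00,71"), path)
  ms <- read_minute_csv(path, "heart_rate_bpm")
  expect_s3_class(ms, "minute_table")
  expect_equal(nrow(ms), 3L)
  expect_equal(ms$time[1], as.POSIXct("2016-05-01 10:15:00", tz = "UTC"))
  expect_true(all(as.numeric(ms$time) %% 60 == 0))
  expect_equal(ms$value, c(72, 74.5, 71))
})

test_that("duplicate patient+minute rows and bad values are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,value",
               "p1,2016-05-01T10:15:10,72",
               "p1,2016-05-01T10:15:50,80"), path)  # same minute after floor
  expect_error(read_minute_csv(path), class = "beta2hr_integrity_error")
  writeLines(c("patient_id,timestamp,value",
               "p1,2016-05-01Tnoon,72"), path)
  expect_error(read_minute_csv(path), class = "beta2hr_parse_error")
  writeLines(c("patient_id,timestamp,value",
               "p1,2016-05-01T10:15:00,-3"), path)
  expect_error(read_minute_csv(path), class = "beta2hr_domain_error")
  writeLines(c("patient_id,when,value", "p1,2016-05-01T10:15:00,70"), path)
  expect_error(read_minute_csv(path), class = "beta2hr_parse_error")
})

test_that("event CSV is sorted, deduplicated and type-checked", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,inhaler_type",
               "p1,2016-05-01T08:00:00,SABA",
               "p1,2016-05-01T07:55:00,ICS_LABA",
               "p1,2016-05-01T08:00:00,SABA"), path)
  ev <- read_event_csv(path)
  expect_equal(nrow(ev), 2L)   # duplicate actuation collapsed
  expect_equal(ev$inhaler_type, c("ICS_LABA", "SABA"))
  expect_true(!is.unsorted(ev$time))
  writeLines(c("patient_id,timestamp,inhaler_type",
               "p1,2016-05-01T08:00:00,RELIEVER"), path)
  expect_error(read_event_csv(path), class = "beta2hr_domain_error")
  expect_error(read_event_csv(path), "SABA, LABA, ICS, ICS_LABA")
})

test_that("medication-status timelines preserve switches and reject overlap", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,start_date,end_date,laba",
               "p1,2016-01-01,2016-03-31,1",
               "p1,2016-04-01,2016-04-30,0",
               "p1,2016-05-01,2016-05-15,1",
               "p1,2016-05-16,2016-06-30,0"), path)
  ms <- read_medstatus_csv(path)
  expect_equal(nrow(ms), 4L)   # three switches -> four intervals, in order
  expect_equal(ms$laba, c(TRUE, FALSE, TRUE, FALSE))
  writeLines(c("patient_id,start_date,end_date,laba",
               "p1,2016-01-01,2016-03-31,1",
               "p1,2016-03-31,2016-04-30,0"), path)
  expect_error(read_medstatus_csv(path), class = "beta2hr_integrity_error")
})

test_that("bundle round-trips through CSV exactly, preserving gaps", {
  tm <- c(minute_grid("2016-02-01 09:00:00", 30),
          minute_grid("2016-02-01 12:00:00", 30))  # 3 h gap, no zero fill
  hr <- hr_series("p1", tm, round(runif(60, 60, 90), 1))
  hr2 <- hr_series("p2", minute_grid("2016-02-02 10:00:00", 20),
                   rep(65.5, 20))
  hr_all <- structure(rbind(as.data.frame(hr), as.data.frame(hr2)),
                      kind = "heart_rate_bpm",
                      class = c("minute_table", "data.frame"))
  st <- step_series("p1", minute_grid("2016-02-01 09:10:00", 5), c(0, 3, 80, 40, 7))
  ev <- event_log(c("p1", "p2"), ts(c("2016-02-01 09:05:00",
                                      "2016-02-02 10:10:00")),
                  c("SABA", "ICS_LABA"))
  ms <- med_status(c("p1", "p2"), as.Date(c("2016-02-01", "2016-02-02")),
                   as.Date(c("2016-02-05", "2016-02-06")), c(1, 0))
  b <- cohort_bundle(hr_all, st, ev, ms)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(nrow(b2$hr), 80L)         # gaps preserved: no invented rows
  expect_equal(b2$hr$value, b$hr$value)
  expect_equal(as.numeric(b2$hr$time), as.numeric(b$hr$time))
  expect_equal(b2$steps$value, b$steps$value)
  expect_equal(b2$events, b$events)
  expect_equal(b2$medstatus, b$medstatus)
  # ingestion is idempotent
  b3 <- read_bundle(dir)
  expect_identical(b3$hr, b2$hr)
})

test_that("an empty bundle writes header-only CSVs that read back empty", {
  b <- cohort_bundle(empty_hr(), empty_steps(), empty_events(),
                     empty_medstatus())
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_equal(readLines(file.path(dir, "hr.csv")),
               "patient_id,timestamp,value")
  b2 <- read_bundle(dir)
  expect_equal(nrow(b2$hr), 0L)
  expect_equal(nrow(b2$events), 0L)
})
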