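test_that("minute CSV reading normalizes wear codes and reports unknowns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,timestamp,mims,wear_class,quality_flag",
    "A,2013-01-07 00:00,3.2,wake,FALSE",
    "A,2013-01-07 00:01,0.4,sleep,FALSE",
    "A,2013-01-07 00:02,0.0,nonwear,FALSE",
    "A,2013-01-07 00:03,1.0,9,FALSE"
  ), path)
  mt <- read_minute_records(path)
  expect_equal(as.character(mt$wear_class),
               c("wake_wear", "sleep_wear", "non_wear", "unknown"))
  expect_equal(attr(mt, "load_report")$n_unknown_wear, 1L)
  expect_equal(attr(mt, "load_report")$n_rows, 4L)
})

test_that("empty minute file yields an empty table with a zero-row report", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,timestamp,mims,wear_class,quality_flag", path)
  mt <- read_minute_records(path)
  expect_equal(nrow(mt), 0L)
  expect_equal(attr(mt, "load_report")$n_rows, 0L)
})

test_that("missing columns and non-monotone timestamps are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,timestamp,mims", "A,2013-01-07 00:00,1"), path)
  expect_error(read_minute_records(path), "wear_class")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,timestamp,mims,wear_class,quality_flag",
    "A,2013-01-07 00:01,1,wake,FALSE",
    "A,2013-01-07 00:01,1,wake,FALSE"
  ), path2)
  expect_error(read_minute_records(path2), class = "actiscan_data_error")
})

test_that("valid minutes are exactly wake/sleep wear without quality flags", {
  m <- make_days(wear = c("wake_wear", "sleep_wear", "non_wear", "unknown"))
  m$quality_flag[5] <- TRUE # a wake minute carrying the upstream flag
  f <- flag_valid_minutes(m)
  expect_true(all(f$is_valid[f$wear_class %in% c("wake_wear", "sleep_wear") &
                               !f$quality_flag]))
  expect_false(any(f$is_valid[f$wear_class %in% c("non_wear", "unknown")]))
  expect_false(f$is_valid[5])
})

test_that("day validity uses the 20-hour boundary and ignores row order", {
  m <- make_days(wear = "wake_wear") # 1440 valid minutes
  dv <- summarize_day_validity(flag_valid_minutes(m))
  expect_equal(dv$valid_minutes, 1440L)
  expect_true(dv$is_valid_day)

  at_boundary <- set_wear(m, as.Date("2013-01-07"), 0, 239, "non_wear")
  dv2 <- summarize_day_validity(flag_valid_minutes(at_boundary)) # 1200 valid
  expect_equal(dv2$valid_minutes, 1200L)
  expect_true(dv2$is_valid_day)

  below <- set_wear(m, as.Date("2013-01-07"), 0, 240, "non_wear") # 1199
  dv3 <- summarize_day_validity(flag_valid_minutes(below))
  expect_false(dv3$is_valid_day)

  shuffled <- below[sample(nrow(below)), ]
  expect_equal(summarize_day_validity(flag_valid_minutes(shuffled)), dv3)
})

test_that("exclusion cascade applies reasons in order and partitions input", {
  p <- make_participants(6)
  p$age <- c(20, 45, 45, 45, 45, 45) # P1 out on age
  p$pregnant <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE) # P1 multi, P2 out
  p$diabetes[5] <- NA # P5 unknown status
  dv <- tibble::tibble(
    participant_id = rep(p$participant_id, each = 7),
    date = rep(as.Date("2013-01-07") + 0:6, 6),
    valid_minutes = 1440L, is_valid_day = TRUE
  )
  # P3 has only 3 valid days
  dv$is_valid_day[dv$participant_id == "P3"][4:7] <- FALSE
  prof <- make_profiles(p$participant_id)
  prof$rel_h07[4] <- NA # P4 missing a window

  res <- apply_exclusion_cascade(p, dv, prof, analysis = "diabetes")
  expect_equal(
    as.character(res$audit$exclusion_reason),
    c("age_le_20", "pregnant", "lt_4_valid_days", "missing_hourly_window",
      "unknown_diabetes", "none")
  )
  expect_equal(sum(res$audit$included) + sum(!res$audit$included), nrow(p))
  expect_equal(res$cohort$participant_id, "P6")
})

test_that("biomarker analyses add missing-outcome and medication exclusions", {
  p <- make_participants(3)
  p$diabetes_medication <- c(FALSE, FALSE, TRUE)
  p$fasting_glucose <- c(5.2, NA, 5.0)
  dv <- tibble::tibble(
    participant_id = rep(p$participant_id, each = 4),
    date = rep(as.Date("2013-01-07") + 0:3, 3),
    valid_minutes = 1440L, is_valid_day = TRUE
  )
  prof <- make_profiles(p$participant_id)
  res <- apply_exclusion_cascade(p, dv, prof, analysis = "fasting_glucose")
  expect_equal(
    as.character(res$audit$exclusion_reason),
    c("none", "missing_outcome", "on_diabetes_medication")
  )
  expect_error(
    apply_exclusion_cascade(p, dv, prof, analysis = "nonsense"),
    class = "actiscan_usage_error"
  )
})
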