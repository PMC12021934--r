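test_that("clock hourly means pool valid minutes and flag empty windows", {
  m <- flag_valid_minutes(make_days(mims = 10))
  hm <- hourly_means_clock(m)
  expect_equal(nrow(hm), 24L)
  expect_true(all(hm$mean_mims == 10))

  # mims 5 inside 00:01-01:00, 15 elsewhere; note 01:00 belongs to window 1
  m2 <- make_days(mims = 15)
  lt <- as.POSIXlt(m2$t, tz = "UTC")
  mod <- lt$hour * 60 + lt$min
  m2$mims[mod >= 1 & mod <= 60] <- 5
  hm2 <- hourly_means_clock(flag_valid_minutes(m2))
  expect_equal(hm2$mean_mims[hm2$window == 1], 5)
  expect_equal(hm2$mean_mims[hm2$window == 2], 15)

  # all of 03:01-04:00 non-wear on every day -> window 4 missing
  m3 <- set_wear(make_days(), as.Date("2013-01-07"), 181, 240, "non_wear")
  hm3 <- hourly_means_clock(flag_valid_minutes(m3))
  expect_true(is.na(hm3$mean_mims[hm3$window == 4]))
  expect_false(anyNA(hm3$mean_mims[hm3$window != 4]))
})

test_that("relative windows anchor at the overall midpoint", {
  ss <- tibble::tibble(participant_id = "P1", overall_midpoint = 420) # 03:00
  m <- make_days(mims = 2)
  lt <- as.POSIXlt(m$t, tz = "UTC")
  mod <- lt$hour * 60 + lt$min
  m$mims[mod >= 181 & mod <= 240] <- 20 # 03:01-04:00 daily
  hr <- hourly_means_relative(flag_valid_minutes(m), ss)
  expect_equal(hr$mean_mims[hr$window == 1], 20)
  expect_equal(hr$mean_mims[hr$window == 2], 2)

  # constant activity: every relative window equals the constant
  hr2 <- hourly_means_relative(flag_valid_minutes(make_days(mims = 10)), ss)
  expect_true(all(hr2$mean_mims == 10))

  # half-minute midpoint 03:00:30: minute 03:01 -> window 1, 04:01 -> window 2
  ss3 <- tibble::tibble(participant_id = "P1", overall_midpoint = 420.5)
  m3 <- make_days(mims = 0)
  m3$mims[mod == 181] <- 60 # 03:01
  m3$mims[mod == 241] <- 90 # 04:01
  hr3 <- hourly_means_relative(flag_valid_minutes(m3), ss3)
  expect_equal(hr3$mean_mims[hr3$window == 1], 1) # 60 over 60 minutes
  expect_equal(hr3$mean_mims[hr3$window == 2], 1.5)

  # a participant with no midpoint gets all relative windows missing
  ssx <- tibble::tibble(participant_id = "P1", overall_midpoint = NA_real_)
  hrx <- hourly_means_relative(flag_valid_minutes(make_days()), ssx)
  expect_true(all(is.na(hrx$mean_mims)))
})

test_that("relative framing with midnight midpoint reproduces clock framing", {
  set.seed(7)
  m <- flag_valid_minutes(make_days(mims = stats::rlnorm(1440, 1, 0.6)))
  ss <- tibble::tibble(participant_id = "P1", overall_midpoint = 240) # 00:00
  expect_equal(
    hourly_means_relative(m, ss)$mean_mims,
    hourly_means_clock(m)$mean_mims
  )
})

test_that("window means conserve total activity mass on a full valid day", {
  set.seed(8)
  m <- flag_valid_minutes(make_days(mims = stats::rlnorm(1440, 1, 0.6)))
  hm <- hourly_means_clock(m)
  expect_equal(sum(hm$mean_mims * 60), sum(m$mims))
  expect_equal(total_activity(m)$total_mims, sum(m$mims))
})

test_that("total activity averages daily sums over valid days", {
  m <- flag_valid_minutes(make_days(mims = 10, n_days = 2))
  expect_equal(total_activity(m)$total_mims, 14400)

  # two days with sums 12000 and 10000
  m2 <- make_days(mims = c(rep(12000 / 1440, 1440), rep(10000 / 1440, 1440)),
                  n_days = 2)
  expect_equal(total_activity(flag_valid_minutes(m2))$total_mims, 11000)
})

test_that("sleep duration categorises with a closed 7-9 band", {
  m <- set_wear(make_days(), as.Date("2013-01-07"), 0, 479, "sleep_wear")
  sd1 <- sleep_duration(flag_valid_minutes(m)) # 480 min = 8 h
  expect_equal(sd1$sleep_h, 8)
  expect_equal(as.character(sd1$sleep_duration_cat), "7-9")

  m2 <- set_wear(make_days(), as.Date("2013-01-07"), 0, 299, "sleep_wear")
  sd2 <- sleep_duration(flag_valid_minutes(m2))
  expect_equal(sd2$sleep_h, 5)
  expect_equal(as.character(sd2$sleep_duration_cat), "<7")

  m3 <- set_wear(make_days(), as.Date("2013-01-07"), 0, 599, "sleep_wear")
  sd3 <- sleep_duration(flag_valid_minutes(m3))
  expect_equal(sd3$sleep_h, 10)
  expect_equal(as.character(sd3$sleep_duration_cat), ">9")

  expect_equal(as.character(sleep_duration_category(c(6.99, 7, 9, 9.01))),
               c("<7", "7-9", "7-9", ">9"))
})

test_that("quintile assignment matches percentile cuts and shares ties", {
  expect_equal(assign_quintiles(1:10), rep(1:5, each = 2))
  expect_equal(assign_quintiles(1:5), 1:5)
  expect_equal(assign_quintiles(rep(3, 8)), rep(1L, 8))
  expect_error(assign_quintiles(c(1, 2, 3, NA, NA)),
               class = "actiscan_usage_error")

  # monotone in the underlying value; ties share a label
  set.seed(31)
  x <- sample(round(stats::rlnorm(200, 2, 1), 1))
  q <- assign_quintiles(x)
  expect_true(all(diff(q[order(x)]) >= 0))
  expect_true(all(tapply(q, x, function(v) length(unique(v))) == 1))
})

test_that("the feature matrix assembles all windows and summaries", {
  cg <- generate_cohort(sim_config(n_participants = 3, n_days = 4, seed = 2))
  m <- flag_valid_minutes(cg$minutes)
  ft <- hourly_features(m)
  expect_equal(nrow(ft), 3L)
  expect_true(all(sprintf("rel_h%02d", 1:24) %in% names(ft)))
  expect_true(all(sprintf("clock_h%02d", 1:24) %in% names(ft)))
  expect_true(all(c("total_mims", "sleep_h", "sleep_duration_cat",
                    "overall_midpoint", "n_valid_days") %in% names(ft)))
  expect_true(all(ft$n_valid_days == 4L))
  expect_true(all(ft$total_mims > 0))
})
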