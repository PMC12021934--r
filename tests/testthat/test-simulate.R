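test_that("the generator is deterministic in its seed", {
  cfg <- sim_config(n_participants = 4, n_days = 3, seed = 77)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)

  g3 <- generate_cohort(sim_config(n_participants = 4, n_days = 3, seed = 78))
  expect_false(identical(g1$minutes$mims, g3$minutes$mims))

  f1 <- generate_feature_cohort(cfg)
  f2 <- generate_feature_cohort(cfg)
  expect_identical(f1, f2)
})

test_that("derived substream seeds stay in the valid integer range", {
  s <- vapply(c(0:50, 499, 500, 2^20), function(i) .sub_seed(2147483628, i),
              integer(1))
  expect_true(all(s >= 1 & s <= 2147483629))
  expect_type(s, "integer")
  # distinct participants get distinct streams
  expect_equal(anyDuplicated(vapply(0:500, function(i) .sub_seed(1, i),
                                    integer(1))), 0L)
})

test_that("minute cohorts have the ingest layout and plausible structure", {
  cfg <- sim_config(n_participants = 3, n_days = 4, seed = 5)
  g <- generate_cohort(cfg)
  expect_equal(nrow(g$minutes), 3L * 4L * 1440L)
  expect_setequal(names(g$minutes),
                  c("participant_id", "t", "mims", "wear_class",
                    "quality_flag"))
  expect_true(all(levels(g$minutes$wear_class) == WEAR_LEVELS))
  expect_true(all(g$minutes$mims >= 0))
  expect_true(all(g$minutes$mims[g$minutes$wear_class == "non_wear"] == 0))
  # timestamps strictly increase within participant
  by_p <- split(g$minutes$t, g$minutes$participant_id)
  expect_true(all(vapply(by_p, function(t) all(diff(as.numeric(t)) == 60),
                         logical(1))))
  expect_equal(nrow(g$participants), 3L)
  expect_equal(nrow(g$truth), 3L)
  expect_true(all(g$truth$true_midpoint > 300 & g$truth$true_midpoint < 540))
})

test_that("detected sleep timing recovers the generator's truth", {
  cfg <- sim_config(n_participants = 20, n_days = 7, seed = 31)
  g <- generate_cohort(cfg)
  m <- flag_valid_minutes(g$minutes)
  s <- summarize_sleep(sleep_windows(m))
  j <- dplyr::inner_join(s, g$truth, by = "participant_id")
  expect_equal(nrow(j), 20L)
  err <- abs(j$overall_midpoint - j$true_midpoint)
  expect_lt(max(err), 2) # fragmented nights, small tolerance
  # a clean cohort (no fragmentation/non-wear) recovers almost exactly
  cfg0 <- sim_config(n_participants = 10, n_days = 7, seed = 32,
                     fragmentation_prob = 0, nonwear_prob = 0)
  g0 <- generate_cohort(cfg0)
  s0 <- summarize_sleep(sleep_windows(flag_valid_minutes(g0$minutes)))
  j0 <- dplyr::inner_join(s0, g0$truth, by = "participant_id")
  expect_lt(max(abs(j0$overall_midpoint - j0$true_midpoint)), 0.51)
})

test_that("the diurnal profile shows up in midpoint-relative features", {
  cfg <- sim_config(n_participants = 12, n_days = 5, seed = 8)
  g <- generate_cohort(cfg)
  m <- flag_valid_minutes(g$minutes)
  ft <- hourly_features(m)
  rel <- as.matrix(ft[, sprintf("rel_h%02d", 1:24)])
  # plateau windows carry far more activity than the sleep windows
  plateau <- rowMeans(rel[, 8:16])
  night <- rowMeans(rel[, c(1:3, 22:24)])
  expect_true(all(plateau > 3 * night))
  # daily totals in the right order of magnitude
  expect_true(all(ft$total_mims > 4000 & ft$total_mims < 40000))
})

test_that("prevalence calibration hits the configured target", {
  cfg <- sim_config(n_participants = 4000, seed = 12)
  d <- generate_feature_cohort(cfg)$data
  expect_lt(abs(mean(d$diabetes) - 0.187), 0.02)
  # outcomes are consistent with the hba1c/self-report definition
  derived <- derive_diabetes(d$hba1c, d$diabetes_selfreport)
  expect_true(all(derived == d$diabetes_true))
})

test_that("an injected effect shifts diabetes risk across true quintiles", {
  cfg <- sim_config(n_participants = 4000, effect_window = 13,
                    effect_log_or = -0.4, seed = 14)
  f <- generate_feature_cohort(cfg)
  prev <- tapply(f$data$diabetes, f$truth$true_quintile, mean)
  expect_gt(prev[["1"]], prev[["5"]]) # protective effect of high activity
})

test_that("stored insulin is on the cycle's raw scale", {
  cfg <- sim_config(n_participants = 2000, seed = 16)
  d <- generate_feature_cohort(cfg)$data
  d <- d[!is.na(d$fasting_insulin), ]
  h <- harmonize_insulin(d$fasting_insulin, d$survey_cycle)
  # after harmonization the two cycles share a distribution scale
  m1 <- median(log(h[d$survey_cycle == "2011-2012"]))
  m2 <- median(log(h[d$survey_cycle == "2013-2014"]))
  expect_lt(abs(m1 - m2), 0.15)
  # before harmonization the 2013-2014 values sit on a different scale
  raw2 <- median(log(d$fasting_insulin[d$survey_cycle == "2013-2014"]))
  expect_gt(abs(raw2 - m2), 0.02)
})

test_that("the survey design has two strata with unequal weights", {
  d <- generate_feature_cohort(sim_config(n_participants = 1000, seed = 3))$data
  expect_setequal(unique(d$stratum), 1:2)
  expect_true(all(d$psu %in% 1:8))
  w1 <- mean(d$weight_mec[d$stratum == 1])
  w2 <- mean(d$weight_mec[d$stratum == 2])
  expect_gt(w2 / w1, 2)
})
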