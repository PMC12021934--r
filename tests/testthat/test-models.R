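# A small weighted cohort used across model tests
sim_model_data <- function(n = 800, seed = 1, beta = 0, family = "binomial") {
  set.seed(seed)
  d <- tibble::tibble(
    q = sample(1:5, n, TRUE),
    age = stats::runif(n, 21, 80),
    gender = sample(c("men", "women"), n, TRUE),
    w = ifelse(stats::runif(n) < 0.5, 1, 3) * exp(stats::rnorm(n, 0, 0.1)),
    stratum = sample(1:2, n, TRUE)
  )
  d$psu <- sample(1:6, n, TRUE)
  eta <- -1.5 + beta * (d$q - 3) + 0.02 * (d$age - 50)
  if (family == "binomial") {
    d$y <- stats::rbinom(n, 1, stats::plogis(eta))
  } else {
    d$y <- eta + stats::rnorm(n, 0, 0.5)
  }
  d$qf <- factor(d$q)
  d
}

test_that("saturated weighted logistic equals the closed-form weighted OR", {
  toy <- tibble::tibble(
    y = c(1, 0, 1, 0),
    x = factor(c(1, 1, 0, 0), levels = c(0, 1)),
    w = c(30, 10, 10, 30)
  )
  fit <- fit_weighted_logistic(toy, "y", "x", weights = "w")
  expect_equal(fit$or[fit$quintile == "1"], 9.0, tolerance = 1e-6)
  expect_equal(fit$estimate[fit$quintile == "1"],
               oracle_weighted_log_or(30, 10, 10, 30), tolerance = 1e-6)
  # reference level is exactly zero
  expect_identical(fit$estimate[fit$quintile == "0"], 0)
  expect_equal(fit$or[fit$quintile == "0"], 1)
})

test_that("equal weights reproduce the unweighted fit", {
  d <- sim_model_data(400, seed = 5, beta = -0.2)
  d$one <- 1
  f1 <- fit_weighted_logistic(d, "y", "qf", "age", weights = "one")
  f0 <- stats::glm(y ~ qf + age, data = d, family = stats::binomial())
  expect_equal(f1$estimate[-1], unname(stats::coef(f0)[2:5]),
               tolerance = 1e-8)
})

test_that("estimates and robust CIs are invariant to weight rescaling", {
  d <- sim_model_data(600, seed = 9, beta = -0.3)
  d$w10 <- d$w * 10
  f1 <- fit_weighted_logistic(d, "y", "qf", "age", weights = "w")
  f2 <- fit_weighted_logistic(d, "y", "qf", "age", weights = "w10")
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-10)
  expect_equal(f1$ci_low, f2$ci_low, tolerance = 1e-8)
  expect_equal(f1$ci_high, f2$ci_high, tolerance = 1e-8)
})

test_that("duplicating rows with halved weights leaves estimates unchanged", {
  d <- sim_model_data(300, seed = 11, beta = 0.2, family = "gaussian")
  dd <- dplyr::bind_rows(d, d)
  dd$w <- dd$w / 2
  f1 <- fit_weighted_linear(d, "y", "qf", "age", weights = "w")
  f2 <- fit_weighted_linear(dd, "y", "qf", "age", weights = "w")
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-10)
})

test_that("zero-noise linear outcome recovers the slope exactly", {
  d <- tibble::tibble(q = rep(1:5, 20), w = 1)
  d$y <- 0.1 * d$q
  tr <- trend_test(d, "y", "q", weights = "w", family = "gaussian")
  expect_equal(tr$estimate, 0.1, tolerance = 1e-8)
  f <- fit_weighted_linear(d, "y", "q", weights = "w")
  expect_equal(f$estimate, 0.1 * (0:4), tolerance = 1e-8)
})

test_that("trend p-value is invariant to affine recoding of the index", {
  d <- sim_model_data(500, seed = 3, beta = -0.25)
  t1 <- trend_test(d, "y", "q", "age", weights = "w", family = "binomial")
  d$q0 <- d$q - 1
  t2 <- trend_test(d, "y", "q0", "age", weights = "w", family = "binomial")
  expect_equal(t1$p_trend, t2$p_trend, tolerance = 1e-10)
  expect_equal(t1$estimate, t2$estimate, tolerance = 1e-10)
})

test_that("degenerate and separated exposures are flagged, not fatal", {
  d <- sim_model_data(100, seed = 2)
  d$const <- 1
  expect_warning(
    f <- fit_weighted_logistic(d, "y", "const", weights = "w"),
    "degenerate"
  )
  expect_false(any(f$estimable))

  # complete separation
  ds <- tibble::tibble(
    y = c(rep(0, 30), rep(1, 30)),
    x = factor(c(rep("a", 30), rep("b", 30))),
    w = 1
  )
  fs <- fit_weighted_logistic(ds, "y", "x", weights = "w")
  expect_false(any(fs$estimable))
  expect_equal(nrow(fs), 2L)
})

test_that("Taylor linearization runs and differs sensibly from the sandwich", {
  d <- sim_model_data(800, seed = 21, beta = -0.2)
  fr <- fit_weighted_logistic(d, "y", "qf", "age", weights = "w")
  ft <- fit_weighted_logistic(d, "y", "qf", "age", weights = "w",
                              strata = "stratum", psu = "psu",
                              variance = "taylor")
  expect_equal(fr$estimate, ft$estimate, tolerance = 1e-10) # same point fits
  expect_true(all(ft$se[-1] > 0))
  # with as many PSUs as observations the two variance estimators coincide
  d$psu_id <- seq_len(nrow(d))
  d$str1 <- 1
  ft2 <- fit_weighted_logistic(d, "y", "qf", "age", weights = "w",
                               strata = "str1", psu = "psu_id",
                               variance = "taylor")
  expect_equal(fr$se, ft2$se, tolerance = 1e-8)
})

test_that("the window scan produces a complete labelled grid", {
  cfg <- sim_config(n_participants = 400, effect_window = 13,
                    effect_log_or = -0.4, seed = 17)
  d <- generate_feature_cohort(cfg)$data
  scan <- run_window_scan(d, "diabetes", covariates = c("age", "gender"),
                          weights = "weight_mec")
  tx <- tidy(scan)
  expect_equal(sort(unique(tx$window)), 1:24)
  expect_true(all(tx$estimate[tx$quintile == "1"] == 0))
  expect_true(all(tx$ci_low <= tx$estimate & tx$estimate <= tx$ci_high,
                  na.rm = TRUE))
  g <- glance(scan)
  expect_equal(g$n_windows, 24L)
  expect_s3_class(autoplot(scan), "ggplot")

  # clock framing with these columns aliased reproduces the relative grid
  d2 <- d
  for (k in 1:24) d2[[sprintf("clock_h%02d", k)]] <- d[[sprintf("rel_h%02d", k)]]
  scan2 <- run_window_scan(d2, "diabetes", framing = "clock",
                           covariates = c("age", "gender"),
                           weights = "weight_mec")
  expect_equal(tidy(scan2)$estimate, tx$estimate, tolerance = 1e-10)
})

test_that("subgroup trends and the extreme-sleep sensitivity rerun work", {
  cfg <- sim_config(n_participants = 600, effect_window = 13,
                    effect_log_or = -0.4, seed = 23)
  d <- generate_feature_cohort(cfg)$data
  res <- run_subgroups_and_sensitivity(
    d, "diabetes", covariates = c("age", "gender"), weights = "weight_mec",
    subgroups = c("gender", "chronotype")
  )
  sub <- res$subgroups
  expect_setequal(unique(sub$stratifier), c("gender", "chronotype"))
  expect_equal(sum(sub$stratifier == "gender"), 2 * 24)

  # no extreme sleepers in this cohort -> sensitivity equals the main scan
  d$sleep_h <- pmin(pmax(d$sleep_h, 5.5), 9.5)
  main <- run_window_scan(d, "diabetes", covariates = c("age", "gender"),
                          weights = "weight_mec")
  res2 <- run_subgroups_and_sensitivity(
    d, "diabetes", covariates = c("age", "gender"), weights = "weight_mec",
    subgroups = character(0)
  )
  expect_equal(tidy(res2$sensitivity)$estimate, tidy(main)$estimate,
               tolerance = 1e-12)
})
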