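# Survey-weighted association models: per-window logistic (diabetes) and
# linear (log biomarkers) fits over quintile exposures, Wald trend tests,
# and the 24-window scans with subgroup and sensitivity variants.
#
# Point estimation is weighted maximum likelihood via stats::glm with prior
# weights. Variance is design-based, computed from the estimating-equation
# scores: a weight-robust sandwich by default, or stratified/PSU Taylor
# linearization when design variables are supplied. Both are invariant to
# rescaling all weights by a constant.

# Weighted GLM with design-based variance. `data` must already be
# complete-case for all model variables; `weights`, `strata`, `psu` are
# vectors aligned to rows of `data`.
svy_glm <- function(formula, data, weights, family = c("binomial", "gaussian"),
                    strata = NULL, psu = NULL,
                    variance = c("robust", "taylor")) {
  family <- match.arg(family)
  variance <- match.arg(variance)
  if (any(is.na(weights)) || any(weights <= 0)) {
    stop_data("survey weights must be positive and non-missing")
  }
  # normalize to mean 1 so rescaling all weights is an exact no-op (the
  # IRLS stopping rule would otherwise leave ~1e-8 wobble)
  weights <- weights / mean(weights)
  fam <- if (family == "binomial") stats::quasibinomial() else stats::gaussian()
  data$.w <- weights
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, weights = .w, family = fam),
    warning = function(w) invokeRestart("muffleWarning")
  )
  beta <- stats::coef(fit)
  keep <- !is.na(beta)
  X <- stats::model.matrix(fit)[, keep, drop = FALSE]
  y <- fit$y
  mu <- fit$fitted.values
  pw <- fit$prior.weights
  n <- length(y)

  converged <- isTRUE(fit$converged)

  # estimating-function contributions and observed information (canonical
  # links, so both have the same simple form)
  Z <- X * (pw * (y - mu))
  irwt <- if (family == "binomial") pw * mu * (1 - mu) else pw
  A <- crossprod(X, X * irwt)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)

  if (is.null(Ainv) || !converged) {
    V <- matrix(NA_real_, sum(keep), sum(keep))
  } else if (variance == "taylor" && !is.null(psu)) {
    if (is.null(strata)) strata <- rep(1L, n)
    zg <- rowsum(Z, group = paste(strata, psu, sep = "\r"))
    sg <- sub("\r.*$", "", rownames(zg))
    M <- matrix(0, ncol(Z), ncol(Z))
    for (h in unique(sg)) {
      zh <- zg[sg == h, , drop = FALSE]
      nh <- nrow(zh)
      if (nh < 2) next # single-PSU stratum contributes no variance
      zc <- sweep(zh, 2, colMeans(zh))
      M <- M + crossprod(zc) * nh / (nh - 1)
    }
    V <- Ainv %*% M %*% Ainv
  } else {
    zc <- sweep(Z, 2, colMeans(Z))
    M <- crossprod(zc) * n / (n - 1)
    V <- Ainv %*% M %*% Ainv
  }
  dimnames(V) <- list(names(beta[keep]), names(beta[keep]))
  list(
    coef = beta[keep], vcov = V, n = n, converged = converged,
    family = family, fit = fit
  )
}

# model rows complete for all variables in `vars`; returns logical index
complete_rows <- function(data, vars) {
  stats::complete.cases(data[intersect(vars, names(data))])
}

# drop covariates observed at fewer than two distinct values in the
# complete-case data (stats::glm drops unused factor levels and then fails
# on single-level factors; a constant covariate carries no information
# either way)
prune_covariates <- function(data, covariates) {
  if (is.null(covariates)) return(NULL)
  keep <- vapply(covariates, function(v) {
    v %in% names(data) &&
      length(unique(stats::na.omit(as.character(data[[v]])))) > 1
  }, logical(1))
  out <- covariates[keep]
  if (length(out) == 0) NULL else out
}

build_formula <- function(outcome, exposure, covariates) {
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  stats::as.formula(paste0("`", outcome, "` ~ ", rhs))
}

wald_ci <- function(est, se, conf_level = 0.95, df = Inf) {
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df) else
    stats::qnorm(1 - (1 - conf_level) / 2)
  cbind(low = est - q * se, high = est + q * se)
}

#' Survey-weighted logistic regression over a categorical exposure
#'
#' Fits a weighted logistic model of a binary outcome on an exposure factor
#' (quintiles in the main analysis) plus covariates, and reports per-level
#' odds ratios against the first (reference) level with design-based 95%
#' confidence intervals. Complete separation or non-convergence yields rows
#' flagged `estimable = FALSE` rather than an error; a single-level exposure
#' is skipped with a warning.
#'
#' @param data Tibble holding all model columns.
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @param exposure Name of the exposure column (coerced to factor).
#' @param covariates Character vector of adjustment column names (or `NULL`).
#' @param weights Name of the survey-weight column.
#' @param strata,psu Optional design-variable column names (enable Taylor
#'   linearization when `variance = "taylor"`).
#' @param variance `"robust"` (weight-robust sandwich, default) or
#'   `"taylor"` (stratified/PSU linearization).
#' @param conf_level Confidence level, default 0.95.
#' @param df Degrees of freedom for interval quantiles; `Inf` (default) uses
#'   normal quantiles.
#' @return Tibble with one row per exposure level: `quintile`, `estimate`
#'   (log-OR, exactly 0 for the reference), `se`, `or`, `or_low`, `or_high`,
#'   `ci_low`, `ci_high` (log scale), `n_used`, `estimable`.
#' @export
fit_weighted_logistic <- function(data, outcome, exposure, covariates = NULL,
                                  weights, strata = NULL, psu = NULL,
                                  variance = c("robust", "taylor"),
                                  conf_level = 0.95, df = Inf) {
  fit_weighted_model(data, outcome, exposure, covariates, weights, strata,
                     psu, match.arg(variance), conf_level, df,
                     family = "binomial")
}

#' Survey-weighted linear regression over a categorical exposure
#'
#' Linear analogue of [fit_weighted_logistic()] for continuous (log-scale)
#' outcomes; estimates are beta coefficients on the outcome scale.
#'
#' @inheritParams fit_weighted_logistic
#' @param outcome Name of the continuous outcome column.
#' @return Tibble as for [fit_weighted_logistic()] without the OR columns.
#' @export
fit_weighted_linear <- function(data, outcome, exposure, covariates = NULL,
                                weights, strata = NULL, psu = NULL,
                                variance = c("robust", "taylor"),
                                conf_level = 0.95, df = Inf) {
  fit_weighted_model(data, outcome, exposure, covariates, weights, strata,
                     psu, match.arg(variance), conf_level, df,
                     family = "gaussian")
}

fit_weighted_model <- function(data, outcome, exposure, covariates, weights,
                               strata, psu, variance, conf_level, df, family) {
  vars <- c(outcome, exposure, covariates, weights, strata, psu)
  idx <- complete_rows(data, vars)
  d <- data[idx, , drop = FALSE]
  covariates <- prune_covariates(d, covariates)
  d[[exposure]] <- droplevels(factor(d[[exposure]]))
  levs <- levels(d[[exposure]])

  empty_row <- function(lev, est = NA_real_) {
    tibble::tibble(
      quintile = lev, estimate = est, se = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, n_used = nrow(d),
      estimable = FALSE
    )
  }
  if (length(levs) < 2) {
    warning("degenerate exposure (single level); window skipped",
            call. = FALSE)
    out <- empty_row(levs[1], est = 0)
    return(finish_assoc(out, family))
  }

  res <- svy_glm(
    build_formula(outcome, exposure, covariates), d,
    weights = d[[weights]], family = family,
    strata = if (!is.null(strata)) d[[strata]],
    psu = if (!is.null(psu)) d[[psu]],
    variance = variance
  )
  terms_needed <- paste0(exposure, levs[-1])
  # separation in the exposure itself (runaway log-OR) is non-estimable;
  # a sparse nuisance-covariate level is not grounds to drop the window
  separated <- all(terms_needed %in% names(res$coef)) &&
    family == "binomial" && max(abs(res$coef[terms_needed])) >= 15
  if (!res$converged || separated ||
      !all(terms_needed %in% names(res$coef))) {
    out <- dplyr::bind_rows(lapply(levs, empty_row))
    out$estimate[1] <- 0
    return(finish_assoc(out, family))
  }
  est <- res$coef[terms_needed]
  se <- sqrt(diag(res$vcov)[terms_needed])
  ci <- wald_ci(est, se, conf_level, df)
  out <- tibble::tibble(
    quintile = levs,
    estimate = c(0, unname(est)),
    se = c(0, unname(se)),
    ci_low = c(0, ci[, "low"]),
    ci_high = c(0, ci[, "high"]),
    n_used = res$n,
    estimable = TRUE
  )
  finish_assoc(out, family)
}

finish_assoc <- function(out, family) {
  if (family == "binomial") {
    out$or <- exp(out$estimate)
    out$or_low <- exp(out$ci_low)
    out$or_high <- exp(out$ci_high)
  }
  out
}

#' Wald trend test over the quintile index
#'
#' Refits the model with the exposure entered as a continuous index (1-5 for
#' Q1-Q5) and reports the Wald p-value for its coefficient with the same
#' design-based variance as the main fits. The p-value is invariant to
#' affine recoding of the index.
#'
#' @inheritParams fit_weighted_logistic
#' @param exposure Name of a numeric quintile-index column (or a column
#'   coercible to numeric).
#' @param family `"binomial"` or `"gaussian"`.
#' @return One-row tibble: `estimate` (per-step log-OR or beta), `se`,
#'   `ci_low`, `ci_high`, `p_trend`, `n_used`, `estimable`.
#' @export
trend_test <- function(data, outcome, exposure, covariates = NULL, weights,
                       strata = NULL, psu = NULL,
                       variance = c("robust", "taylor"),
                       family = c("binomial", "gaussian"),
                       conf_level = 0.95, df = Inf) {
  variance <- match.arg(variance)
  family <- match.arg(family)
  vars <- c(outcome, exposure, covariates, weights, strata, psu)
  idx <- complete_rows(data, vars)
  d <- data[idx, , drop = FALSE]
  covariates <- prune_covariates(d, covariates)
  d[[exposure]] <- as.numeric(d[[exposure]])
  if (length(unique(d[[exposure]])) < 2) {
    return(tibble::tibble(
      estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p_trend = NA_real_, n_used = nrow(d),
      estimable = FALSE
    ))
  }
  res <- svy_glm(
    build_formula(outcome, exposure, covariates), d,
    weights = d[[weights]], family = family,
    strata = if (!is.null(strata)) d[[strata]],
    psu = if (!is.null(psu)) d[[psu]],
    variance = variance
  )
  term <- paste0("`", exposure, "`")
  term <- if (term %in% names(res$coef)) term else exposure
  separated <- term %in% names(res$coef) && family == "binomial" &&
    abs(res$coef[[term]]) >= 15
  if (!res$converged || separated || !term %in% names(res$coef)) {
    return(tibble::tibble(
      estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p_trend = NA_real_, n_used = res$n,
      estimable = FALSE
    ))
  }
  est <- unname(res$coef[term])
  se <- sqrt(res$vcov[term, term])
  ci <- wald_ci(est, se, conf_level, df)
  zdf <- df
  p <- if (is.finite(zdf)) 2 * stats::pt(-abs(est / se), zdf) else
    2 * stats::pnorm(-abs(est / se))
  tibble::tibble(
    estimate = est, se = se, ci_low = ci[, "low"], ci_high = ci[, "high"],
    p_trend = p, n_used = res$n, estimable = TRUE
  )
}

#' Scan all 24 hourly windows for outcome associations
#'
#' For each hourly window of the chosen framing, divides the cohort into
#' quintiles of mean activity in that window (quintile 1, lowest, as
#' reference), fits the survey-weighted model adjusted for the supplied
#' covariates, and computes the trend test over the continuous quintile
#' index. Non-estimable windows are reported as explicit flagged rows, never
#' silently dropped.
#'
#' @param cohort Analysis cohort: one row per participant holding the hourly
#'   feature columns (`rel_h01..24` / `clock_h01..24`), the outcome,
#'   covariates and design variables.
#' @param outcome Name of the outcome column; a logical/binary column
#'   selects logistic fits, numeric selects linear fits (overridable via
#'   `family`).
#' @param framing `"relative"` (sleep-midpoint-anchored, primary) or
#'   `"clock"`.
#' @param family `NULL` (auto) or `"binomial"`/`"gaussian"`.
#' @inheritParams fit_weighted_logistic
#' @return A `window_scan` object: tibble with per-window, per-quintile rows
#'   (`window`, `quintile`, `estimate`, CIs, `p_trend`, `trend_estimate`,
#'   `n_used`, `estimable`) plus metadata attributes. Use [tidy.window_scan()],
#'   [glance.window_scan()], [autoplot.window_scan()].
#' @export
run_window_scan <- function(cohort, outcome, framing = c("relative", "clock"),
                            covariates = NULL, weights, strata = NULL,
                            psu = NULL, variance = c("robust", "taylor"),
                            family = NULL, conf_level = 0.95, df = Inf) {
  framing <- match.arg(framing)
  variance <- match.arg(variance)
  if (is.null(family)) {
    y <- cohort[[outcome]]
    family <- if (is.logical(y) || all(stats::na.omit(y) %in% 0:1)) {
      "binomial"
    } else "gaussian"
  }
  if (family == "binomial" && is.logical(cohort[[outcome]])) {
    cohort[[outcome]] <- as.integer(cohort[[outcome]])
  }
  prefix <- if (framing == "relative") "rel_h" else "clock_h"
  fitter <- if (family == "binomial") fit_weighted_logistic else
    fit_weighted_linear

  rows <- purrr::map(1:24, function(k) {
    col <- sprintf("%s%02d", prefix, k)
    assert_columns(cohort, col, "cohort feature matrix")
    d <- cohort
    d$.quintile <- assign_quintiles(d[[col]])
    fit <- suppressWarnings(fitter(
      d, outcome, ".quintile", covariates, weights, strata, psu,
      variance = variance, conf_level = conf_level, df = df
    ))
    tr <- trend_test(
      d, outcome, ".quintile", covariates, weights, strata, psu,
      variance = variance, family = family, conf_level = conf_level, df = df
    )
    fit$window <- k
    fit$p_trend <- tr$p_trend
    fit$trend_estimate <- tr$estimate
    fit$trend_se <- tr$se
    fit$trend_ci_low <- tr$ci_low
    fit$trend_ci_high <- tr$ci_high
    fit
  })
  grid <- dplyr::bind_rows(rows) |>
    dplyr::mutate(framing = framing, .before = 1) |>
    dplyr::relocate("window", .after = "framing")
  structure(
    grid,
    class = c("window_scan", class(grid)),
    outcome = outcome, family = family, framing = framing,
    covariates = covariates, variance = variance
  )
}

#' Subgroup and sensitivity analyses around the main scan
#'
#' Subgroups re-run the per-window association with the exposure modelled as
#' a continuous quintile index (the power-preserving choice for smaller
#' strata): by gender, age (`<65` / `>=65`), chronotype (weekend sleep
#' midpoint at or before vs after the in-sample median, recomputed, never
#' hard-coded) and sleep duration (`<7` / `>=7` h), for whichever stratifier
#' columns are present. The sensitivity analysis repeats the full main scan
#' excluding extreme sleepers (duration <= 4 or >= 10 h).
#'
#' @inheritParams run_window_scan
#' @param subgroups Character vector naming which stratifications to run;
#'   subset of `c("gender", "age", "chronotype", "sleep_duration")`.
#' @param sensitivity Logical; run the extreme-sleep-duration exclusion.
#' @return A list with `subgroups` (tibble of per-window trend results
#'   labelled by stratum) and `sensitivity` (a `window_scan` or `NULL`).
#' @export
run_subgroups_and_sensitivity <- function(cohort, outcome,
                                          framing = c("relative", "clock"),
                                          covariates = NULL, weights,
                                          strata = NULL, psu = NULL,
                                          variance = c("robust", "taylor"),
                                          family = NULL,
                                          subgroups = c("gender", "age",
                                                        "chronotype",
                                                        "sleep_duration"),
                                          sensitivity = TRUE) {
  framing <- match.arg(framing)
  variance <- match.arg(variance)
  defs <- list()
  if ("gender" %in% subgroups && "gender" %in% names(cohort)) {
    defs$gender <- as.character(cohort$gender)
  }
  if ("age" %in% subgroups && "age" %in% names(cohort)) {
    defs$age <- ifelse(cohort$age < 65, "<65", ">=65")
  }
  if ("chronotype" %in% subgroups && "weekend_midpoint" %in% names(cohort)) {
    med <- stats::median(cohort$weekend_midpoint, na.rm = TRUE)
    defs$chronotype <- ifelse(cohort$weekend_midpoint <= med,
                              "early", "late")
  }
  if ("sleep_duration" %in% subgroups && "sleep_h" %in% names(cohort)) {
    defs$sleep_duration <- ifelse(cohort$sleep_h < 7, "<7h", ">=7h")
  }

  prefix <- if (framing == "relative") "rel_h" else "clock_h"
  if (is.null(family)) {
    y <- cohort[[outcome]]
    family <- if (is.logical(y) || all(stats::na.omit(y) %in% 0:1)) {
      "binomial"
    } else "gaussian"
  }
  if (family == "binomial" && is.logical(cohort[[outcome]])) {
    cohort[[outcome]] <- as.integer(cohort[[outcome]])
  }

  sub_rows <- purrr::imap(defs, function(lab, var) {
    purrr::map(stats::na.omit(unique(lab)), function(lv) {
      d <- cohort[!is.na(lab) & lab == lv, , drop = FALSE]
      res <- purrr::map(1:24, function(k) {
        col <- sprintf("%s%02d", prefix, k)
        d$.quintile <- tryCatch(assign_quintiles(d[[col]]),
                                error = function(e) rep(NA_integer_, nrow(d)))
        out <- if (all(is.na(d$.quintile)) ||
                   length(unique(stats::na.omit(d[[outcome]]))) < 2) {
          tibble::tibble(
            estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
            ci_high = NA_real_, p_trend = NA_real_, n_used = nrow(d),
            estimable = FALSE
          )
        } else {
          trend_test(d, outcome, ".quintile", covariates, weights, strata,
                     psu, variance = variance, family = family)
        }
        out$window <- k
        out
      })
      dplyr::bind_rows(res) |>
        dplyr::mutate(stratifier = var, stratum = lv, .before = 1)
    }) |>
      dplyr::bind_rows()
  })

  sens <- NULL
  if (sensitivity && "sleep_h" %in% names(cohort)) {
    keep <- is.na(cohort$sleep_h) | (cohort$sleep_h > 4 & cohort$sleep_h < 10)
    sens <- run_window_scan(
      cohort[keep, , drop = FALSE], outcome, framing, covariates, weights,
      strata, psu, variance = variance, family = family
    )
    attr(sens, "sensitivity_label") <- "excl_extreme_sleep"
  }
  list(subgroups = dplyr::bind_rows(sub_rows), sensitivity = sens)
}
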