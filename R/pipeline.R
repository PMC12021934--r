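# End-to-end orchestration: ingest or simulate, sleep timing, features,
# cascade, association scans, subgroup/sensitivity outputs, manifest.

analysis_columns <- function(analysis) {
  switch(analysis,
    diabetes = list(outcome = "diabetes", weight = "weight_mec",
                    family = "binomial"),
    fasting_glucose = list(outcome = "log_fasting_glucose",
                           weight = "weight_fasting", family = "gaussian"),
    fasting_insulin = list(outcome = "log_fasting_insulin",
                           weight = "weight_fasting", family = "gaussian"),
    homa_ir = list(outcome = "log_homa_ir", weight = "weight_fasting",
                   family = "gaussian"),
    ogtt = list(outcome = "log_ogtt_2h_glucose", weight = "weight_ogtt",
                family = "gaussian"),
    stop_usage("unknown analysis label")
  )
}

default_covariates <- function(include_bmi = TRUE) {
  c("age", "gender", "race_ethnicity", "education", "income", "marital",
    "smoking", "alcohol", if (include_bmi) "bmi_cat", "energy_kj",
    "sleep_duration_cat", "sleep_midpoint", "total_mims")
}

log_stage <- function(con, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage: input (minute/participant files or a synthetic
#' cohort), validity flagging, sleep-timing detection, hourly features, the
#' exclusion cascade, the 24-window association scan (one or both framings),
#' optional subgroup and sensitivity analyses, and a results directory with
#' audit trail, feature matrix, scan grids, curve data for plotting, a
#' JSON-lines stage log and a run manifest.
#'
#' @param minutes_path,participants_path Paths to CSV inputs (ignored when
#'   `sim` is given).
#' @param sim A [sim_config()] to generate the cohort instead of reading
#'   files. Exactly one input source must be supplied.
#' @param analysis `"diabetes"` (default), `"fasting_glucose"`,
#'   `"fasting_insulin"`, `"homa_ir"` or `"ogtt"`.
#' @param framing `"relative"`, `"clock"` or `"both"`.
#' @param include_bmi Include the BMI category among covariates (default
#'   TRUE).
#' @param variance `"robust"` or `"taylor"`.
#' @param subgroups Run subgroup/sensitivity analyses (default FALSE).
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest and used for any simulation.
#' @return Invisibly, a list with the cohort, audit, features, scans and
#'   manifest.
#' @export
run_pipeline <- function(minutes_path = NULL, participants_path = NULL,
                         sim = NULL,
                         analysis = "diabetes",
                         framing = c("relative", "clock", "both"),
                         include_bmi = TRUE,
                         variance = c("robust", "taylor"),
                         subgroups = FALSE,
                         out_dir, seed = 1L) {
  framing <- match.arg(framing)
  variance <- match.arg(variance)
  have_files <- !is.null(minutes_path) || !is.null(participants_path)
  if (is.null(sim) == !have_files) {
    stop_usage("supply exactly one input source: file paths or a sim config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "log.jsonl"), open = "wt")
  on.exit(close(logf), add = TRUE)

  if (!is.null(sim)) {
    sim$seed <- seed
    gen <- generate_cohort(sim)
    minutes <- gen$minutes
    participants <- gen$participants
  } else {
    minutes <- read_minute_records(minutes_path)
    participants <- read_participants(participants_path)
  }
  log_stage(logf, "input", n_minutes = nrow(minutes),
            n_participants = nrow(participants))

  minutes <- flag_valid_minutes(minutes)
  dayv <- summarize_day_validity(minutes)
  windows <- sleep_windows(minutes)
  sleeps <- summarize_sleep(windows)
  features <- hourly_features(minutes, sleeps)
  log_stage(logf, "features", n_with_features = nrow(features),
            n_nights = nrow(windows))

  panel <- derive_outcome_panel(participants)
  panel <- encode_covariates(panel, features)

  casc <- apply_exclusion_cascade(
    panel, dayv, features, analysis = analysis,
    framing = if (framing == "clock") "clock" else "relative"
  )
  counts <- casc$audit |>
    dplyr::count(.data$exclusion_reason, .drop = FALSE)
  log_stage(logf, "cascade",
            included = sum(casc$audit$included),
            excluded = sum(!casc$audit$included))

  cols <- analysis_columns(analysis)
  covs <- default_covariates(include_bmi)
  cohort <- casc$cohort
  use_design <- variance == "taylor" &&
    all(c("stratum", "psu") %in% names(cohort))

  framings <- if (framing == "both") c("relative", "clock") else framing
  scans <- purrr::map(framings, function(fr) {
    run_window_scan(
      cohort, cols$outcome, framing = fr, covariates = covs,
      weights = cols$weight,
      strata = if (use_design) "stratum", psu = if (use_design) "psu",
      variance = variance, family = cols$family
    )
  })
  names(scans) <- framings
  log_stage(logf, "scan", framings = framings,
            n_used = max(tidy(scans[[1]])$n_used))

  subs <- NULL
  if (subgroups) {
    subs <- run_subgroups_and_sensitivity(
      cohort, cols$outcome, framing = framings[1], covariates = covs,
      weights = cols$weight,
      strata = if (use_design) "stratum", psu = if (use_design) "psu",
      variance = variance, family = cols$family
    )
    log_stage(logf, "subgroups", n_rows = nrow(subs$subgroups))
  }

  # outputs
  write_audit(casc$audit, file.path(out_dir, "cohort_audit.tsv"))
  write_sleep_tables(windows, sleeps,
                     file.path(out_dir, "sleep_nights.tsv"),
                     file.path(out_dir, "sleep_summary.tsv"))
  write_features(features, file.path(out_dir, "features.tsv"))
  curve_paths <- character()
  for (fr in framings) {
    write_scan_tables(
      scans[[fr]],
      file.path(out_dir, sprintf("scan_%s_%s.tsv", analysis, fr)),
      file.path(out_dir, sprintf("scan_%s_%s_long.tsv", analysis, fr))
    )
    cp <- file.path(out_dir, sprintf("curve_%s_%s.tsv", analysis, fr))
    readr::write_tsv(curve_data(scans[[fr]]), cp)
    curve_paths <- c(curve_paths, cp)
  }
  if (!is.null(subs)) {
    readr::write_tsv(subs$subgroups, file.path(out_dir, "subgroups.tsv"))
    if (!is.null(subs$sensitivity)) {
      write_scan_tables(
        subs$sensitivity,
        file.path(out_dir, sprintf("scan_%s_sensitivity.tsv", analysis)),
        file.path(out_dir, sprintf("scan_%s_sensitivity_long.tsv", analysis))
      )
    }
  }

  config <- list(
    analysis = analysis, framing = framing, include_bmi = include_bmi,
    variance = variance, subgroups = subgroups, seed = seed,
    covariates = covs,
    source = if (!is.null(sim)) "simulation" else "files",
    sim = if (!is.null(sim)) unclass(sim)[setdiff(names(sim), "start_date")]
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("actiscan")),
    r_version = R.version.string,
    config = config,
    config_hash = digest::digest(config),
    cascade_counts = stats::setNames(as.list(counts$n),
                                     as.character(counts$exclusion_reason)),
    n_input = nrow(casc$audit),
    n_included = sum(casc$audit$included)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage(logf, "done", out_dir = out_dir)

  invisible(list(
    cohort = cohort, audit = casc$audit, features = features,
    sleep = sleeps, scans = scans, subgroups = subs, manifest = manifest
  ))
}

#' Extract top-vs-bottom quintile curve data from a scan
#'
#' @param scan A `window_scan`.
#' @return Tibble with one row per window: Q5-vs-Q1 estimate and CI (log-OR
#'   or beta scale), trend p-value and estimability flag.
#' @export
curve_data <- function(scan) {
  tx <- tidy(scan)
  tx |>
    dplyr::filter(.data$quintile == max(.data$quintile)) |>
    dplyr::transmute(
      framing = .data$framing, window = .data$window,
      estimate = dplyr::if_else(.data$estimable, .data$estimate, NA_real_),
      ci_low = dplyr::if_else(.data$estimable, .data$ci_low, NA_real_),
      ci_high = dplyr::if_else(.data$estimable, .data$ci_high, NA_real_),
      p_trend = .data$p_trend,
      estimable = .data$estimable
    )
}

#' Plot association curves from curve data
#'
#' Renders the 24-point top-vs-bottom-quintile curve with a CI ribbon from a
#' curve-data table (as written by [run_pipeline()] or built by
#' [curve_data()]). Odds ratios are drawn on a log-scaled axis when
#' `or_scale = TRUE`; non-estimable windows appear as gaps.
#'
#' @param curves A curve-data tibble or path to a curve TSV.
#' @param or_scale Exponentiate estimates and use a log axis (logistic
#'   scans).
#' @param path Optional output file; the figure is saved there via
#'   [ggplot2::ggsave()].
#' @return The ggplot object (invisibly when `path` is given). Empty input
#'   is a no-op with a warning.
#' @export
plot_curves <- function(curves, or_scale = TRUE, path = NULL) {
  if (is.character(curves)) {
    curves <- readr::read_tsv(curves, show_col_types = FALSE)
  }
  if (nrow(curves) == 0) {
    warning("empty curve data; nothing to plot", call. = FALSE)
    return(invisible(NULL))
  }
  tr <- if (or_scale) exp else identity
  ref <- if (or_scale) 1 else 0
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$window,
                                            y = tr(.data$estimate))) +
    ggplot2::geom_hline(yintercept = ref, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = tr(.data$ci_low), ymax = tr(.data$ci_high)),
      alpha = 0.25, fill = "steelblue"
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.4, colour = "steelblue") +
    ggplot2::scale_x_continuous(breaks = seq(2, 24, 2)) +
    ggplot2::labs(x = "Hourly window (by ending hour)",
                  y = if (or_scale) "OR (Q5 vs Q1)" else "β (Q5 vs Q1)") +
    ggplot2::theme_minimal()
  if (or_scale) p <- p + ggplot2::scale_y_log10()
  if (!is.null(curves$framing)) {
    p <- p + ggplot2::facet_wrap(~framing)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 4)
    return(invisible(p))
  }
  p
}
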