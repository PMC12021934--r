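# Validity rules and the cohort exclusion cascade.

#' Flag valid minutes
#'
#' A minute is valid when the upstream classifier labelled it wake wear or
#' sleep wear; non-wear and unknown minutes are invalid, as are minutes
#' carrying the upstream "unlikely human movement" quality flag.
#'
#' @param minutes Minute-level tibble (see [read_minute_records()]).
#' @return The input with a logical `is_valid` column added.
#' @export
flag_valid_minutes <- function(minutes) {
  assert_columns(minutes, c("participant_id", "t", "wear_class"), "minute table")
  qf <- if ("quality_flag" %in% names(minutes)) {
    !is.na(minutes$quality_flag) & minutes$quality_flag
  } else {
    rep(FALSE, nrow(minutes))
  }
  dplyr::mutate(
    minutes,
    is_valid = .data$wear_class %in% c("wake_wear", "sleep_wear") & !qf
  )
}

#' Summarize day-level validity
#'
#' One row per participant per calendar day (midnight to midnight, local
#' clock). A day is valid when it holds at least 20 h (1200 min) of valid
#' data.
#'
#' @param minutes Minute table flagged by [flag_valid_minutes()].
#' @return Tibble with `participant_id`, `date`, `valid_minutes`,
#'   `is_valid_day`.
#' @export
summarize_day_validity <- function(minutes) {
  assert_columns(minutes, c("participant_id", "t", "is_valid"), "minute table")
  minutes |>
    dplyr::mutate(date = lubridate::as_date(.data$t)) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(valid_minutes = sum(.data$is_valid), .groups = "drop") |>
    dplyr::mutate(is_valid_day = .data$valid_minutes >= 1200L)
}

#' Apply the study exclusion cascade
#'
#' Applies, in order: age at or below 20 years; pregnancy; fewer than 4 valid
#' actigraphy days; a missing mean-activity value for any hourly window;
#' unknown diabetes status; and, for the biomarker analyses only, a missing
#' outcome and current diabetes-medication use. A participant meeting several
#' criteria is charged to the first in this order, so the audit partitions
#' the input cohort.
#'
#' @param participants Participant tibble with `participant_id`, `age`,
#'   `pregnant` (logical), `diabetes` (logical or NA = unknown), and for
#'   biomarker analyses `diabetes_medication` plus the analysis outcome
#'   column (`fasting_glucose`, `fasting_insulin`, `homa_ir`, or
#'   `ogtt_2h_glucose`; `ogtt_eligible` is honoured when present).
#' @param day_validity Output of [summarize_day_validity()].
#' @param hourly_profiles Feature matrix from [hourly_features()]; windows of
#'   the chosen framing must be non-missing for inclusion.
#' @param analysis One of `"diabetes"`, `"fasting_glucose"`,
#'   `"fasting_insulin"`, `"homa_ir"`, `"ogtt"`.
#' @param framing Which framing's hourly windows must be complete
#'   (`"relative"`, the primary framing, by default).
#' @return A list with `cohort` (included participants joined to their
#'   profiles) and `audit` (one row per input participant: `included`,
#'   `exclusion_reason`, `n_valid_days`).
#' @export
apply_exclusion_cascade <- function(participants, day_validity, hourly_profiles,
                                    analysis = c("diabetes", "fasting_glucose",
                                                 "fasting_insulin", "homa_ir",
                                                 "ogtt"),
                                    framing = c("relative", "clock")) {
  analysis <- tryCatch(match.arg(analysis),
                       error = function(e) stop_usage("unknown analysis label"))
  framing <- match.arg(framing)
  assert_columns(participants, c("participant_id", "age"), "participant table")

  n_days <- day_validity |>
    dplyr::filter(.data$is_valid_day) |>
    dplyr::count(.data$participant_id, name = "n_valid_days")

  prefix <- if (framing == "relative") "rel_h" else "clock_h"
  wcols <- sprintf("%s%02d", prefix, 1:24)
  complete_windows <- if (nrow(hourly_profiles) > 0) {
    assert_columns(hourly_profiles, wcols, "hourly profile table")
    tibble::tibble(
      participant_id = hourly_profiles$participant_id,
      windows_complete = !apply(is.na(hourly_profiles[wcols]), 1, any)
    )
  } else {
    tibble::tibble(participant_id = character(), windows_complete = logical())
  }

  aud <- participants |>
    dplyr::left_join(n_days, by = "participant_id") |>
    dplyr::left_join(complete_windows, by = "participant_id") |>
    dplyr::mutate(
      n_valid_days = dplyr::coalesce(.data$n_valid_days, 0L),
      windows_complete = dplyr::coalesce(.data$windows_complete, FALSE)
    )

  pregnant <- if ("pregnant" %in% names(aud)) {
    !is.na(aud$pregnant) & aud$pregnant
  } else rep(FALSE, nrow(aud))
  diabetes_unknown <- if ("diabetes" %in% names(aud)) {
    is.na(aud$diabetes)
  } else rep(TRUE, nrow(aud))

  outcome_col <- switch(analysis,
    diabetes = NULL, fasting_glucose = "fasting_glucose",
    fasting_insulin = "fasting_insulin", homa_ir = "homa_ir",
    ogtt = "ogtt_2h_glucose"
  )
  missing_outcome <- rep(FALSE, nrow(aud))
  on_medication <- rep(FALSE, nrow(aud))
  if (!is.null(outcome_col)) {
    missing_outcome <- if (outcome_col %in% names(aud)) is.na(aud[[outcome_col]]) else
      rep(TRUE, nrow(aud))
    if (analysis == "ogtt" && "ogtt_eligible" %in% names(aud)) {
      missing_outcome <- missing_outcome | !(dplyr::coalesce(aud$ogtt_eligible, FALSE))
    }
    on_medication <- if ("diabetes_medication" %in% names(aud)) {
      !is.na(aud$diabetes_medication) & aud$diabetes_medication
    } else rep(FALSE, nrow(aud))
  }

  reason <- dplyr::case_when(
    !is.na(aud$age) & aud$age <= 20 ~ "age_le_20",
    pregnant ~ "pregnant",
    aud$n_valid_days < 4L ~ "lt_4_valid_days",
    !aud$windows_complete ~ "missing_hourly_window",
    diabetes_unknown ~ "unknown_diabetes",
    missing_outcome ~ "missing_outcome",
    on_medication ~ "on_diabetes_medication",
    TRUE ~ "none"
  )

  audit <- tibble::tibble(
    participant_id = aud$participant_id,
    included = reason == "none",
    exclusion_reason = factor(reason, levels = EXCLUSION_REASONS),
    n_valid_days = aud$n_valid_days
  )

  # keep the participants' version of any column present in both tables
  # (e.g. sleep features already merged upstream)
  prof_cols <- c("participant_id",
                 setdiff(names(hourly_profiles), names(participants)))
  cohort <- participants |>
    dplyr::semi_join(dplyr::filter(audit, .data$included), by = "participant_id") |>
    dplyr::left_join(hourly_profiles[prof_cols], by = "participant_id")

  list(cohort = cohort, audit = audit)
}

#' Write a cohort audit as TSV
#'
#' @param audit Audit tibble from [apply_exclusion_cascade()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  readr::write_tsv(audit, path)
  invisible(path)
}
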