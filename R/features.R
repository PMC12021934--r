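# Hourly activity features: clock-anchored and sleep-midpoint-relative hourly
# mean MIMS, total daily activity, sleep duration, quintile exposure coding.
#
# All hourly windows are half-open and labelled by their ending hour: clock
# window 1 is 00:01-01:00, relative window 1 is (midpoint, midpoint + 60 min].
# Means pool valid minutes across valid days (minute-weighted); a window is
# missing iff zero valid minutes ever fall in it.

# clock window label (1..24) for a clock time in seconds after an anchor
window_of <- function(clock_sec, anchor_sec) {
  d <- (clock_sec - anchor_sec) %% 86400
  d[d == 0] <- 86400
  as.integer(ceiling(d / 3600))
}

# valid minutes falling on valid days, with minute-of-day attached
valid_day_minutes <- function(minutes) {
  assert_columns(minutes, c("participant_id", "t", "mims", "is_valid"),
                 "minute table")
  dv <- summarize_day_validity(minutes)
  minutes |>
    dplyr::mutate(date = lubridate::as_date(.data$t)) |>
    dplyr::inner_join(
      dplyr::filter(dv, .data$is_valid_day)[c("participant_id", "date")],
      by = c("participant_id", "date")
    )
}

hourly_means_by_window <- function(vm, window) {
  ids <- unique(vm$participant_id)
  vm$window <- window
  vm |>
    dplyr::filter(.data$is_valid) |>
    dplyr::group_by(.data$participant_id, .data$window) |>
    dplyr::summarise(mean_mims = mean(.data$mims), .groups = "drop") |>
    tidyr::complete(
      participant_id = ids, window = 1:24,
      fill = list(mean_mims = NA_real_)
    )
}

#' Hourly mean MIMS in clock time
#'
#' Secondary framing: window k covers `(k-1):01` to `k:00` (window 1 is
#' 00:01-01:00). Only valid minutes on valid days contribute.
#'
#' @param minutes Minute table flagged by [flag_valid_minutes()].
#' @return Long tibble `participant_id`, `window` (1-24), `mean_mims` (NA
#'   when no valid minute ever falls in the window).
#' @export
hourly_means_clock <- function(minutes) {
  vm <- valid_day_minutes(minutes)
  hourly_means_by_window(vm, window_of(minute_of_day(vm$t) * 60, 0))
}

#' Hourly mean MIMS relative to the sleep midpoint
#'
#' Primary framing: the 24-window frame is anchored at each participant's
#' overall average sleep midpoint, replicated every calendar day; window k is
#' `(midpoint + (k-1) h, midpoint + k h]` and is labelled by the hours passed
#' beyond the midpoint at the end of the window. Midpoints are carried at
#' second resolution (half-integer night-axis minutes are not rounded).
#'
#' @param minutes Minute table flagged by [flag_valid_minutes()].
#' @param sleep_summaries Per-participant tibble with `participant_id` and
#'   `overall_midpoint` (night-axis minutes, see [summarize_sleep()]).
#' @return Long tibble as for [hourly_means_clock()]; participants without a
#'   midpoint get all 24 windows missing.
#' @export
hourly_means_relative <- function(minutes, sleep_summaries) {
  assert_columns(sleep_summaries, c("participant_id", "overall_midpoint"),
                 "sleep summary table")
  vm <- valid_day_minutes(minutes) |>
    dplyr::left_join(
      sleep_summaries[c("participant_id", "overall_midpoint")],
      by = "participant_id"
    )
  has_mid <- !is.na(vm$overall_midpoint)
  out <- hourly_means_by_window(
    vm[has_mid, ],
    window_of(
      minute_of_day(vm$t[has_mid]) * 60,
      night_index_to_clock_sec(vm$overall_midpoint[has_mid])
    )
  )
  no_mid <- setdiff(unique(vm$participant_id), out$participant_id)
  if (length(no_mid) > 0) {
    out <- dplyr::bind_rows(
      out,
      tidyr::expand_grid(participant_id = no_mid, window = 1:24,
                         mean_mims = NA_real_)
    )
  }
  out
}

#' Total daily activity
#'
#' Average over valid days of the within-day sum of per-minute MIMS over
#' valid minutes (MIMS/day).
#'
#' @param minutes Minute table flagged by [flag_valid_minutes()].
#' @return Tibble `participant_id`, `total_mims` (NA when no valid day).
#' @export
total_activity <- function(minutes) {
  valid_day_minutes(minutes) |>
    dplyr::filter(.data$is_valid) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(day_sum = sum(.data$mims), .groups = "drop_last") |>
    dplyr::summarise(total_mims = mean(.data$day_sum), .groups = "drop")
}

#' Daily sleep duration and its category
#'
#' Average minutes classified sleep wear per valid day containing any sleep
#' (so days recorded entirely awake, e.g. a truncated last day, do not
#' dilute the nightly duration), expressed in hours, with the conventional
#' `<7`, `7-9` (closed on both ends), `>9` h bands. A participant with no
#' sleep minutes on any valid day gets `NA`.
#'
#' @param minutes Minute table flagged by [flag_valid_minutes()].
#' @return Tibble `participant_id`, `sleep_h`, `sleep_duration_cat`.
#' @export
sleep_duration <- function(minutes) {
  valid_day_minutes(minutes) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      sleep_min = sum(.data$wear_class == "sleep_wear"), .groups = "drop_last"
    ) |>
    dplyr::filter(.data$sleep_min > 0) |>
    dplyr::summarise(sleep_h = mean(.data$sleep_min) / 60, .groups = "drop") |>
    dplyr::mutate(sleep_duration_cat = sleep_duration_category(.data$sleep_h))
}

sleep_duration_category <- function(sleep_h) {
  factor(
    dplyr::case_when(
      is.na(sleep_h) ~ NA_character_,
      sleep_h < 7 ~ "<7",
      sleep_h <= 9 ~ "7-9",
      TRUE ~ ">9"
    ),
    levels = c("<7", "7-9", ">9")
  )
}

#' Assign quintiles of an exposure
#'
#' Cut points at the unweighted 20/40/60/80th percentiles of the non-missing
#' values; a value at or below a cut point falls in the lower quintile, so
#' tied values always share a quintile (with all values identical everyone is
#' quintile 1). Quintile 1 (lowest activity) is the reference group.
#'
#' @param values Numeric vector (per-participant window means).
#' @return Integer vector of quintile labels 1-5 (NA preserved).
#' @export
assign_quintiles <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 5) stop_usage("need at least 5 non-missing values for quintiles")
  cuts <- stats::quantile(values[ok], c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  out <- rep(NA_integer_, length(values))
  out[ok] <- 1L + vapply(values[ok], function(v) sum(v > cuts), integer(1))
  out
}

#' Build the per-participant hourly feature matrix
#'
#' One row per participant: the 24 midpoint-relative and 24 clock hourly
#' means (`rel_h01..rel_h24`, `clock_h01..clock_h24`), total daily activity,
#' sleep duration with category, sleep-timing summaries and the number of
#' valid days.
#'
#' @param minutes Minute-level tibble (flagged or not; validity flags are
#'   recomputed if absent).
#' @param sleep_summaries Output of [summarize_sleep()]; computed from
#'   `minutes` when omitted.
#' @return Wide tibble, one row per participant.
#' @export
hourly_features <- function(minutes, sleep_summaries = NULL) {
  if (!"is_valid" %in% names(minutes)) minutes <- flag_valid_minutes(minutes)
  if (is.null(sleep_summaries)) {
    sleep_summaries <- summarize_sleep(sleep_windows(minutes))
  }
  widen <- function(long, prefix) {
    long |>
      dplyr::mutate(window = sprintf("%s%02d", prefix, .data$window)) |>
      tidyr::pivot_wider(names_from = "window", values_from = "mean_mims")
  }
  rel <- widen(hourly_means_relative(minutes, sleep_summaries), "rel_h")
  clk <- widen(hourly_means_clock(minutes), "clock_h")
  dv <- summarize_day_validity(minutes) |>
    dplyr::filter(.data$is_valid_day) |>
    dplyr::count(.data$participant_id, name = "n_valid_days")

  rel |>
    dplyr::left_join(clk, by = "participant_id") |>
    dplyr::left_join(total_activity(minutes), by = "participant_id") |>
    dplyr::left_join(sleep_duration(minutes), by = "participant_id") |>
    dplyr::left_join(
      sleep_summaries[c("participant_id", "overall_midpoint",
                        "weekend_midpoint", "n_nights")],
      by = "participant_id"
    ) |>
    dplyr::left_join(dv, by = "participant_id") |>
    dplyr::mutate(n_valid_days = dplyr::coalesce(.data$n_valid_days, 0L))
}

#' Write the feature matrix as TSV
#'
#' @param features Tibble from [hourly_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}
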