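# Nightly sleep onset/offset detection and sleep-midpoint (chronotype)
# summaries.
#
# Detection runs on the night axis: minute 0 = 20:00, minute 839 = 09:59 the
# next morning. Restricting the search to 20:00-10:00 avoids mistaking
# severely misaligned rest for the main nightly sleep bout. A rolling
# 30-minute window slides forward (for onset) or backward (for offset) one
# minute at a time; the bout edge is the first (resp. last) sleep-labelled
# minute inside the first window holding >= 15 sleep-wear minutes (>= 50%).

#' Detect sleep onset within a night
#'
#' @param sleep_flags Logical vector of length 840 (night axis, 20:00-09:59):
#'   `TRUE` where the minute is labelled sleep wear. Minutes absent from the
#'   recording must be supplied as `FALSE`.
#' @return Night-axis minute index (0-based) of sleep onset, or `NA` if no
#'   30-minute window reaches 15 sleep minutes.
#' @export
detect_onset <- function(sleep_flags) {
  stopifnot(is.logical(sleep_flags), length(sleep_flags) == NIGHT_LEN)
  cs <- cumsum(c(0L, sleep_flags))
  counts <- cs[31:(NIGHT_LEN + 1)] - cs[1:(NIGHT_LEN - 29)] # windows [s, s+29]
  s <- which(counts >= 15L)[1]
  if (is.na(s)) return(NA_integer_)
  first_in <- which(sleep_flags[s:(s + 29L)])[1]
  as.integer(s + first_in - 2L) # 0-based
}

#' Detect sleep offset within a night
#'
#' Mirror of [detect_onset()]: windows end at 09:59 and roll one minute
#' backward until one holds >= 15 sleep-wear minutes; the offset is the last
#' sleep-labelled minute inside that window.
#'
#' @inheritParams detect_onset
#' @return Night-axis minute index (0-based) of sleep offset, or `NA`.
#' @export
detect_offset <- function(sleep_flags) {
  stopifnot(is.logical(sleep_flags), length(sleep_flags) == NIGHT_LEN)
  cs <- cumsum(c(0L, sleep_flags))
  counts <- cs[31:(NIGHT_LEN + 1)] - cs[1:(NIGHT_LEN - 29)] # window [e-29, e] at e = s+29
  e <- rev(which(counts >= 15L))[1] + 29L
  if (is.na(e)) return(NA_integer_)
  last_in <- rev(which(sleep_flags[(e - 29L):e]))[1]
  as.integer(e - 30L + last_in - 1L) # 0-based
}

#' Sleep window for one night
#'
#' @inheritParams detect_onset
#' @param anchor_date Date of the evening the night belongs to.
#' @param participant_id Optional id carried into the result.
#' @return One-row tibble (`participant_id`, `anchor_date`, `onset`,
#'   `offset`, `midpoint`) or `NULL` when either detector fails or the
#'   detected offset precedes the onset.
#' @export
nightly_sleep_window <- function(sleep_flags, anchor_date,
                                 participant_id = NA_character_) {
  onset <- detect_onset(sleep_flags)
  offset <- detect_offset(sleep_flags)
  if (is.na(onset) || is.na(offset) || offset < onset) return(NULL)
  tibble::tibble(
    participant_id = participant_id,
    anchor_date = anchor_date,
    onset = onset, offset = offset,
    midpoint = (onset + offset) / 2
  )
}

#' Detect sleep windows for every night in a minute table
#'
#' Minutes between 20:00 and 09:59 are grouped into nights anchored on the
#' evening date; minutes missing from the recording count as not-sleep.
#'
#' @param minutes Minute-level tibble (see [read_minute_records()]).
#' @return Tibble of per-night sleep windows (participants' failed nights are
#'   absent).
#' @export
sleep_windows <- function(minutes) {
  assert_columns(minutes, c("participant_id", "t", "wear_class"), "minute table")
  mod <- minute_of_day(minutes$t)
  in_night <- mod >= NIGHT_START_MOD | mod < 600L
  nm <- tibble::tibble(
    participant_id = minutes$participant_id[in_night],
    date = lubridate::as_date(minutes$t[in_night]),
    idx = ifelse(mod[in_night] >= NIGHT_START_MOD,
                 mod[in_night] - NIGHT_START_MOD, mod[in_night] + 240L),
    sleep = minutes$wear_class[in_night] == "sleep_wear"
  )
  # evening minutes (index < 240) anchor to their own date; morning minutes
  # belong to the previous evening's night
  nm$anchor_date <- dplyr::if_else(nm$idx < 240L, nm$date, nm$date - 1L)

  nm |>
    dplyr::group_by(.data$participant_id, .data$anchor_date) |>
    dplyr::group_map(function(g, key) {
      flags <- logical(NIGHT_LEN)
      flags[g$idx[g$sleep] + 1L] <- TRUE
      nightly_sleep_window(flags, key$anchor_date, key$participant_id)
    }) |>
    dplyr::bind_rows()
}

#' Summarize sleep timing per participant
#'
#' Onset and offset are averaged arithmetically on the 20:00-anchored night
#' axis (the search window precludes midnight wraparound); the overall sleep
#' midpoint is the midpoint of these averages. The weekend midpoint — the
#' chronotype proxy — uses Friday and Saturday nights only and is missing
#' when the recording covers none.
#'
#' @param windows Per-night tibble from [sleep_windows()].
#' @return One row per participant: `mean_onset`, `mean_offset`,
#'   `overall_midpoint`, `weekend_midpoint` (night-axis minutes), their
#'   `HH:MM:SS` clock renderings, and `n_nights`.
#' @export
summarize_sleep <- function(windows) {
  if (nrow(windows) == 0) {
    return(tibble::tibble(
      participant_id = character(), mean_onset = numeric(),
      mean_offset = numeric(), overall_midpoint = numeric(),
      weekend_midpoint = numeric(), n_nights = integer(),
      midpoint_clock = character(), weekend_midpoint_clock = character()
    ))
  }
  windows |>
    dplyr::mutate(
      weekend = lubridate::wday(.data$anchor_date, week_start = 1) %in% c(5L, 6L)
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      mean_onset = mean(.data$onset),
      mean_offset = mean(.data$offset),
      overall_midpoint = (mean(.data$onset) + mean(.data$offset)) / 2,
      weekend_midpoint = if (any(.data$weekend)) {
        (mean(.data$onset[.data$weekend]) + mean(.data$offset[.data$weekend])) / 2
      } else NA_real_,
      n_nights = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      midpoint_clock = night_index_to_clock(.data$overall_midpoint),
      weekend_midpoint_clock = ifelse(
        is.na(.data$weekend_midpoint), NA_character_,
        night_index_to_clock(.data$weekend_midpoint)
      )
    )
}

#' Write per-night and per-participant sleep tables as TSV
#'
#' @param windows Per-night tibble from [sleep_windows()].
#' @param summaries Per-participant tibble from [summarize_sleep()].
#' @param nights_path,summary_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_sleep_tables <- function(windows, summaries, nights_path, summary_path) {
  windows |>
    dplyr::mutate(
      onset_clock = night_index_to_clock(.data$onset),
      offset_clock = night_index_to_clock(.data$offset),
      midpoint_clock = night_index_to_clock(.data$midpoint)
    ) |>
    dplyr::select("participant_id", "anchor_date", "onset_clock",
                  "offset_clock", "midpoint_clock") |>
    readr::write_tsv(nights_path)
  readr::write_tsv(summaries, summary_path)
  invisible(c(nights_path, summary_path))
}
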