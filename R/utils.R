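# Shared internal helpers: time axes, clock formatting, input checks.

# Night axis: minute index 0..839 maps 20:00 (index 0) to 09:59 next day
# (index 839). All sleep detection happens on this axis.
NIGHT_LEN <- 840L
NIGHT_START_MOD <- 1200L # 20:00 as minute-of-day

WEAR_LEVELS <- c("wake_wear", "sleep_wear", "non_wear", "unknown")

EXCLUSION_REASONS <- c(
  "age_le_20", "pregnant", "lt_4_valid_days", "missing_hourly_window",
  "unknown_diabetes", "missing_outcome", "on_diabetes_medication", "none"
)

#' Convert a night-axis minute index to a clock string
#'
#' The night axis anchors minute 0 at 20:00 and minute 839 at 09:59 the next
#' morning; fractional indices (half-integer midpoints) are carried at second
#' resolution.
#'
#' @param idx Numeric vector of night-axis minute indices (may be fractional).
#' @return Character vector of `HH:MM:SS` 24 h clock strings.
#' @export
#' @examples
#' night_index_to_clock(c(0, 419.5, 839))
night_index_to_clock <- function(idx) {
  sec <- (NIGHT_START_MOD * 60 + round(idx * 60)) %% 86400
  sprintf(
    "%02d:%02d:%02d",
    sec %/% 3600L, (sec %% 3600L) %/% 60L, sec %% 60L
  )
}

# Night-axis index -> clock time in seconds after midnight.
night_index_to_clock_sec <- function(idx) {
  (NIGHT_START_MOD * 60 + idx * 60) %% 86400
}

# minute-of-day (0..1439) for POSIXct timestamps, local clock as recorded
minute_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour * 60L + lt$min
}

stop_data <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "actiscan_data_error")
}

stop_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "actiscan_format_error")
}

stop_usage <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "actiscan_usage_error")
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_format(
      "%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    )
  }
  invisible(df)
}
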