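# Programmatic fixtures: tiny minute tables and participant tables.

# One or more full recording days for one participant. `wear` and `mims`
# recycle over 1440 * n_days minutes.
make_days <- function(participant_id = "P1", start = as.Date("2013-01-07"),
                      n_days = 1, wear = "wake_wear", mims = 10) {
  n <- 1440L * n_days
  tibble::tibble(
    participant_id = participant_id,
    t = as.POSIXct(paste(start, "00:00:00"), tz = "UTC") + (0:(n - 1)) * 60,
    mims = rep_len(mims, n),
    wear_class = factor(rep_len(wear, n), levels = actiscan:::WEAR_LEVELS),
    quality_flag = FALSE
  )
}

# set the wear class of the minutes whose clock minute-of-day lies in
# [from, to] (inclusive, 0-based) on a given date
set_wear <- function(minutes, date, from, to, wear) {
  lt <- as.POSIXlt(minutes$t, tz = "UTC")
  mod <- lt$hour * 60 + lt$min
  sel <- as.Date(minutes$t, tz = "UTC") == date & mod >= from & mod <= to
  minutes$wear_class[sel] <- wear
  minutes
}

# night-axis logical flags for a set of [on, off] 0-based index intervals
night_flags <- function(...) {
  flags <- logical(840)
  for (iv in list(...)) flags[(iv[1]:iv[2]) + 1] <- TRUE
  flags
}

# minute table realizing given night-axis sleep flags for the night anchored
# on `anchor` (covers the full 20:00-09:59 window, wake elsewhere)
night_minutes <- function(flags, anchor = as.Date("2013-01-07"),
                          participant_id = "P1", mims = 5) {
  idx <- 0:839
  mod <- ifelse(idx < 240, 1200 + idx, idx - 240)
  date <- dplyr::if_else(idx < 240, anchor, anchor + 1)
  tibble::tibble(
    participant_id = participant_id,
    t = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + mod * 60,
    mims = mims,
    wear_class = factor(ifelse(flags, "sleep_wear", "wake_wear"),
                        levels = actiscan:::WEAR_LEVELS),
    quality_flag = FALSE
  ) |>
    dplyr::arrange(t)
}

# minimal participant table for cascade tests
make_participants <- function(n, age = 45, pregnant = FALSE, diabetes = FALSE) {
  tibble::tibble(
    participant_id = sprintf("P%d", seq_len(n)),
    age = rep_len(age, n),
    pregnant = rep_len(pregnant, n),
    diabetes = rep_len(diabetes, n)
  )
}

# feature matrix with all 48 windows present (constant means)
make_profiles <- function(ids, value = 10) {
  m <- matrix(value, nrow = length(ids), ncol = 48)
  colnames(m) <- c(sprintf("rel_h%02d", 1:24), sprintf("clock_h%02d", 1:24))
  dplyr::bind_cols(tibble::tibble(participant_id = ids), tibble::as_tibble(m))
}

write_minutes_csv <- function(minutes, path) {
  df <- minutes
  df$timestamp <- format(df$t, "%Y-%m-%d %H:%M")
  df$t <- NULL
  readr::write_csv(df[c("participant_id", "timestamp", "mims", "wear_class",
                        "quality_flag")], path)
  path
}
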