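# Ingest: minute-level and participant-level readers.

# Wear-code synonyms accepted on input; anything else maps to "unknown".
.wear_code_map <- c(
  "wake" = "wake_wear", "wake_wear" = "wake_wear", "1" = "wake_wear",
  "sleep" = "sleep_wear", "sleep_wear" = "sleep_wear", "2" = "sleep_wear",
  "nonwear" = "non_wear", "non_wear" = "non_wear", "non-wear" = "non_wear",
  "3" = "non_wear",
  "unknown" = "unknown", "4" = "unknown"
)

#' Read minute-level actigraphy records
#'
#' Reads a minute-level table (one row per participant-minute) carrying MIMS
#' values and upstream wear/sleep classifications, in the layout used by the
#' national accelerometry files this package targets. Required columns:
#' `participant_id`, `timestamp` (ISO-8601, minute resolution), `mims`,
#' `wear_class`, and optionally `quality_flag`.
#'
#' Wear codes `wake`/`wake_wear`/`1`, `sleep`/`sleep_wear`/`2`,
#' `nonwear`/`non_wear`/`3` are normalised; any other code becomes
#' `"unknown"` and is counted in the load report (attached as attribute
#' `"load_report"`).
#'
#' @param path Path to the input file.
#' @param dialect `"csv"` (canonical) or `"xpt"` (SAS transport; requires the
#'   `foreign` package, column names matched case-insensitively).
#' @return A tibble sorted by `(participant_id, t)` with columns
#'   `participant_id`, `t` (POSIXct, UTC-encoded local clock), `mims`,
#'   `wear_class` (factor), `quality_flag`; attribute `load_report` lists row
#'   and unknown-code counts.
#' @export
read_minute_records <- function(path, dialect = c("csv", "xpt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_usage("input file does not exist: %s", path)
  if (dialect == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  } else {
    if (!requireNamespace("foreign", quietly = TRUE)) {
      stop_usage("reading SAS transport files requires the 'foreign' package")
    }
    raw <- tibble::as_tibble(foreign::read.xport(path))
    names(raw) <- tolower(names(raw))
  }
  assert_columns(raw, c("participant_id", "timestamp", "mims", "wear_class"),
                 "minute-level input")
  if (!"quality_flag" %in% names(raw)) raw$quality_flag <- "FALSE"

  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    t = lubridate::ymd_hm(raw$timestamp, tz = "UTC", quiet = TRUE),
    mims = as.numeric(raw$mims),
    wear_class = normalize_wear_class(as.character(raw$wear_class)),
    quality_flag = as.logical(raw$quality_flag)
  )
  if (nrow(out) > 0 && anyNA(out$t)) {
    # accept full ISO date-times with seconds too
    bad <- is.na(out$t)
    out$t[bad] <- lubridate::ymd_hms(raw$timestamp[bad], tz = "UTC", quiet = TRUE)
    if (anyNA(out$t)) stop_format("unparseable timestamp(s) in minute-level input")
  }
  out <- dplyr::arrange(out, .data$participant_id, .data$t)
  check_monotone_minutes(out)

  report <- list(
    n_rows = nrow(out),
    n_participants = dplyr::n_distinct(out$participant_id),
    n_unknown_wear = sum(out$wear_class == "unknown")
  )
  attr(out, "load_report") <- report
  out
}

normalize_wear_class <- function(x) {
  mapped <- unname(.wear_code_map[tolower(trimws(x))])
  mapped[is.na(mapped)] <- "unknown"
  factor(mapped, levels = WEAR_LEVELS)
}

check_monotone_minutes <- function(minutes) {
  if (nrow(minutes) < 2) return(invisible(minutes))
  same <- minutes$participant_id[-1] == minutes$participant_id[-nrow(minutes)]
  dt <- diff(as.numeric(minutes$t))
  if (any(same & dt <= 0)) {
    bad <- minutes$participant_id[-1][same & dt <= 0][1]
    stop_data("non-monotone timestamps within participant %s", bad)
  }
  invisible(minutes)
}

#' Read a participant-level table
#'
#' One row per participant with demographics, covariates, outcomes, survey
#' design variables and subsample flags. Only `participant_id` is required;
#' all other columns are passed through with type guessing, so the data
#' dictionary is enforced downstream by [encode_covariates()] and
#' [apply_exclusion_cascade()].
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per participant.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop_usage("input file does not exist: %s", path)
  out <- readr::read_csv(path, col_types = readr::cols(), show_col_types = FALSE)
  assert_columns(out, "participant_id", "participant-level input")
  out$participant_id <- as.character(out$participant_id)
  if (anyDuplicated(out$participant_id)) {
    stop_data("duplicate participant_id in participant-level input")
  }
  out
}
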