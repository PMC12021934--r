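# Outcome derivation, biomarker harmonization/transforms, covariate coding.

#' Derive prevalent diabetes status
#'
#' Diabetes is glycated haemoglobin (HbA1c) of at least 48 mmol/mol (6.5%)
#' or a self-reported diagnosis. The disjunction is evaluated with
#' missingness propagated: a single `TRUE` branch suffices, both branches
#' must be known `FALSE` for a negative, and the status is unknown (`NA`)
#' otherwise.
#'
#' @param hba1c Numeric, HbA1c in mmol/mol (NA allowed).
#' @param selfreport Logical, self-reported diagnosis (NA = unknown).
#' @return Logical vector (NA = unknown status).
#' @export
derive_diabetes <- function(hba1c, selfreport) {
  # three-valued OR: NA | TRUE is TRUE, NA | FALSE is NA
  (hba1c >= 48) | selfreport
}

#' Harmonize fasting insulin across survey cycles
#'
#' Laboratory protocols changed between the 2011-2012 and 2013-2014 cycles;
#' 2013-2014 values are mapped onto the 2011-2012 scale with the recommended
#' conversion `10^(1.024 * log10(x) - 0.0802)`. 2011-2012 values pass
#' through unchanged, so cycle tagging prevents double application.
#'
#' @param value Fasting insulin in uU/ml, positive.
#' @param cycle Character vector, `"2011-2012"` or `"2013-2014"`.
#' @return Insulin on the 2011-2012 scale (uU/ml).
#' @export
harmonize_insulin <- function(value, cycle) {
  ok <- is.na(value) | value > 0
  if (!all(ok)) stop_data("fasting insulin must be positive")
  cycle <- as.character(cycle)
  if (!all(cycle %in% c("2011-2012", "2013-2014") | is.na(cycle))) {
    stop_usage("unknown survey cycle label")
  }
  n <- max(length(value), length(cycle))
  value <- rep_len(value, n)
  cycle <- rep_len(cycle, n)
  conv <- !is.na(cycle) & cycle == "2013-2014" & !is.na(value)
  value[conv] <- 10^(1.024 * log10(value[conv]) - 0.0802)
  value
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' The standard HOMA1-IR form: fasting glucose (mmol/l) times fasting
#' insulin (uU/ml, already cycle-harmonized) divided by 22.5.
#'
#' @param fasting_glucose mmol/l, positive.
#' @param fasting_insulin uU/ml, positive, harmonized.
#' @return Unitless HOMA-IR.
#' @export
compute_homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (!all(is.na(fasting_glucose) | fasting_glucose > 0) ||
      !all(is.na(fasting_insulin) | fasting_insulin > 0)) {
    stop_data("glucose and insulin must be positive for HOMA-IR")
  }
  fasting_glucose * fasting_insulin / 22.5
}

#' Natural-log transform the glycaemic outcomes
#'
#' Fasting glucose, fasting insulin, HOMA-IR and the 2 h OGTT glucose are
#' analysed on the natural-log scale to improve normality.
#'
#' @param panel Tibble with (any of) `fasting_glucose`, `fasting_insulin`,
#'   `homa_ir`, `ogtt_2h_glucose`.
#' @return The input with `log_*` columns added.
#' @export
transform_outcomes <- function(panel) {
  cols <- intersect(
    c("fasting_glucose", "fasting_insulin", "homa_ir", "ogtt_2h_glucose"),
    names(panel)
  )
  for (cl in cols) {
    v <- panel[[cl]]
    if (any(!is.na(v) & v <= 0)) {
      stop_data("non-positive %s cannot be log-transformed", cl)
    }
    panel[[paste0("log_", cl)]] <- log(v)
  }
  panel
}

# closed categorical level sets used in every model
COVARIATE_LEVELS <- list(
  gender = c("men", "women"),
  race_ethnicity = c("nh_white", "nh_black", "hispanic", "other"),
  education = c("lt_high_school", "high_school", "some_college",
                "college_or_above"),
  income = c("<20k", "20k-44.9k", "45k-74.9k", ">=75k"),
  marital = c("not_married", "married"),
  smoking = c("never", "former", "current"),
  alcohol = c("<1/week", "1/week-<1/day", ">=1/day"),
  bmi_cat = c("<18.5", "18.5-<25", "25-<30", ">=30")
)

#' Encode the model covariate set
#'
#' Fixes every categorical covariate to its closed level set (first level =
#' reference), bins BMI at 18.5/25/30 kg/m2 (right-open) and household
#' income at US$20k/45k/75k when supplied as dollars, and attaches the
#' continuous sleep midpoint (minutes on the 20:00-anchored night axis) and
#' sleep-duration category when sleep features are supplied. Missing
#' covariates stay `NA`; analyses are complete-case.
#'
#' @param participants Participant tibble with raw covariate fields (`age`,
#'   `gender`, `race_ethnicity`, `education`, `income` or `income_usd`,
#'   `marital`, `smoking`, `alcohol`, `bmi` or `bmi_cat`, `energy_kj`).
#' @param sleep_features Optional tibble with `participant_id`,
#'   `overall_midpoint`, `sleep_h` and/or `sleep_duration_cat` (e.g. from
#'   [hourly_features()]); joined on id.
#' @return The input tibble with covariates coded as factors/numerics.
#' @export
encode_covariates <- function(participants, sleep_features = NULL) {
  p <- participants
  if (!is.null(sleep_features)) {
    keep <- intersect(
      c("participant_id", "overall_midpoint", "sleep_h", "sleep_duration_cat"),
      names(sleep_features)
    )
    p <- dplyr::left_join(
      p, sleep_features[keep], by = "participant_id",
      suffix = c("", ".feat")
    )
  }
  as_level <- function(x, levels) {
    if (is.factor(x)) x <- as.character(x)
    bad <- !is.na(x) & !x %in% levels
    if (any(bad)) {
      stop_data("covariate value(s) outside the closed level set: %s",
                paste(unique(x[bad]), collapse = ", "))
    }
    factor(x, levels = levels)
  }
  for (nm in c("gender", "race_ethnicity", "education", "marital",
               "smoking", "alcohol")) {
    if (nm %in% names(p)) p[[nm]] <- as_level(p[[nm]], COVARIATE_LEVELS[[nm]])
  }
  if ("bmi" %in% names(p)) {
    if (any(!is.na(p$bmi) & p$bmi <= 0)) stop_data("BMI must be positive")
    p$bmi_cat <- cut(p$bmi, c(0, 18.5, 25, 30, Inf),
                     labels = COVARIATE_LEVELS$bmi_cat, right = FALSE)
  } else if ("bmi_cat" %in% names(p)) {
    p$bmi_cat <- as_level(p$bmi_cat, COVARIATE_LEVELS$bmi_cat)
  }
  if ("income_usd" %in% names(p) && !"income" %in% names(p)) {
    p$income <- cut(p$income_usd, c(-Inf, 20000, 45000, 75000, Inf),
                    labels = COVARIATE_LEVELS$income, right = FALSE)
  } else if ("income" %in% names(p)) {
    p$income <- as_level(p$income, COVARIATE_LEVELS$income)
  }
  if ("sleep_h" %in% names(p) && !"sleep_duration_cat" %in% names(p)) {
    p$sleep_duration_cat <- sleep_duration_category(p$sleep_h)
  }
  if ("overall_midpoint" %in% names(p)) {
    p$sleep_midpoint <- p$overall_midpoint
  }
  p
}

#' Assemble the analysis-ready glycaemic panel
#'
#' Harmonizes fasting insulin across cycles, computes HOMA-IR, derives
#' diabetes status from HbA1c and self-report, and adds the log-scale
#' outcomes.
#'
#' @param participants Tibble with `hba1c`, `diabetes_selfreport`,
#'   `fasting_glucose`, `fasting_insulin`, `survey_cycle`,
#'   `ogtt_2h_glucose` (all optional except ids).
#' @return The input with `fasting_insulin` harmonized, `homa_ir`,
#'   `diabetes` and `log_*` columns added.
#' @export
derive_outcome_panel <- function(participants) {
  p <- participants
  if (all(c("fasting_insulin", "survey_cycle") %in% names(p))) {
    p$fasting_insulin <- harmonize_insulin(p$fasting_insulin, p$survey_cycle)
  }
  if (all(c("fasting_glucose", "fasting_insulin") %in% names(p))) {
    p$homa_ir <- compute_homa_ir(p$fasting_glucose, p$fasting_insulin)
  }
  if (all(c("hba1c", "diabetes_selfreport") %in% names(p))) {
    p$diabetes <- derive_diabetes(p$hba1c, p$diabetes_selfreport)
  }
  transform_outcomes(p)
}
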