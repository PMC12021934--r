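# tidy()/glance()/autoplot()/print() methods for window-scan results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a window scan
#'
#' @param x A `window_scan` from [run_window_scan()].
#' @param ... Unused.
#' @return A plain tibble of per-window, per-quintile association rows.
#' @method tidy window_scan
#' @export
tidy.window_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "window_scan")
  tibble::as_tibble(out)
}

#' One-row summary of a window scan
#'
#' @param x A `window_scan`.
#' @param ... Unused.
#' @return Tibble with the outcome, model family, framing, window counts and
#'   the window with the strongest top-vs-bottom quintile estimate.
#' @method glance window_scan
#' @export
glance.window_scan <- function(x, ...) {
  tx <- tidy(x)
  top <- tx |>
    dplyr::filter(.data$quintile == max(.data$quintile), .data$estimable)
  extreme <- if (nrow(top) > 0) top$window[which.max(abs(top$estimate))] else
    NA_integer_
  tibble::tibble(
    outcome = attr(x, "outcome"),
    family = attr(x, "family"),
    framing = attr(x, "framing"),
    n_windows = dplyr::n_distinct(tx$window),
    n_estimable = dplyr::n_distinct(tx$window[tx$estimable]),
    n_used = max(tx$n_used),
    extreme_window = extreme,
    min_p_trend = suppressWarnings(min(tx$p_trend, na.rm = TRUE))
  )
}

#' Plot the top-vs-bottom quintile association curve
#'
#' Draws the 24-point curve of the highest-vs-lowest quintile estimate with
#' its 95% CI ribbon: odds ratios on a log-scaled axis for logistic scans,
#' beta coefficients for linear scans. Non-estimable windows appear as gaps.
#'
#' @param object A `window_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_scan
#' @export
autoplot.window_scan <- function(object, ...) {
  tx <- tidy(object)
  logistic <- attr(object, "family") == "binomial"
  top <- tx |>
    dplyr::filter(.data$quintile == max(.data$quintile)) |>
    dplyr::mutate(
      y = dplyr::if_else(.data$estimable,
                         if (logistic) exp(.data$estimate) else .data$estimate,
                         NA_real_),
      lo = dplyr::if_else(.data$estimable,
                          if (logistic) exp(.data$ci_low) else .data$ci_low,
                          NA_real_),
      hi = dplyr::if_else(.data$estimable,
                          if (logistic) exp(.data$ci_high) else .data$ci_high,
                          NA_real_)
    )
  ref <- if (logistic) 1 else 0
  xlab <- if (attr(object, "framing") == "relative") {
    "Hours after sleep midpoint (window end)"
  } else "Clock hour (window end)"
  p <- ggplot2::ggplot(top, ggplot2::aes(x = .data$window, y = .data$y)) +
    ggplot2::geom_hline(yintercept = ref, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      alpha = 0.25, fill = "steelblue"
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.4, colour = "steelblue") +
    ggplot2::scale_x_continuous(breaks = seq(2, 24, 2)) +
    ggplot2::labs(
      x = xlab,
      y = if (logistic) "OR (Q5 vs Q1)" else "β (Q5 vs Q1)",
      title = attr(object, "outcome")
    ) +
    ggplot2::theme_minimal()
  if (logistic) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf(
    "<window_scan> outcome=%s family=%s framing=%s (%d windows)\n",
    attr(x, "outcome"), attr(x, "family"), attr(x, "framing"),
    dplyr::n_distinct(x$window)
  ))
  NextMethod()
}

#' Write a window-scan grid in results-table layout
#'
#' Wide layout mirroring the familiar per-window table: one row per window,
#' OR (95% CI) text per quintile and the trend p-value; plus the long format
#' used for plotting.
#'
#' @param scan A `window_scan`.
#' @param path_wide,path_long Output TSV paths (either may be `NULL`).
#' @return Invisibly, the wide tibble.
#' @export
write_scan_tables <- function(scan, path_wide = NULL, path_long = NULL) {
  tx <- tidy(scan)
  logistic <- attr(scan, "family") == "binomial"
  fmt <- function(e, lo, hi, est) {
    dplyr::case_when(
      !est ~ "-",
      e == 0 & lo == 0 & hi == 0 ~ "Ref",
      TRUE ~ sprintf("%.2f (%.2f, %.2f)",
                     if (logistic) exp(e) else e,
                     if (logistic) exp(lo) else lo,
                     if (logistic) exp(hi) else hi)
    )
  }
  wide <- tx |>
    dplyr::mutate(cell = fmt(.data$estimate, .data$ci_low, .data$ci_high,
                             .data$estimable),
                  quintile = paste0("Q", .data$quintile)) |>
    dplyr::select("window", "quintile", "cell", "p_trend") |>
    tidyr::pivot_wider(names_from = "quintile", values_from = "cell") |>
    dplyr::relocate("p_trend", .after = dplyr::last_col())
  if (!is.null(path_wide)) readr::write_tsv(wide, path_wide)
  if (!is.null(path_long)) readr::write_tsv(tx, path_long)
  invisible(wide)
}
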