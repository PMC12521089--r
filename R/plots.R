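#' @import ggplot2
NULL

#' Forest plot of reporting odds ratios
#'
#' Shows the top terms of a signal table by ROR with their 95% confidence
#' intervals on a log scale; consensus signals are highlighted.
#'
#' @param object A `faers_signals` table from [detect_signals()].
#' @param top_n How many terms (by ROR) to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faers_signals
#' @export
autoplot.faers_signals <- function(object, top_n = 30, ...) {
  d <- as_tibble(object) |>
    dplyr::arrange(dplyr::desc(.data$ror)) |>
    utils::head(top_n) |>
    dplyr::mutate(term = stats::reorder(.data$term, .data$ror))
  ggplot(d, aes(x = .data$ror, y = .data$term, colour = .data$consensus)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ror_lo, xmax = .data$ror_hi), height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    scale_x_log10() +
    scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
                        name = "consensus") +
    labs(x = "Reporting odds ratio (95% CI)", y = NULL,
         title = paste0("Disproportionality signals (",
                        attr(object, "level") %||% "", " level)")) +
    theme_minimal()
}

#' @rdname autoplot.faers_signals
#' @export
plot_signal_forest <- function(object, top_n = 30) {
  autoplot.faers_signals(object, top_n = top_n)
}

#' Histogram of the time-to-onset distribution
#'
#' @param object A `tto_summary` from [summarize_tto()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tto_summary
#' @export
autoplot.tto_summary <- function(object, ...) {
  d <- object$bins |>
    dplyr::mutate(bin = factor(.data$bin, levels = .data$bin))
  ggplot(d, aes(x = .data$bin, y = .data$count)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = scales_pct(.data$proportion)), vjust = -0.4,
              size = 3) +
    labs(x = "Days from therapy start to event", y = "Reports",
         title = sprintf("Time to onset (median %s days, IQR %s-%s)",
                         format(object$median_days), format(object$q1),
                         format(object$q3))) +
    theme_minimal()
}

scales_pct <- function(p) {
  ifelse(is.na(p), "", sprintf("%.1f%%", 100 * p))
}

#' @rdname autoplot.tto_summary
#' @export
plot_tto <- function(object) autoplot.tto_summary(object)

#' Annual report counts
#'
#' Bar chart of reports per FDA receipt year, from the `year` block of the
#' demographic summary.
#'
#' @param demographics Tibble from [summarize_demographics()].
#' @return A ggplot object.
#' @export
plot_annual_reports <- function(demographics) {
  d <- demographics |>
    dplyr::filter(.data$characteristic == "year") |>
    dplyr::mutate(year = as.integer(.data$level))
  ggplot(d, aes(x = .data$year, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "Year", y = "Reports", title = "Reports per year") +
    theme_minimal()
}
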