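#' Plot a fitted carcass distance distribution
#'
#' Histogram of the observed (truncated) carcass distances with the
#' fitted density rescaled to the truncated sample, and a reference
#' line at the plot half-width beyond which only the plot corners are
#' searched.
#'
#' @param object A [twl_fit()].
#' @param binwidth Histogram bin width in metres.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot twl_fit
#' @export
autoplot.twl_fit <- function(object, binwidth = 5, ...) {
  tau <- object$plot$truncation_distance
  a <- object$plot$half_width
  grid <- tibble::tibble(
    distance_m = seq(0, tau, length.out = 200)
  ) |>
    dplyr::mutate(
      density = dist_density(.data$distance_m, object$family, object$shape,
                             object$scale) /
        dist_cdf(tau, object$family, object$shape, object$scale)
    )
  ggplot2::ggplot(tibble::tibble(distance_m = object$distances),
                  ggplot2::aes(x = .data$distance_m)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      binwidth = binwidth, boundary = 0, fill = "grey70", colour = "grey40"
    ) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$density), colour = "#2166ac",
                       linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = a, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::labs(
      x = "Distance from turbine (m)", y = "Density",
      title = sprintf("%s fit%s", object$family,
                      if (!is.null(object$treatment))
                        paste0(" (", object$treatment, ")") else ""),
      subtitle = sprintf("n = %d, mode %.1f m%s", object$n, object$mode_m,
                         if (object$reliable) "" else " [unreliable]")
    ) +
    ggplot2::theme_minimal()
}

#' Plot adjusted fatality estimates with confidence intervals
#'
#' @param object A `fatality_study` from [estimate_study_fatalities()]
#'   or [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot of observed and adjusted fatalities per turbine by
#'   treatment, with bootstrap CIs.
#' @method autoplot fatality_study
#' @export
autoplot.fatality_study <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$treatment)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_per_turbine),
                      fill = "grey75", width = 0.6) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$m_per_turbine, ymin = .data$m_ci_lower,
                   ymax = .data$m_ci_upper),
      colour = "#b2182b"
    ) +
    ggplot2::labs(
      x = NULL, y = "Fatalities / turbine / season",
      title = "Observed (bars) and detection-adjusted (points) fatalities",
      subtitle = sprintf("%.0f%% bootstrap CIs, k = %.2f",
                         100 * object$ci_level, object$k)
    ) +
    ggplot2::theme_minimal()
}

#' Curtailment cost-benefit plot
#'
#' Scatter of each treatment's fatality reduction against its revenue
#' loss relative to control, summarising the cost-benefit trade-off of
#' the curtailment strategies.
#'
#' @param report A `study_report` from [run_pipeline()] that includes
#'   operation summaries.
#' @return A ggplot.
#' @export
plot_cost_benefit <- function(report) {
  if (is.null(report$ops_comparisons)) {
    abort("`report` has no operations comparisons; supply ops records.")
  }
  comp <- report$comparisons |>
    dplyr::mutate(alt = .data$treatment) |>
    dplyr::inner_join(
      report$ops_comparisons |>
        dplyr::mutate(alt = sub("^.* vs\\. ", "", .data$comparison)) |>
        dplyr::select("alt", "revenue_difference"),
      by = "alt"
    )
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$revenue_difference,
                                     y = 100 * .data$reduction,
                                     label = .data$alt)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * .data$ci_lower,
                                        ymax = 100 * .data$ci_upper),
                           width = 0) +
    ggplot2::geom_text(nudge_x = 0, nudge_y = 4) +
    ggplot2::labs(
      x = "Revenue loss vs control ($ / turbine)",
      y = "Fatality reduction vs control (%)",
      title = "Cost-benefit of curtailment strategies"
    ) +
    ggplot2::theme_minimal()
}
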