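scenario_palette <- c(none = "grey40", moderate = "#f2c45f",
                      high = "#e98b4a", maximum = "#c23b22",
                      progressive = "#4a7fb5")

#' Plot the suppression filter's containment curves
#'
#' Proportion of spread suppressed against fireline intensity (log scale)
#' for each scenario, with the common impossibility cutoff.
#'
#' @param scenarios Named list of [suppression_scenario()]s.
#' @return A ggplot object.
#' @export
plot_containment_curves <- function(scenarios = default_scenarios()) {
  d <- containment_curve_table(scenarios)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$intensity,
                                  y = .data$prop_suppressed,
                                  colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = scenario_palette) +
    ggplot2::labs(x = "Fireline intensity (kW/m)",
                  y = "Proportion of spread suppressed",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}

#' Plot Lorenz curves of burned area by scenario
#'
#' @param records Fire-record tibble from [run_experiment()]; Lorenz curves
#'   are computed per scenario, pooling replicates, at the given level.
#' @param level Gradient level index (default the first level).
#' @return A ggplot object.
#' @export
plot_lorenz <- function(records, level = min(records$level)) {
  check_record_columns(records)
  d <- records |>
    dplyr::filter(.data$level == !!level) |>
    dplyr::group_by(.data$scenario) |>
    dplyr::group_modify(~ lorenz_curve(.x$final_area)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_fires, y = .data$p_area,
                                  colour = .data$scenario)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::scale_colour_manual(values = scenario_palette) +
    ggplot2::labs(x = "Cumulative share of fires (ranked by area)",
                  y = "Cumulative share of burned area",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}

#' Plot a per-level summary metric across the gradient
#'
#' @param levels Level-summary tibble from [summarize_levels()].
#' @param metric One of `"mean_area"`, `"mean_cbi"`, `"prop_high_severity"`,
#'   `"cbi_mad"`.
#' @return A ggplot object with 95% CI ribbons where available.
#' @export
plot_gradient <- function(levels, metric = c("mean_area", "mean_cbi",
                                             "prop_high_severity", "cbi_mad")) {
  metric <- match.arg(metric)
  lab <- c(mean_area = "Mean fire size (ha)",
           mean_cbi = "Mean fire severity (CBI)",
           prop_high_severity = "Proportion high severity",
           cbi_mad = "Diversity of fire severity (CBI MAD)")[[metric]]
  p <- ggplot2::ggplot(levels,
                       ggplot2::aes(x = .data$level_value,
                                    y = .data[[metric]],
                                    colour = .data$scenario,
                                    fill = .data$scenario))
  lo <- paste0(metric, "_lo"); hi <- paste0(metric, "_hi")
  if (all(c(lo, hi) %in% names(levels)) && any(!is.na(levels[[lo]])))
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[lo]],
                                               ymax = .data[[hi]]),
                                  alpha = 0.2, colour = NA)
  p + ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::scale_colour_manual(values = scenario_palette) +
    ggplot2::scale_fill_manual(values = scenario_palette) +
    ggplot2::labs(x = "Gradient level (kPa or Mg/ha)", y = lab,
                  colour = "Scenario", fill = "Scenario") +
    ggplot2::theme_minimal()
}

#' Plot a simulated fire perimeter
#'
#' Overhead view of the per-angle perimeter of one simulated fire, colored by
#' ring fireline intensity; requires a fire simulated with
#' `keep_rings = TRUE`.
#'
#' @param fire A fire record from [simulate_fire()] with a `"rings"`
#'   attribute.
#' @return A ggplot object.
#' @export
plot_perimeter <- function(fire) {
  rings <- attr(fire, "rings")
  if (is.null(rings) || nrow(rings) == 0)
    stop("simulate the fire with `keep_rings = TRUE` (and a spreading fire) to plot its perimeter",
         call. = FALSE)
  d <- dplyr::mutate(rings, x = .data$dist * cos(.data$angle),
                     y = .data$dist * sin(.data$angle))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$intensity,
                                  group = .data$angle)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::scale_colour_viridis_c(option = "inferno", trans = "log10") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "m (heading direction = +x)", y = "m",
                  colour = "kW/m") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
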