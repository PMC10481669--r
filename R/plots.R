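#' Plot a solved pressure profile along the CV-PV axis
#'
#' @param object A `pressure_solution`.
#' @param ... Unused.
#' @return A ggplot of canalicular pressure (Pa) against the radial
#'   coordinate (um).
#' @method autoplot pressure_solution
#' @export
autoplot.pressure_solution <- function(object, ...) {
  ggplot2::ggplot(as.data.frame(object),
                  ggplot2::aes(x = .data$rho_um, y = .data$p_pa)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = expression(rho ~ "[" * mu * "m]"),
                  y = "canalicular pressure [Pa]") +
    ggplot2::theme_minimal()
}

#' Plot zone-resolved network statistics
#'
#' @param object A `zone_profile` from [zone_statistics()].
#' @param statistic Column to plot (default `"mean_radius_um"`).
#' @param ... Unused.
#' @return A ggplot of the statistic per zone 0 (CV) to 10 (PV).
#' @method autoplot zone_profile
#' @export
autoplot.zone_profile <- function(object, statistic = "mean_radius_um",
                                  ...) {
  if (!statistic %in% names(object)) {
    abort(sprintf("unknown zone statistic `%s`.", statistic))
  }
  ggplot2::ggplot(as.data.frame(object),
                  ggplot2::aes(x = .data$zone, y = .data[[statistic]])) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2, colour = "#b2182b") +
    ggplot2::scale_x_continuous(breaks = object$zone) +
    ggplot2::labs(x = "zone (0 = CV, 10 = PV)", y = statistic) +
    ggplot2::theme_minimal()
}

#' Plot a canalicular network in projection
#'
#' xy projection of the spatial graph, edges shaded by radius; rosette
#' segments (radius above half the given diameter threshold) highlighted.
#'
#' @param object A [canalicular_network()].
#' @param diameter_threshold_um Rosette highlight threshold (default 6).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot canalicular_network
#' @export
autoplot.canalicular_network <- function(object,
                                         diameter_threshold_um = 6, ...) {
  nodes <- object$nodes
  idx <- match(object$edges$from, nodes$id)
  jdx <- match(object$edges$to, nodes$id)
  seg <- tibble(x = nodes$x_um[idx], y = nodes$y_um[idx],
                xend = nodes$x_um[jdx], yend = nodes$y_um[jdx],
                radius_um = object$edges$radius_um,
                rosette = 2 * object$edges$radius_um > diameter_threshold_um)
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                    xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_segment(ggplot2::aes(linewidth = .data$radius_um,
                                       colour = .data$rosette)) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 2)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#b2182b")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [um]", y = "y [um]", linewidth = "radius [um]",
                  colour = "rosette") +
    ggplot2::theme_minimal()
}

#' Scatter plot of the pooled correlation stage
#'
#' @param obs An `axis_observations` tibble from [simulate_cohort()].
#' @param y `"pressure_pa"` or `"connectivity"`.
#' @return A ggplot of rosette/network volume ratio against `y`, pooled
#'   over (sample, zone) observations.
#' @export
plot_correlation <- function(obs, y = c("pressure_pa", "connectivity")) {
  y <- match.arg(y)
  ggplot2::ggplot(as.data.frame(obs),
                  ggplot2::aes(x = .data$rosette_ratio, y = .data[[y]],
                               colour = .data$regime)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "black",
                         linewidth = 0.5) +
    ggplot2::labs(x = "rosette / network volume", y = y) +
    ggplot2::theme_minimal()
}
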