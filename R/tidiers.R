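#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a solved pressure profile
#'
#' @param x A `pressure_solution`.
#' @param ... Unused.
#' @return The solution as a plain tibble (`rho_um`, `w_m_s`, `p_pa`,
#'   `c_mol_m3`, `wc_m_s`).
#' @method tidy pressure_solution
#' @export
tidy.pressure_solution <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a solved pressure profile
#'
#' @param x A `pressure_solution`.
#' @param n_zones Zones used for the elevation summary (default 11).
#' @param ... Unused.
#' @return A one-row tibble: `p0_pa`, `axis_median_pa`, `elevation_pa`,
#'   `residual_pa`, `iterations`.
#' @method glance pressure_solution
#' @export
glance.pressure_solution <- function(x, n_zones = 11L, ...) {
  zs <- zone_pressure_summary(x, n_zones = n_zones)
  tibble(p0_pa = attr(x, "p0_pa"),
         axis_median_pa = zs$axis_median_pa,
         elevation_pa = zs$elevation_pa,
         residual_pa = attr(x, "residual_pa"),
         iterations = attr(x, "iterations"))
}

#' Tidy a rosette detection result
#'
#' @param x A `rosette_counts`.
#' @param ... Unused.
#' @return The per-(zone, j) count table.
#' @method tidy rosette_counts
#' @export
tidy.rosette_counts <- function(x, ...) x$counts

#' One-row summary of a rosette detection result
#'
#' @param x A `rosette_counts`.
#' @param ... Unused.
#' @return A one-row tibble: `n_segments`, `total_volume_um3`,
#'   `max_radius_um`.
#' @method glance rosette_counts
#' @export
glance.rosette_counts <- function(x, ...) {
  tibble(n_segments = nrow(x$segments),
         total_volume_um3 = rosette_volume(x),
         max_radius_um = if (nrow(x$segments)) max(x$segments$max_radius_um)
                         else NA_real_)
}
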