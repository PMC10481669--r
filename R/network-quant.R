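#' Assign lobule zones along the CV-PV axis
#'
#' Labels every node and edge of a spatial canalicular network with its
#' radial zone. A node's normalized axis coordinate is its distance from
#' the central-vein edge divided by the CV-edge-to-PV-edge distance; zones
#' are `n_zones` equal-width bins of that coordinate (zone 0 at the CV,
#' zone `n_zones - 1` at the PV), with out-of-range values clamped into
#' the end bins. Edges are assigned by their midpoint.
#'
#' @param net A [canalicular_network()].
#' @param n_zones Number of zones (default 11, displayed as 0-10).
#' @return A list of class `zoned_network` extending the network with
#'   `zone` columns on `nodes` and `edges` and an `n_zones` element.
#' @examples
#' zn <- assign_zones(gen_network(synthetic_config("control", seed = 2)))
#' table(zn$edges$zone)
#' @export
assign_zones <- function(net, n_zones = 11L) {
  stopifnot(inherits(net, "canalicular_network"))
  n_zones <- check_count(n_zones, "n_zones", 1L)
  lm <- net$landmarks
  if (lm$pv_radius_um - lm$cv_radius_um <= 0) {
    abort("CV and PV landmarks coincide.")
  }
  bin <- function(t) pmin(pmax(floor(t * n_zones), 0), n_zones - 1)

  nodes <- net$nodes
  t_node <- axis_coordinate(net, nodes$x_um, nodes$y_um)
  nodes$zone <- as.integer(bin(t_node))

  idx <- match(net$edges$from, nodes$id)
  jdx <- match(net$edges$to, nodes$id)
  mx <- (nodes$x_um[idx] + nodes$x_um[jdx]) / 2
  my <- (nodes$y_um[idx] + nodes$y_um[jdx]) / 2
  t_edge <- axis_coordinate(net, mx, my)
  edges <- net$edges
  edges$zone <- as.integer(bin(t_edge))

  out <- net
  out$nodes <- nodes
  out$edges <- edges
  out$n_zones <- n_zones
  class(out) <- c("zoned_network", class(net))
  out
}

zone_tissue_volumes_um3 <- function(net, n_zones) {
  lm <- net$landmarks
  breaks <- seq(lm$cv_radius_um, lm$pv_radius_um, length.out = n_zones + 1)
  (net$sector_angle_rad / 2) *
    (breaks[-1]^2 - breaks[-(n_zones + 1)]^2) * net$tissue_depth_um
}

#' Zone-resolved canalicular network statistics
#'
#' Computes, for each lobule zone, the six network descriptors used to
#' characterize canalicular remodelling along the CV-PV axis:
#' \describe{
#'   \item{mean_radius_um}{length-weighted mean edge radius}
#'   \item{volume_fraction_pct}{`100 * sum(pi r^2 l) /` zone tissue volume}
#'   \item{surface_to_volume_um2_mm3}{`sum(2 pi r l) /` zone tissue volume,
#'     in um^2 per mm^3}
#'   \item{connectivity}{`1 /` number of connected components of the
#'     zone-induced subgraph (1 = a single piece)}
#'   \item{crossings_per_mm2}{edges whose endpoint zones straddle this
#'     zone's CV-side boundary, per boundary area (arc length x depth)}
#'   \item{junctions_per_um}{nodes of full-graph degree >= 3 in the zone,
#'     per total zone network length}
#' }
#' Zone tissue volumes use the annular-sector geometry the network
#' occupies. Zones without edges yield `NA` statistics with a warning.
#'
#' @param zoned A `zoned_network` from [assign_zones()].
#' @return A tibble of class `zone_profile`, one row per zone, with the
#'   columns above plus `zone`, `n_nodes`, `n_edges`,
#'   `network_volume_um3`.
#' @export
zone_statistics <- function(zoned) {
  stopifnot(inherits(zoned, "zoned_network"))
  nz <- zoned$n_zones
  nodes <- zoned$nodes
  edges <- zoned$edges
  vz <- zone_tissue_volumes_um3(zoned, nz)
  lm <- zoned$landmarks
  breaks <- seq(lm$cv_radius_um, lm$pv_radius_um, length.out = nz + 1)

  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = nodes$id))
  deg <- igraph::degree(g)[as.character(nodes$id)]

  out <- purrr::map(seq_len(nz) - 1L, function(z) {
    ez <- edges[edges$zone == z, ]
    nz_nodes <- nodes[nodes$zone == z, ]
    vol <- sum(pi * ez$radius_um^2 * ez$length_um)
    len <- sum(ez$length_um)
    if (nrow(ez) == 0L) {
      warn(sprintf("zone %d has no edges; statistics set to NA.", z))
      conn <- NA_real_; mr <- NA_real_; s2v <- NA_real_
      vf <- 0; jpl <- NA_real_
    } else {
      sub <- igraph::subgraph_from_edges(
        g, which(edges$zone == z), delete.vertices = TRUE)
      conn <- 1 / igraph::count_components(sub)
      mr <- sum(ez$radius_um * ez$length_um) / len
      vf <- 100 * vol / vz[z + 1]
      # um^2 / um^3 -> um^2 / mm^3: multiply by 1e9
      s2v <- sum(2 * pi * ez$radius_um * ez$length_um) / vz[z + 1] * 1e9
      jpl <- sum(deg[nodes$zone == z] >= 3) / len
    }
    # edges straddling this zone's CV-side radial boundary
    if (z == 0L) {
      crossings <- 0L
      boundary_area_mm2 <- zoned$sector_angle_rad * breaks[1] *
        zoned$tissue_depth_um / 1e6
    } else {
      zf <- nodes$zone[match(edges$from, nodes$id)]
      zt <- nodes$zone[match(edges$to, nodes$id)]
      crossings <- sum(pmin(zf, zt) < z & pmax(zf, zt) >= z)
      boundary_area_mm2 <- zoned$sector_angle_rad * breaks[z + 1] *
        zoned$tissue_depth_um / 1e6
    }
    tibble(zone = z, n_nodes = nrow(nz_nodes), n_edges = nrow(ez),
           mean_radius_um = mr, volume_fraction_pct = vf,
           surface_to_volume_um2_mm3 = s2v, connectivity = conn,
           crossings_per_mm2 = crossings / boundary_area_mm2,
           junctions_per_um = jpl, network_volume_um3 = vol)
  }) |> bind_rows()

  structure(out, class = c("zone_profile", class(out)))
}

#' Lobule radius summaries from CV-PV axis measurements
#'
#' Summarizes per-sample lobule radii the way cohort medians are reported:
#' each sample contributes the median of its CV-edge-to-PV-edge distance
#' measurements; the cohort value is the mean of the per-sample medians.
#'
#' @param measurements A data frame with columns `sample` and
#'   `distance_um` (one row per measured axis), or a bare numeric vector
#'   for a single sample.
#' @return A list with `per_sample` (tibble: `sample`,
#'   `median_radius_um`, `n`) and `cohort_mean_um`.
#' @examples
#' lobule_radius(c(400, 500, 600))$per_sample$median_radius_um
#' @export
lobule_radius <- function(measurements) {
  if (is.numeric(measurements)) {
    measurements <- tibble(sample = "sample1", distance_um = measurements)
  }
  if (!all(c("sample", "distance_um") %in% names(measurements))) {
    abort("`measurements` needs columns `sample` and `distance_um`.")
  }
  if (nrow(measurements) == 0L) abort("no lobule radius measurements given.")
  if (any(!is.finite(measurements$distance_um) |
            measurements$distance_um <= 0)) {
    abort("lobule radius measurements must be positive.")
  }
  per_sample <- measurements |>
    group_by(.data$sample) |>
    summarise(median_radius_um = median(.data$distance_um), n = n(),
              .groups = "drop")
  list(per_sample = per_sample,
       cohort_mean_um = mean(per_sample$median_radius_um))
}
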