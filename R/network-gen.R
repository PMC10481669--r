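#' Spatial canalicular network container
#'
#' A `canalicular_network` holds a skeletonized bile-canaliculi network as a
#' pair of tibbles plus the vein landmarks needed to place it on the CV-PV
#' axis. Edge lengths are always derived from node coordinates.
#'
#' @param nodes Tibble with columns `id` (integer), `x_um`, `y_um`, `z_um`.
#' @param edges Tibble with columns `from`, `to` (node ids) and `radius_um`.
#'   A `length_um` column is (re)computed from the node coordinates.
#' @param landmarks Named list with `cv_center_um` (length-2 xy position of
#'   the central-vein axis), `cv_radius_um` (vein radius, the CV edge) and
#'   `pv_radius_um` (distance from the CV centre to the PV edge, i.e. the
#'   lobule radius `L`).
#' @param tissue_depth_um Imaged tissue depth (um).
#' @param sector_angle_rad Angular width (rad) of the annular sector the
#'   network occupies; used for shell/zone volume normalizations.
#' @return An object of class `canalicular_network`: a list with elements
#'   `nodes`, `edges`, `landmarks`, `tissue_depth_um`, `sector_angle_rad`.
#' @export
canalicular_network <- function(nodes, edges, landmarks,
                                tissue_depth_um, sector_angle_rad = 0.2) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  need_n <- c("id", "x_um", "y_um", "z_um")
  if (!all(need_n %in% names(nodes))) {
    abort(sprintf("`nodes` must have columns %s.",
                  paste(need_n, collapse = ", ")))
  }
  if (anyDuplicated(nodes$id)) abort("duplicate node ids.")
  need_e <- c("from", "to", "radius_um")
  if (!all(need_e %in% names(edges))) {
    abort(sprintf("`edges` must have columns %s.",
                  paste(need_e, collapse = ", ")))
  }
  if (any(edges$from == edges$to)) {
    abort("self-loop edge(s) found; the graph must be simple.")
  }
  if (!all(c(edges$from, edges$to) %in% nodes$id)) {
    abort("edge endpoint refers to an unknown node id.")
  }
  if (any(!is.finite(edges$radius_um) | edges$radius_um <= 0)) {
    abort("edge radii must be positive and finite.")
  }
  for (nm in c("cv_center_um", "cv_radius_um", "pv_radius_um")) {
    if (is.null(landmarks[[nm]])) abort(sprintf("landmark `%s` missing.", nm))
  }
  if (landmarks$pv_radius_um <= landmarks$cv_radius_um) {
    abort("landmarks coincide or are inverted: need pv_radius_um > cv_radius_um.")
  }
  idx <- match(edges$from, nodes$id)
  jdx <- match(edges$to, nodes$id)
  edges$length_um <- sqrt(
    (nodes$x_um[idx] - nodes$x_um[jdx])^2 +
      (nodes$y_um[idx] - nodes$y_um[jdx])^2 +
      (nodes$z_um[idx] - nodes$z_um[jdx])^2
  )
  if (any(edges$length_um <= 0)) {
    abort("zero-length edge (coincident node coordinates).")
  }
  check_number(tissue_depth_um, "tissue_depth_um", 0, strict_lower = TRUE)
  structure(
    list(nodes = nodes, edges = edges, landmarks = landmarks,
         tissue_depth_um = tissue_depth_um,
         sector_angle_rad = sector_angle_rad),
    class = "canalicular_network"
  )
}

#' @export
print.canalicular_network <- function(x, ...) {
  cat(sprintf(
    "<canalicular_network> %d nodes, %d edges; annulus %g-%g um, depth %g um\n",
    nrow(x$nodes), nrow(x$edges), x$landmarks$cv_radius_um,
    x$landmarks$pv_radius_um, x$tissue_depth_um))
  invisible(x)
}

# normalized CV->PV coordinate of arbitrary xy positions (can exceed [0,1])
axis_coordinate <- function(net, x_um, y_um) {
  lm <- net$landmarks
  rho <- sqrt((x_um - lm$cv_center_um[1])^2 + (y_um - lm$cv_center_um[2])^2)
  (rho - lm$cv_radius_um) / (lm$pv_radius_um - lm$cv_radius_um)
}

#' Generate a synthetic canalicular network for one lobule axis
#'
#' Fills the annular sector `rho0 .. L` (angular width
#' `config$sector_angle_rad`, depth `config$tissue_depth_um`) with a
#' connected-by-construction spatial graph:
#' node positions are stratified along the normalized CV->PV coordinate
#' (exactly `nodes_per_zone` per zone), each node is joined to its nearest
#' predecessor (a spanning tree), and extra short-range edges are added to
#' create branch points. Edge radii are drawn around
#' `baseline_radius_um * radius_dilation_factor` (truncated below 3 um); a
#' `rosette_fraction` subset of edges is re-assigned radii uniform in
#' `rosette_radius_range_um`; finally a `dropout_fraction` of edges is
#' removed to emulate network degradation.
#'
#' Adjacency is decided in normalized coordinates, so two configurations
#' differing only in lobule radius, dilation or rosette burden share the
#' same topology under the same seed; with matched seeds and no dropout the
#' dilated regime's edge radii dominate the control's edge-by-edge.
#'
#' @param config A [synthetic_config()].
#' @return A [canalicular_network()]. Regeneration with the same config is
#'   identical.
#' @examples
#' net <- gen_network(synthetic_config("control", seed = 7))
#' nrow(net$edges)
#' @export
gen_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, gen_network_impl(config))
}

gen_network_impl <- function(config) {
  nz <- config$n_zones
  npz <- config$nodes_per_zone
  n <- nz * npz
  rho0 <- config$cv_radius_um
  L <- config$lobule_radius_um

  # stratified axis positions: npz nodes per zone, so no zone is ever empty
  t <- sort(runif(n, rep((seq_len(nz) - 1) / nz, each = npz),
                  rep(seq_len(nz) / nz, each = npz)))
  theta <- runif(n, -config$sector_angle_rad / 2, config$sector_angle_rad / 2)
  zrel <- runif(n)

  rho <- rho0 + t * (L - rho0)
  nodes <- tibble(
    id = seq_len(n),
    x_um = rho * cos(theta),
    y_um = rho * sin(theta),
    z_um = zrel * config$tissue_depth_um
  )

  # adjacency in normalized (regime-independent) coordinates
  u <- cbind(t, (theta / config$sector_angle_rad + 0.5) * 0.25, zrel * 0.25)
  from <- integer(0); to <- integer(0)
  for (i in 2:n) {
    d2 <- (u[seq_len(i - 1), 1] - u[i, 1])^2 +
      (u[seq_len(i - 1), 2] - u[i, 2])^2 +
      (u[seq_len(i - 1), 3] - u[i, 3])^2
    j <- which.min(d2)
    from <- c(from, j); to <- c(to, i)
  }
  # extra short-range links -> branch points (junctions, degree >= 3)
  key <- paste(pmin(from, to), pmax(from, to))
  add_from <- integer(0); add_to <- integer(0)
  p_extra <- 0.45
  for (i in seq_len(n)) {
    if (runif(1) > p_extra) next
    d2 <- (u[, 1] - u[i, 1])^2 + (u[, 2] - u[i, 2])^2 + (u[, 3] - u[i, 3])^2
    d2[i] <- Inf
    ord <- order(d2)[1:4]
    for (j in ord) {
      k <- paste(min(i, j), max(i, j))
      if (!k %in% key) {
        key <- c(key, k)
        add_from <- c(add_from, min(i, j)); add_to <- c(add_to, max(i, j))
        break
      }
    }
  }
  from <- c(from, add_from); to <- c(to, add_to)
  m <- length(from)

  # baseline radii: lognormal jitter around the (possibly dilated) baseline,
  # truncated so baseline calibres never reach the rosette range
  r_base <- config$baseline_radius_um * config$radius_dilation_factor *
    exp(rnorm(m, sd = 0.18))
  r_base <- pmin(pmax(r_base, 0.2), 2.5)

  # rosette insertion: per-edge probability, optionally tilted pericentrally
  t_mid <- (t[from] + t[to]) / 2
  p_ros <- pmin(pmax(
    config$rosette_fraction * (1 + config$rosette_cv_bias * (1 - 2 * t_mid)),
    0), 1)
  ros_draw <- runif(m)
  ros_radius <- runif(m, config$rosette_radius_range_um[1],
                      config$rosette_radius_range_um[2])
  is_ros <- ros_draw < p_ros

  nodes <- as.data.frame(nodes)
  edges <- data.frame(from = from, to = to, radius_um = r_base)
  # a rosette is a localized dilation, not a dilated canaliculus: split the
  # host edge and blow up only its middle third (a compact blob between
  # two stretches of ordinary calibre)
  for (e in which(is_ros)) {
    a <- edges$from[e]; b <- edges$to[e]
    ia <- match(a, nodes$id); ib <- match(b, nodes$id)
    id1 <- nrow(nodes) + 1L; id2 <- nrow(nodes) + 2L
    mid <- function(w) {
      c(nodes$x_um[ia], nodes$y_um[ia], nodes$z_um[ia]) * (1 - w) +
        c(nodes$x_um[ib], nodes$y_um[ib], nodes$z_um[ib]) * w
    }
    p1 <- mid(1 / 3); p2 <- mid(2 / 3)
    nodes <- rbind(nodes,
                   data.frame(id = c(id1, id2),
                              x_um = c(p1[1], p2[1]),
                              y_um = c(p1[2], p2[2]),
                              z_um = c(p1[3], p2[3])))
    r0 <- edges$radius_um[e]
    edges$to[e] <- id1
    edges <- rbind(edges,
                   data.frame(from = c(id1, id2), to = c(id2, b),
                              radius_um = c(ros_radius[e], r0)))
  }
  edges <- as_tibble(edges)
  t_mid <- c(t_mid, t_mid[rep(which(is_ros), each = 2)])
  if (config$dropout_fraction > 0) {
    # degradation co-localizes with rosette formation: same axial bias
    p_drop <- pmin(pmax(
      config$dropout_fraction *
        (1 + config$rosette_cv_bias * (1 - 2 * t_mid)), 0), 1)
    keep <- runif(nrow(edges)) >= p_drop
    if (any(keep)) edges <- edges[keep, ]
  }

  canalicular_network(
    nodes, edges,
    landmarks = list(cv_center_um = c(0, 0), cv_radius_um = rho0,
                     pv_radius_um = L),
    tissue_depth_um = config$tissue_depth_um,
    sector_angle_rad = config$sector_angle_rad
  )
}
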