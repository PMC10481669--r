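#' Reduce a spatial network to radial geometry profiles
#'
#' Bridges the graph representation to the radial profiles the pressure
#' model consumes. The annulus is partitioned into `n_shells` equal-width
#' radial shells; each edge is assigned to the shell containing its
#' midpoint; per shell,
#' \describe{
#'   \item{eps_bc}{`sum(pi r^2 l) / V_shell` — lumen volume fraction}
#'   \item{A_per_um}{`sum(2 pi r l) / V_shell` — apical surface density}
#'   \item{r_bc_um}{length-weighted mean edge radius — the typical
#'     canalicular calibre that sets the viscous resistance; rare cystic
#'     dilations contribute their volume and surface but are not allowed
#'     to dominate the effective flow radius}
#' }
#' where `V_shell` is the volume of the annular-sector shell actually
#' sampled: `(sector_angle / 2) (rho_out^2 - rho_in^2) * depth`. Shells with
#' no edges are filled by linear interpolation from neighbouring shells and
#' a warning is raised. The profile grid is the shell midpoints; `f` and
#' `tau` take the standard constants (0.28, 1.8) unless overridden.
#'
#' @param net A [canalicular_network()].
#' @param tissue_depth_um Depth used for shell volumes; defaults to the
#'   network's own.
#' @param n_shells Number of radial shells (default 11).
#' @param f Free lumen ratio applied to all shells (default 0.28).
#' @param tau Tortuosity (default 1.8).
#' @return A [radial_geometry()] on the shell-midpoint grid.
#' @export
network_to_geometry <- function(net, tissue_depth_um = NULL, n_shells = 11L,
                                f = 0.28, tau = 1.8) {
  stopifnot(inherits(net, "canalicular_network"))
  n_shells <- check_count(n_shells, "n_shells", 2L)
  depth <- tissue_depth_um %||% net$tissue_depth_um
  check_number(depth, "tissue_depth_um", 0, strict_lower = TRUE)

  lm <- net$landmarks
  rho0 <- lm$cv_radius_um
  L <- lm$pv_radius_um
  breaks <- seq(rho0, L, length.out = n_shells + 1)

  nodes <- net$nodes
  idx <- match(net$edges$from, nodes$id)
  jdx <- match(net$edges$to, nodes$id)
  mx <- (nodes$x_um[idx] + nodes$x_um[jdx]) / 2
  my <- (nodes$y_um[idx] + nodes$y_um[jdx]) / 2
  rho_mid <- sqrt((mx - lm$cv_center_um[1])^2 + (my - lm$cv_center_um[2])^2)
  shell <- pmin(pmax(findInterval(rho_mid, breaks, rightmost.closed = TRUE),
                     1L), n_shells)

  r <- net$edges$radius_um
  l <- net$edges$length_um
  vol <- pi * r^2 * l
  surf <- 2 * pi * r * l

  v_shell <- (net$sector_angle_rad / 2) *
    (breaks[-1]^2 - breaks[-(n_shells + 1)]^2) * depth

  sum_by <- function(x) {
    out <- numeric(n_shells)
    agg <- tapply(x, shell, sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  vol_s <- sum_by(vol)
  surf_s <- sum_by(surf)
  len_s <- sum_by(l)
  lenr_s <- sum_by(l * r)

  eps <- vol_s / v_shell
  A <- surf_s / v_shell
  r_bc <- ifelse(len_s > 0, lenr_s / len_s, NA_real_)

  empty <- vol_s == 0
  if (any(empty)) {
    warn(sprintf("%d empty radial shell(s) filled by interpolation: %s",
                 sum(empty), paste(which(empty) - 1, collapse = ", ")))
    fill <- function(v) {
      ok <- which(!empty)
      if (length(ok) == 0L) abort("no populated shells: empty network.")
      if (length(ok) == 1L) return(rep(v[ok], n_shells))
      approx(ok, v[ok], xout = seq_len(n_shells), rule = 2)$y
    }
    eps <- fill(eps); A <- fill(A); r_bc <- fill(r_bc)
  }

  mid <- (breaks[-1] + breaks[-(n_shells + 1)]) / 2
  radial_geometry(mid, A, eps, r_bc, rep(f, n_shells), tau = tau)
}

#' @importFrom stats approx
NULL
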