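#' Solve the lobule bile-pressure boundary-value problem by shooting
#'
#' Finds the central pressure `p0` such that the outward integration of the
#' osmotic/Darcy system hits the periportal boundary pressure
#' `p(L) = pL`. The shooting residual `r(p0) = p(L) - pL` is bracketed by
#' geometric expansion upward from `pL` (with positive secretion the
#' pressure can only fall outward, so `r(pL) <= 0`) and refined by Brent's
#' method. The concentration is reconstructed from the osmolyte balance
#' `c = G/(rho w)` and the canalicular velocity as `wc = w / eps_bc`.
#'
#' @param geom A [radial_geometry()].
#' @param params A [bile_params()].
#' @param tol Tolerance on the terminal pressure residual
#'   `|p(L) - pL|` (Pa); default 0.1.
#' @param max_expand Maximum bracket expansions before giving up.
#' @inheritParams integrate_outward
#' @return A `pressure_solution`: a tibble with columns `rho_um`,
#'   `w_m_s` (bulk velocity), `p_pa`, `c_mol_m3`, `wc_m_s` (canalicular
#'   velocity), and attributes `p0_pa`, `residual_pa`, `iterations`,
#'   `params`. Works with [tidy()][generics::tidy], `glance()` and
#'   `autoplot()`.
#' @examples
#' geom <- gen_radial_geometry(synthetic_config("control", seed = 1))
#' sol <- solve_pressure(geom, bile_params(g = 0.3))
#' glance(sol)
#' @export
solve_pressure <- function(geom, params, tol = 0.1, delta = NULL,
                           rtol = 1e-8, max_expand = 60L) {
  stopifnot(inherits(geom, "radial_geometry"),
            inherits(params, "bile_params"))
  check_number(tol, "tol", 0, strict_lower = TRUE)
  pL <- params$pL
  n_iter <- 0L
  shoot <- function(p0) {
    n_iter <<- n_iter + 1L
    integrate_outward(p0, geom, params, delta = delta, rtol = rtol)
  }

  traj <- shoot(pL)
  r0 <- traj$p_end - pL
  if (abs(r0) > tol) {
    if (r0 > 0) {
      abort("shooting residual positive at p0 = pL; with non-negative secretion the pressure cannot rise outward - review parameters.")
    }
    lo <- pL; r_lo <- r0
    hi <- pL; step <- max(abs(r0), 100)
    found <- FALSE
    for (k in seq_len(max_expand)) {
      hi <- hi + step
      traj_hi <- shoot(hi)
      if (traj_hi$p_end - pL > 0) { found <- TRUE; break }
      lo <- hi; r_lo <- traj_hi$p_end - pL
      step <- step * 2
    }
    if (!found) {
      abort("could not bracket the central pressure; parameters may be unphysical (secretion too strong?).")
    }
    root <- uniroot(function(p0) shoot(p0)$p_end - pL,
                    interval = c(lo, hi), tol = tol * 1e-3)
    traj <- shoot(root$root)
    if (abs(traj$p_end - pL) > tol) {
      abort(sprintf("shooting did not converge: residual %.3g Pa > tol %.3g Pa.",
                    abs(traj$p_end - pL), tol))
    }
  }

  w <- traj$u / traj$rho
  cc <- traj$c
  if (any(geom$eps_bc == 0)) abort("eps_bc = 0: canalicular velocity undefined.")
  wc <- w / geom$eps_bc

  out <- tibble(rho_um = geom$rho_um, w_m_s = w, p_pa = traj$p,
                c_mol_m3 = cc, wc_m_s = wc)
  structure(out,
            class = c("pressure_solution", class(out)),
            p0_pa = traj$p[1], residual_pa = abs(traj$p_end - pL),
            iterations = n_iter, params = params,
            rho0_um = geom_rho0_um(geom), L_um = geom_L_um(geom))
}

#' Canalicular velocity from a solved pressure profile
#'
#' The bulk (tissue-scale) velocity `w` and the velocity inside the
#' canalicular lumen differ by the volume fraction: `wc = w / eps_bc`.
#'
#' @param sol A `pressure_solution`.
#' @param geom The [radial_geometry()] it was solved on.
#' @return A tibble with `rho_um` and `wc_m_s`.
#' @export
canalicular_velocity <- function(sol, geom) {
  stopifnot(inherits(sol, "pressure_solution"),
            inherits(geom, "radial_geometry"))
  if (any(geom$eps_bc == 0)) abort("eps_bc = 0 at some grid point.")
  tibble(rho_um = sol$rho_um, wc_m_s = sol$w_m_s / geom$eps_bc)
}

#' Zone-resolved pressure summary along the CV-PV axis
#'
#' Partitions the radial grid into `n_zones` equal-width zones (zone 0
#' surrounds the central vein, zone `n_zones - 1` the portal field) and
#' summarizes the solved pressure: per-zone medians, the axis median (the
#' median of the pointwise pressure over the grid, reported alongside the
#' median of the zone medians) and the pericentral-over-periportal
#' elevation (zone-0 median minus last-zone median).
#'
#' @param sol A `pressure_solution`.
#' @param n_zones Number of zones (default 11, displayed as 0-10).
#' @return A list of class `zone_pressure_summary`: `zones` (tibble with
#'   `zone`, `median_pa`, `n`), `axis_median_pa` (pointwise, canonical),
#'   `axis_median_zones_pa`, `elevation_pa`.
#' @export
zone_pressure_summary <- function(sol, n_zones = 11L) {
  stopifnot(inherits(sol, "pressure_solution"))
  n_zones <- check_count(n_zones, "n_zones", 2L)
  rho0 <- attr(sol, "rho0_um"); L <- attr(sol, "L_um")
  t <- (sol$rho_um - rho0) / (L - rho0)
  zone <- pmin(pmax(floor(t * n_zones), 0), n_zones - 1)
  zones <- tibble(zone = zone, p_pa = sol$p_pa) |>
    group_by(zone) |>
    summarise(median_pa = median(p_pa), n = n(), .groups = "drop")
  if (nrow(zones) < n_zones) {
    abort("empty pressure zone: the radial grid is too coarse for this zone count.")
  }
  structure(list(
    zones = zones,
    axis_median_pa = median(sol$p_pa),
    axis_median_zones_pa = median(zones$median_pa),
    elevation_pa = zones$median_pa[1] - zones$median_pa[n_zones]
  ), class = "zone_pressure_summary")
}

#' @export
print.zone_pressure_summary <- function(x, ...) {
  cat(sprintf(
    "<zone_pressure_summary> axis median %.1f Pa, CV-over-PV elevation %.1f Pa\n",
    x$axis_median_pa, x$elevation_pa))
  print(x$zones, n = nrow(x$zones))
  invisible(x)
}

#' Calibrate a constant secretion rate against a reference axis pressure
#'
#' Inverse problem for the one free input of the model: finds the spatially
#' constant osmolyte secretion rate `g` at which the solved axis-median
#' pressure equals `target_axis_median_pa`. The axis median is monotone
#' increasing in `g` (it equals `pL` at `g = 0`), so the root is found by
#' geometric bracket expansion plus bisection.
#'
#' @param geom A [radial_geometry()].
#' @param params A [bile_params()]; its `g` entry is ignored.
#' @param target_axis_median_pa Reference axis-median pressure (Pa); must
#'   exceed `params$pL`.
#' @param tol_rel Relative tolerance on the achieved axis median.
#' @param g_init Initial bracket guess (mol/(m^3 s)).
#' @param g_max Upper cap on the secretion rate.
#' @return A list with `g`, `axis_median_pa`, `iterations` and the final
#'   `solution`.
#' @export
calibrate_secretion <- function(geom, params, target_axis_median_pa,
                                tol_rel = 1e-3, g_init = 0.1, g_max = 1e4) {
  stopifnot(inherits(geom, "radial_geometry"),
            inherits(params, "bile_params"))
  target <- check_number(target_axis_median_pa, "target_axis_median_pa", 0)
  if (target <= params$pL) {
    abort(sprintf("target axis median (%g Pa) must exceed the boundary pressure pL (%g Pa).",
                  target, params$pL))
  }
  if (params$kappa == 0) {
    abort("kappa = 0: the pressure is pinned to pL and no target above pL is achievable.")
  }
  solve_g <- function(g) {
    p <- params; p$g <- g
    solve_pressure(geom, p)
  }
  h <- function(sol) median(sol$p_pa) - target

  n_it <- 0L
  lo <- 0; h_lo <- params$pL - target  # g = 0 -> p == pL everywhere
  hi <- g_init
  repeat {
    n_it <- n_it + 1L
    sol_hi <- solve_g(hi)
    if (h(sol_hi) > 0) break
    lo <- hi; h_lo <- h(sol_hi)
    hi <- hi * 4
    if (hi > g_max) {
      abort(sprintf("target %g Pa not reachable below the secretion cap %g.",
                    target, g_max))
    }
  }
  sol <- sol_hi; g_cur <- hi
  for (k in seq_len(80L)) {
    mid <- (lo + hi) / 2
    n_it <- n_it + 1L
    sol <- solve_g(mid)
    g_cur <- mid
    hm <- h(sol)
    if (abs(hm) <= tol_rel * target) break
    if (hm > 0) hi <- mid else lo <- mid
  }
  if (abs(h(sol)) > tol_rel * target) {
    abort("secretion calibration did not converge to the requested tolerance.")
  }
  list(g = g_cur, axis_median_pa = median(sol$p_pa),
       iterations = n_it, solution = sol)
}
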