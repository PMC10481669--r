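# Governing equations (radially symmetric lobule, SI units):
#   (rho w)'/rho = kappa A (RT (c - c0) - p)   water influx across membrane
#   (rho c w)'/rho = g(rho)                    osmolyte secretion
#   p' = -K(rho) w                             Darcy flow
# with w(rho0) = 0 and p(L) = pL. Writing u = rho w and
# G(rho) = int_{rho0}^{rho} rho~ g(rho~) d rho~, the concentration
# c = G/u is eliminated and the system reduces to two states (u, p).

# geometry in SI, as plain vectors
geom_si <- function(geom) {
  list(rho = um_to_m(geom$rho_um),
       A = geom$A_per_um * 1e6,       # 1/um -> 1/m
       eps = geom$eps_bc,
       r_bc = um_to_m(geom$r_bc_um),
       f = geom$f,
       tau = geom_tau(geom),
       rho0 = um_to_m(geom_rho0_um(geom)),
       L = um_to_m(geom_L_um(geom)))
}

#' Darcy flow resistance of the canalicular network
#'
#' Evaluates the porous-media closure for the Darcy proportionality
#' constant, `K(rho) = 8 mu tau^2 / (eps_bc(rho) r_bc(rho)^2 f(rho))`,
#' on the geometry grid. `K` relates the pressure gradient to the bulk
#' velocity via `p' = -K w`.
#'
#' @param geom A [radial_geometry()].
#' @param mu Bile viscosity (Pa s).
#' @return A tibble with columns `rho_um` and `K_pa_s_m2` (Pa s/m^2).
#' @examples
#' g <- gen_radial_geometry(synthetic_config("control", seed = 1))
#' head(darcy_resistance(g))
#' @export
darcy_resistance <- function(geom, mu = 9.2e-4) {
  stopifnot(inherits(geom, "radial_geometry"))
  check_number(mu, "mu", 0, strict_lower = TRUE)
  tibble(rho_um = geom$rho_um, K_pa_s_m2 = darcy_resistance_vec(geom, mu))
}

darcy_resistance_vec <- function(geom, mu) {
  si <- geom_si(geom)
  denom <- si$eps * si$r_bc^2 * si$f
  bad <- which(!is.finite(denom) | denom <= 0)
  if (length(bad)) {
    abort(sprintf(
      "non-positive eps_bc * r_bc^2 * f at grid point %d (rho = %g um).",
      bad[1], geom$rho_um[bad[1]]))
  }
  8 * mu * si$tau^2 / denom
}

#' Cumulative osmolyte influx G(rho)
#'
#' Integrates the secretion source term of the osmolyte balance:
#' `G(rho) = int_{rho0}^{rho} rho~ g(rho~) d rho~`, so that
#' `rho c w = G(rho)` along any solution. Trapezoidal quadrature on the
#' geometry grid (exact for secretion profiles linear in rho).
#'
#' @param geom A [radial_geometry()].
#' @param g Secretion rate (mol/(m^3 s)): scalar or vector on the grid.
#' @return A tibble with columns `rho_um` and `G` (mol/(m^2 s)).
#' @export
osmolyte_influx <- function(geom, g) {
  stopifnot(inherits(geom, "radial_geometry"))
  tibble(rho_um = geom$rho_um,
         G = osmolyte_influx_vec(um_to_m(geom$rho_um),
                                 g_profile(list(g = g), nrow(geom))))
}

osmolyte_influx_vec <- function(rho, g) {
  if (length(g) != length(rho)) {
    abort("secretion profile and grid lengths differ.")
  }
  if (any(g < 0)) abort("`g` must be non-negative.")
  integrand <- rho * g
  n <- length(rho)
  c(0, cumsum(diff(rho) * (integrand[-1] + integrand[-n]) / 2))
}

#' Regularized start state at the central vein
#'
#' The boundary condition `w(rho0) = 0` makes the concentration
#' `c = G/(rho w)` a 0/0 limit at the central vein. Its finite limit `c*`
#' solves the self-consistency condition `c* = g / (kappa A (RT (c* - c0)
#' - p0))`, i.e. the quadratic `kappa A RT c*^2 - kappa A (RT c0 + p0) c*
#' - g = 0`, whose positive root always exceeds `c0 + p0/(RT)` when
#' `g > 0`, so the initial water influx is strictly outward. The state is
#' then advanced analytically to `rho0 + delta` by the leading-order
#' series `u = rho0 kappa A (RT (c* - c0) - p0) delta`.
#'
#' @param p0 Trial central pressure (Pa).
#' @param geom A [radial_geometry()].
#' @param params A [bile_params()].
#' @param delta Regularization offset (m); default `1e-3 (L - rho0)`.
#' @param g0 Effective local secretion rate at the centre (mol/(m^3 s));
#'   defaults to the profile value. The solver passes the slope of the
#'   discretized influx integral here so that the start state lies exactly
#'   on the quasi-steady manifold of the integrated system.
#' @return A list with `c_star` (mol/m^3), `u` (= rho w, m^2/s), `p` (Pa),
#'   `slope` (du/drho at the centre) and `delta`.
#' @export
central_start_state <- function(p0, geom, params, delta = NULL, g0 = NULL) {
  stopifnot(inherits(geom, "radial_geometry"),
            inherits(params, "bile_params"))
  check_number(p0, "p0")
  si <- geom_si(geom)
  delta <- delta %||% (1e-3 * (si$L - si$rho0))
  RT <- params$R * params$T
  A0 <- si$A[1]
  g0 <- g0 %||% g_profile(params, nrow(geom))[1]
  kA <- params$kappa * A0

  # kA RT c^2 - kA (RT c0 + p0) c - g0 = 0, positive root
  a <- kA * RT
  b <- -kA * (RT * params$c0 + p0)
  disc <- b^2 + 4 * a * g0
  c_star <- if (a > 0 && disc >= 0) (-b + sqrt(disc)) / (2 * a) else NA_real_
  if (!is.finite(c_star) || c_star <= 0) {
    warn("no positive root for the central concentration; falling back to c0 + eps.")
    c_star <- params$c0 + 1e-9
  }

  slope <- si$rho0 * kA * (RT * (c_star - params$c0) - p0)
  K0 <- darcy_resistance_vec(geom, params$mu)[1]
  list(c_star = c_star,
       u = slope * delta,
       p = p0 - K0 * slope * delta^2 / (2 * si$rho0),
       slope = slope,
       delta = delta)
}

#' Integrate the reduced system outward from the central vein
#'
#' Integrates the eliminated two-state system — equivalent to
#' `u' = rho kappa A (RT (G/u - c0) - p)` with `u = rho w`, together with
#' Darcy's law `p' = -K u / rho` — from the regularized start at
#' `rho0 + delta` to the lobule boundary `L` with an adaptive
#' stiff-capable integrator (`deSolve::lsoda`), returning the trajectory
#' on the geometry grid. Internally the integration states are the
#' concentration `c = G/u` and the pressure `p`: both are O(c0) and O(pL)
#' respectively, which keeps the stiff start layer (where `u` spans many
#' orders of magnitude) well-scaled; `u` is recovered from the osmolyte
#' balance `u = G/c`. The impermeable (`kappa = 0`) and secretion-free
#' (`g = 0`) limits are handled exactly: no flow, uniform pressure.
#'
#' @inheritParams central_start_state
#' @param rtol,atol_p Relative tolerance and pressure absolute tolerance
#'   of the integrator (the concentration uses `rtol` with an absolute
#'   floor scaled to `c0`).
#' @return A list with vectors `rho` (m), `u`, `p`, `c`, `G`, the
#'   terminal pressure `p_end`, `c_star` and the start-state information.
#' @export
integrate_outward <- function(p0, geom, params, delta = NULL,
                              rtol = 1e-8, atol_p = 1e-8) {
  stopifnot(inherits(geom, "radial_geometry"),
            inherits(params, "bile_params"))
  si <- geom_si(geom)
  n <- length(si$rho)
  g <- g_profile(params, n)
  G <- osmolyte_influx_vec(si$rho, g)

  if (params$kappa == 0 || max(g) == 0) {
    # impermeable membrane or no secretion: no flow, uniform pressure
    return(list(rho = si$rho, u = rep(0, n), p = rep(p0, n),
                c = rep(NA_real_, n), G = G, p_end = p0, c_star = NA_real_,
                start = list(delta = 0), n_rhs = 0L))
  }
  if (G[2] <= 0) {
    abort("secretion vanishes near the central vein; the concentration limit is undefined there.")
  }

  # effective centre secretion from the discrete G so the start state sits
  # on the quasi-steady manifold of the interpolated system (c ~ G/u)
  g_eff <- (G[2] - G[1]) / (si$rho[2] - si$rho[1]) / si$rho0
  start <- central_start_state(p0, geom, params, delta = delta, g0 = g_eff)
  RT <- params$R * params$T
  c0 <- params$c0
  kappa <- params$kappa
  A_f <- approxfun(si$rho, si$A, rule = 2)
  K_f <- approxfun(si$rho, darcy_resistance_vec(geom, params$mu), rule = 2)
  G_f <- approxfun(si$rho, G, rule = 2)
  g_f <- approxfun(si$rho, g, rule = 2)

  n_rhs <- 0L
  # states (c, p); c' follows from differentiating c = G/u:
  #   c' = (rho c / G) (g - kappa A c (RT (c - c0) - p))
  rhs <- function(rho, y, parms) {
    n_rhs <<- n_rhs + 1L
    cc <- y[1]; p <- y[2]
    Gr <- G_f(rho)
    dc <- (rho * cc / Gr) *
      (g_f(rho) - kappa * A_f(rho) * cc * (RT * (cc - c0) - p))
    dp <- -K_f(rho) * Gr / (cc * rho)
    list(c(dc, dp))
  }

  a <- si$rho0 + start$delta
  gap <- 1e-9 * (si$L - si$rho0)   # avoid output times coinciding with a
  keep <- si$rho > a + gap
  times <- c(a, si$rho[keep])
  sol <- deSolve::lsoda(
    y = c(c = start$c_star, p = start$p), times = times, func = rhs,
    rtol = rtol, atol = c(rtol * c0, atol_p), maxsteps = 100000L)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    abort(sprintf("outward integration failed for p0 = %g Pa.", p0))
  }

  u_out <- numeric(n); p_out <- numeric(n); c_out <- rep(NA_real_, n)
  # inside the regularization offset: series values
  u_out[!keep] <- start$slope * pmax(si$rho[!keep] - si$rho0, 0)
  p_out[!keep] <- p0
  c_out[!keep] <- start$c_star
  c_out[keep] <- sol[-1, "c"]
  p_out[keep] <- sol[-1, "p"]
  u_out[keep] <- G[keep] / c_out[keep]

  list(rho = si$rho, u = u_out, p = p_out, c = c_out, G = G,
       p_end = p_out[n], c_star = start$c_star, start = start,
       n_rhs = n_rhs)
}
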