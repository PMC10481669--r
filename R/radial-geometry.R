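#' Radial geometry profiles of the canalicular network
#'
#' A `radial_geometry` is a tibble with one row per radial grid point of the
#' lobule annulus `rho0 .. L` and columns
#' \describe{
#'   \item{rho_um}{radial coordinate (um), strictly increasing, first value
#'     `rho0`, last value `L`}
#'   \item{A_per_um}{apical surface density (1/um): apical membrane area per
#'     tissue volume}
#'   \item{eps_bc}{canalicular volume fraction (dimensionless, in (0, 1))}
#'   \item{r_bc_um}{effective canalicular radius (um)}
#'   \item{f}{free lumen ratio / focusing function (dimensionless)}
#' }
#' with attributes `tau` (tortuosity), `rho0_um` and `L_um`.
#'
#' @param rho_um,A_per_um,eps_bc,r_bc_um,f Profile vectors (equal length).
#' @param tau Tortuosity (>= 1), ratio of true canalicular path length to
#'   straight-line length; enters the Darcy resistance as `tau^2`.
#' @return A tibble of subclass `radial_geometry`.
#' @seealso [gen_radial_geometry()], [darcy_resistance()], [solve_pressure()]
#' @export
radial_geometry <- function(rho_um, A_per_um, eps_bc, r_bc_um, f, tau = 1.8) {
  n <- length(rho_um)
  lens <- c(length(A_per_um), length(eps_bc), length(r_bc_um), length(f))
  if (any(lens != n)) abort("all geometry profiles must have equal length.")
  if (n < 3L) abort("a radial geometry needs at least 3 grid points.")
  if (any(diff(rho_um) <= 0)) {
    abort("`rho_um` must be strictly increasing (non-monotone grid).")
  }
  bad <- function(v, nm, hi = Inf) {
    i <- which(!is.finite(v) | v <= 0 | v >= hi)
    if (length(i)) {
      abort(sprintf("`%s` must be finite and in (0, %s); offending grid point %d (rho = %g um).",
                    nm, format(hi), i[1], rho_um[i[1]]))
    }
  }
  bad(A_per_um, "A_per_um"); bad(eps_bc, "eps_bc", hi = 1)
  bad(r_bc_um, "r_bc_um"); bad(f, "f")
  check_number(tau, "tau", 1)
  out <- tibble(rho_um = as.numeric(rho_um), A_per_um = as.numeric(A_per_um),
                eps_bc = as.numeric(eps_bc), r_bc_um = as.numeric(r_bc_um),
                f = as.numeric(f))
  structure(out,
            class = c("radial_geometry", class(out)),
            tau = tau, rho0_um = rho_um[1], L_um = rho_um[n])
}

geom_tau <- function(geom) attr(geom, "tau")
geom_rho0_um <- function(geom) attr(geom, "rho0_um")
geom_L_um <- function(geom) attr(geom, "L_um")

#' Generate analytic radial geometry profiles for a synthetic lobule
#'
#' Synthesizes the radial profiles the pressure model consumes: apical
#' surface density `A(rho)`, canalicular volume fraction `eps_bc(rho)`,
#' effective canalicular radius `r_bc(rho)` and free-lumen ratio `f(rho)`
#' on a uniform grid over the annulus `rho0 .. L`. The volume fraction
#' declines mildly from pericentral to periportal (a few percent of tissue
#' volume throughout); the radius profile is the configured baseline with a
#' mild pericentral enrichment, scaled by the regime's dilation factor; `A`
#' is tied to the other two by the cylinder-bundle identity
#' `A = 2 eps_bc / r_bc` (a bundle of cylinders of radius r at volume
#' fraction eps has surface density 2 eps / r); `f` is the constant 0.28
#' and `tau = 1.8`.
#'
#' @param config A [synthetic_config()].
#' @param n_grid Number of radial grid points (default 101).
#' @return A [radial_geometry()] tibble.
#' @examples
#' geom <- gen_radial_geometry(synthetic_config("control", seed = 1))
#' attr(geom, "L_um")
#' @export
gen_radial_geometry <- function(config, n_grid = 101L) {
  stopifnot(inherits(config, "synthetic_config"))
  n_grid <- check_count(n_grid, "n_grid", 3L)
  rho0 <- config$cv_radius_um
  L <- config$lobule_radius_um
  rho <- seq(rho0, L, length.out = n_grid)
  t <- (rho - rho0) / (L - rho0)
  # volume fraction: ~5 % pericentral declining to ~3.5 % periportal
  eps <- 0.05 - 0.015 * t
  # radius: baseline with a 10 % pericentral enrichment, regime dilation
  r_bc <- config$baseline_radius_um * (1 + 0.1 * (1 - t)) *
    config$radius_dilation_factor
  A <- 2 * eps / r_bc
  f <- rep(0.28, n_grid)
  radial_geometry(rho, A, eps, r_bc, f, tau = 1.8)
}
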