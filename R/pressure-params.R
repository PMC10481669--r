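#' Physical parameters and boundary data of the bile-pressure model
#'
#' Collects the physical constants and boundary conditions of the
#' osmotic/Darcy lobule model. Defaults are the literature values used for
#' normal control livers: water permeability `kappa = 4.7e-10` m/(Pa s),
#' hepatocyte osmolyte concentration `c0 = 300` mmol/l (= mol/m^3), bile
#' viscosity `mu = 9.2e-4` Pa s, and a bile-duct (periportal boundary)
#' pressure `pL` of 1,000 Pa; for PSC-like runs `pL = 2,000` Pa reflects the
#' pressure built up behind bile-duct strictures. Temperature enters only
#' through `R*T`; body temperature 310 K is the default.
#'
#' @param kappa Water permeability of the apical membrane (m/(Pa s)).
#' @param R Gas constant (J/(mol K)).
#' @param T Temperature (K).
#' @param c0 Osmolyte concentration of the hepatocytes (mol/m^3).
#' @param mu Bile viscosity (Pa s).
#' @param pL Hydrostatic pressure at the periportal boundary (Pa).
#' @param g Osmolyte secretion rate (mol/(m^3 s)): a single number for a
#'   spatially constant rate, or a numeric vector on the geometry grid.
#' @return An object of class `bile_params`.
#' @examples
#' bile_params(g = 0.3)
#' bile_params(pL = 2000, g = 0.3)  # PSC-like boundary pressure
#' @export
bile_params <- function(kappa = 4.7e-10, R = .R_GAS, T = 310, c0 = 300,
                        mu = 9.2e-4, pL = 1000, g = 0.3) {
  check_number(kappa, "kappa", 0)
  check_number(R, "R", 0, strict_lower = TRUE)
  check_number(T, "T", 0, strict_lower = TRUE)
  check_number(c0, "c0", 0, strict_lower = TRUE)
  check_number(mu, "mu", 0, strict_lower = TRUE)
  check_number(pL, "pL", 0)
  if (!is.numeric(g) || any(!is.finite(g)) || any(g < 0)) {
    abort("`g` must be non-negative and finite (scalar or grid vector).")
  }
  structure(list(kappa = kappa, R = R, T = T, c0 = c0, mu = mu, pL = pL,
                 g = g),
            class = "bile_params")
}

#' @export
print.bile_params <- function(x, ...) {
  cat(sprintf(
    "<bile_params> kappa=%.3g m/(Pa s), c0=%g mol/m^3, mu=%.3g Pa s, pL=%g Pa, RT=%.4g J/mol\n",
    x$kappa, x$c0, x$mu, x$pL, x$R * x$T))
  cat(sprintf("  g: %s mol/(m^3 s)\n",
              if (length(x$g) == 1) format(x$g) else
                sprintf("profile on %d points", length(x$g))))
  invisible(x)
}

# expand g to the geometry grid
g_profile <- function(params, n) {
  g <- params$g
  if (length(g) == 1L) rep(g, n)
  else if (length(g) == n) g
  else abort(sprintf("secretion profile has %d values but the grid has %d.",
                     length(g), n))
}
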