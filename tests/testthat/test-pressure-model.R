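flat_geom <- function(eps = 0.1, r_um = 0.5, f = 0.28, tau = 1.8,
                      rho0 = 50, L = 512, n = 101) {
  rho <- seq(rho0, L, length.out = n)
  radial_geometry(rho, rep(2 * eps / r_um, n), rep(eps, n), rep(r_um, n),
                  rep(f, n), tau = tau)
}

test_that("Darcy resistance follows the porous-media closure", {
  g <- flat_geom()
  K <- darcy_resistance(g, mu = 9.2e-4)$K_pa_s_m2
  # hand evaluation: 8 mu tau^2 / (eps r^2 f)
  expect_equal(K, rep(8 * 9.2e-4 * 1.8^2 / (0.1 * (0.5e-6)^2 * 0.28), 101),
               tolerance = 1e-15)
  expect_equal(K[1], 3.40662857142857e12, tolerance = 1e-14)

  # proportionalities: f halves K; tau enters squared
  g2 <- flat_geom(f = 0.56)
  expect_equal(darcy_resistance(g2)$K_pa_s_m2, K / 2, tolerance = 1e-15)
  g_t1 <- flat_geom(tau = 1); g_t2 <- flat_geom(tau = 2)
  expect_equal(darcy_resistance(g_t2)$K_pa_s_m2 /
                 darcy_resistance(g_t1)$K_pa_s_m2,
               rep(4, 101), tolerance = 1e-15)
})

test_that("the cumulative osmolyte influx integral matches closed forms", {
  g <- flat_geom()
  rho <- g$rho_um * 1e-6
  expect_equal(osmolyte_influx(g, 0)$G, rep(0, 101))

  # constant g: the integrand is linear in rho, so trapezoid is exact
  G <- osmolyte_influx(g, 0.5)$G
  expect_equal(G, 0.5 * (rho^2 - rho[1]^2) / 2, tolerance = 1e-12)
  expect_true(all(diff(G) > 0))
  expect_equal(G[1], 0)

  # localized secretion bump: G flat before, flat after
  gb <- rep(0, 101); gb[40:60] <- 1
  Gb <- osmolyte_influx(g, gb)$G
  expect_equal(Gb[1:38], rep(0, 38))
  expect_equal(diff(Gb[62:101]), rep(0, 39))
  expect_gt(Gb[101], 0)

  expect_error(osmolyte_influx(g, rep(1, 50)), "grid")
})

test_that("the central concentration limit solves its quadratic", {
  g <- flat_geom()
  p <- bile_params(g = 0.3)
  st <- central_start_state(1500, g, p)
  RT <- p$R * p$T
  kA <- p$kappa * g$A_per_um[1] * 1e6
  resid <- kA * RT * st$c_star^2 - kA * (RT * p$c0 + 1500) * st$c_star - 0.3
  expect_lt(abs(resid) / (kA * RT * st$c_star^2), 1e-10)

  # u(rho0 + delta) -> 0 with delta
  st_small <- central_start_state(1500, g, p, delta = 1e-12)
  expect_lt(abs(st_small$u), abs(st$u))
  expect_equal(st_small$u / 1e-12, st$slope, tolerance = 1e-9)

  # c* grows monotonically with the secretion rate
  cs <- vapply(c(0.01, 0.1, 1, 10, 100),
               function(gg) central_start_state(
                 1500, g, bile_params(g = gg))$c_star, numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("the impermeable and secretion-free limits carry no flow", {
  g <- flat_geom()
  tr <- integrate_outward(1234, g, bile_params(kappa = 0, g = 0.3))
  expect_equal(tr$u, rep(0, 101))
  expect_equal(tr$p, rep(1234, 101))

  sol0 <- solve_pressure(g, bile_params(kappa = 0, g = 0.3, pL = 1000))
  expect_equal(sol0$p_pa, rep(1000, 101))
  expect_equal(sol0$w_m_s, rep(0, 101))

  solg <- solve_pressure(g, bile_params(g = 0, pL = 800))
  expect_equal(solg$p_pa, rep(800, 101))
})

test_that("the solved trajectory conserves water and osmolytes", {
  g <- flat_geom(n = 801)
  p <- bile_params(g = 0.3)
  sol <- solve_pressure(g, p)
  rho <- g$rho_um * 1e-6
  u <- sol$w_m_s * rho

  # osmolyte balance: rho c w = G at every grid point past the start layer
  G <- osmolyte_influx(g, 0.3)$G
  i <- 5:801
  expect_lt(max(abs(u[i] * sol$c_mol_m3[i] - G[i]) / G[801]), 1e-5)

  # water balance: L w(L) - rho0 w(rho0) = int rho kappa A (RT(c - c0) - p)
  RT <- p$R * p$T
  integrand <- rho * p$kappa * (g$A_per_um * 1e6) *
    (RT * (sol$c_mol_m3 - p$c0) - sol$p_pa)
  lhs <- u[801]
  rhs <- sum(diff(rho) * (integrand[-1] + integrand[-801]) / 2)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-5)
})

test_that("shooting satisfies both boundary conditions", {
  g <- flat_geom()
  sol <- solve_pressure(g, bile_params(g = 0.5, pL = 1000), tol = 0.1)
  expect_lt(abs(sol$p_pa[101] - 1000), 0.1)
  expect_lt(abs(sol$w_m_s[1]) * g$rho_um[1] * 1e-6, 1e-12)
  expect_lt(attr(sol, "residual_pa"), 0.1)
  expect_true(all(sol$c_mol_m3 > 0))
  # pressure decreases outward under positive secretion
  expect_true(all(diff(sol$p_pa) < 0))
})

test_that("integration accuracy is stable under tolerance refinement", {
  g <- flat_geom()
  p <- bile_params(g = 0.3)
  t1 <- integrate_outward(1500, g, p, rtol = 1e-8)
  t2 <- integrate_outward(1500, g, p, rtol = 1e-10)
  expect_lt(abs(t1$p_end - t2$p_end), 0.05)
})

test_that("canalicular velocity is the bulk velocity over the volume fraction", {
  g <- flat_geom(eps = 0.5)
  sol <- solve_pressure(g, bile_params(g = 0.3))
  wc <- canalicular_velocity(sol, g)
  expect_equal(wc$wc_m_s, 2 * sol$w_m_s, tolerance = 1e-14)
  expect_equal(sol$wc_m_s * g$eps_bc - sol$w_m_s, rep(0, 101),
               tolerance = 1e-20)
})

test_that("zone pressure summaries reduce the profile correctly", {
  g <- flat_geom()
  sol <- solve_pressure(g, bile_params(g = 0.4))

  # constant profile: every zone median equals it, elevation 0
  solc <- sol
  solc$p_pa <- rep(1000, 101)
  zc <- zone_pressure_summary(solc)
  expect_equal(zc$zones$median_pa, rep(1000, 11))
  expect_equal(zc$elevation_pa, 0)

  # strictly decreasing profile: zone medians strictly decreasing
  zs <- zone_pressure_summary(sol)
  expect_true(all(diff(zs$zones$median_pa) < 0))
  expect_gt(zs$elevation_pa, 0)

  # linear profile: brute-force per-zone medians on the discretized grid
  soll <- sol
  soll$p_pa <- seq(2000, 1000, length.out = 101)
  zl <- zone_pressure_summary(soll)
  t <- (soll$rho_um - 50) / (512 - 50)
  zone <- pmin(floor(t * 11), 10)
  ref <- vapply(0:10, function(z) median(soll$p_pa[zone == z]), numeric(1))
  expect_equal(zl$zones$median_pa, ref)
  expect_equal(zl$elevation_pa, ref[1] - ref[11])
  expect_equal(zl$elevation_pa, 1000 * 10 / 11, tolerance = 0.01)
})

test_that("secretion calibration inverts the forward model", {
  g <- flat_geom()
  p <- bile_params(pL = 1000)
  expect_error(calibrate_secretion(g, p, 900), "exceed")
  expect_error(calibrate_secretion(g, bile_params(kappa = 0), 1500), "kappa")

  cal <- calibrate_secretion(g, p, 1500, tol_rel = 1e-3)
  expect_lt(abs(cal$axis_median_pa - 1500) / 1500, 1e-3)
  # a higher target needs more secretion
  cal2 <- calibrate_secretion(g, p, 2200, tol_rel = 1e-3)
  expect_gt(cal2$g, cal$g)
})

test_that("geometry validation names the offending grid point", {
  rho <- seq(50, 512, length.out = 11)
  expect_error(radial_geometry(rho, rep(1, 11), c(0.1, rep(0.1, 9), 0),
                               rep(0.5, 11), rep(0.28, 11)),
               "grid point")
  expect_error(radial_geometry(rev(rho), rep(1, 11), rep(0.1, 11),
                               rep(0.5, 11), rep(0.28, 11)),
               "increasing")
})
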