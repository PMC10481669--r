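test_that("regime defaults reproduce the cohort lobule radii", {
  expect_equal(synthetic_config("control", seed = 1)$lobule_radius_um, 512)
  expect_equal(synthetic_config("psc", seed = 1)$lobule_radius_um, 968)
  g_c <- gen_radial_geometry(synthetic_config("control", seed = 1))
  g_p <- gen_radial_geometry(synthetic_config("psc", seed = 1))
  expect_equal(attr(g_c, "L_um"), 512)
  expect_equal(attr(g_p, "L_um"), 968)
  expect_equal(attr(g_c, "tau"), 1.8)
  expect_true(all(g_c$f == 0.28))
})

test_that("configuration validation rejects degenerate annuli and bad knobs", {
  expect_error(synthetic_config("control", seed = 1, lobule_radius_um = 40),
               "exceed")
  expect_error(synthetic_config("control", seed = 1, rosette_fraction = 1.5),
               "rosette_fraction")
  expect_error(synthetic_config("control", seed = 1,
                                rosette_radius_range_um = c(2, 8)),
               "within")
  expect_error(synthetic_config("control", seed = 1, nodes_per_zone = 1),
               "nodes_per_zone")
})

test_that("analytic profiles satisfy the cylinder-bundle closure A = 2 eps / r", {
  for (regime in c("control", "psc")) {
    g <- gen_radial_geometry(synthetic_config(regime, seed = 3))
    expect_equal(g$A_per_um * g$r_bc_um / (2 * g$eps_bc),
                 rep(1, nrow(g)), tolerance = 1e-12)
    expect_true(all(g$eps_bc > 0 & g$eps_bc <= 0.2))
  }
})

test_that("paired regimes with one seed give dilated radii and a larger lobule", {
  g_c <- gen_radial_geometry(synthetic_config("control", seed = 7))
  g_p <- gen_radial_geometry(synthetic_config("psc", seed = 7))
  expect_gt(attr(g_p, "L_um"), attr(g_c, "L_um"))
  # same normalized grid position -> strictly dilated radius profile
  expect_true(all(g_p$r_bc_um > g_c$r_bc_um))

  cfg_c <- synthetic_config("control", seed = 7, dropout_fraction = 0)
  cfg_p <- synthetic_config("psc", seed = 7, dropout_fraction = 0)
  zs_c <- zone_statistics(assign_zones(gen_network(cfg_c)))
  zs_p <- zone_statistics(assign_zones(gen_network(cfg_p)))
  expect_true(all(zs_p$mean_radius_um > zs_c$mean_radius_um))
})

test_that("network generation is seed-deterministic", {
  cfg <- synthetic_config("psc", seed = 11)
  expect_identical(gen_network(cfg), gen_network(cfg))
  # and different seeds differ
  cfg2 <- synthetic_config("psc", seed = 12)
  expect_false(identical(gen_network(cfg)$edges, gen_network(cfg2)$edges))
})

test_that("rosette insertion respects its probability", {
  # none requested -> all radii stay below the rosette range
  n0 <- gen_network(synthetic_config("control", seed = 5,
                                     rosette_fraction = 0))
  expect_lt(max(n0$edges$radius_um), 3)

  # requested fraction recovered within the 99% binomial interval;
  # each insertion splits its host edge, adding two baseline edges
  cfg <- synthetic_config("control", seed = 2, rosette_fraction = 0.05,
                          nodes_per_zone = 300L, dropout_fraction = 0)
  net <- gen_network(cfg)
  k <- sum(net$edges$radius_um >= 3)
  m <- nrow(net$edges) - 2L * k
  ci <- qbinom(c(0.005, 0.995), m, 0.05)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
  expect_true(all(net$edges$radius_um[net$edges$radius_um >= 3] <= 8))
})

test_that("section tables carry the configured rosette count and marker extremes", {
  cfg0 <- synthetic_config("psc", seed = 8, sox9_positive_fraction = 0,
                           panck_positive_fraction = 0)
  s0 <- gen_section_table(cfg0)
  expect_equal(dplyr::n_distinct(s0$lumen_id),
               cfg0$n_rosettes_2d + cfg0$n_lumina_2d)
  expect_equal(count_rosettes_2d(s0)$n_rosettes, cfg0$n_rosettes_2d)
  m0 <- classify_rosette_markers(s0)
  expect_equal(m0$sox9_fraction, 0)
  expect_equal(m0$panck_fraction, 0)

  cfg1 <- synthetic_config("psc", seed = 8, sox9_positive_fraction = 1)
  m1 <- classify_rosette_markers(gen_section_table(cfg1))
  expect_equal(m1$sox9_fraction, 1)
})

test_that("marker-positive fractions are recovered within binomial sampling error", {
  cfg <- synthetic_config("psc", seed = 21, n_rosettes_2d = 500L,
                          sox9_positive_fraction = 0.28)
  m <- classify_rosette_markers(gen_section_table(cfg))
  expect_equal(m$n_rosettes, 500L)
  ci <- qbinom(c(0.005, 0.995), 500, 0.28) / 500
  expect_gte(m$sox9_fraction, ci[1])
  expect_lte(m$sox9_fraction, ci[2])
})

test_that("network-to-geometry reduction matches closed forms on one edge", {
  # single edge of radius r and length l in a known shell
  nodes <- tibble::tibble(id = 1:2, x_um = c(100, 120), y_um = 0,
                          z_um = c(0, 0))
  net <- canalicular_network(
    nodes, tibble::tibble(from = 1, to = 2, radius_um = 2),
    landmarks = list(cv_center_um = c(0, 0), cv_radius_um = 50,
                     pv_radius_um = 512),
    tissue_depth_um = 100, sector_angle_rad = 0.2)
  suppressWarnings(geom <- network_to_geometry(net, n_shells = 11L))
  breaks <- seq(50, 512, length.out = 12)
  shell <- findInterval(110, breaks)
  v <- 0.1 * (breaks[shell + 1]^2 - breaks[shell]^2) * 100
  expect_equal(geom$eps_bc[shell], pi * 2^2 * 20 / v, tolerance = 1e-12)
  expect_equal(geom$A_per_um[shell], 2 * pi * 2 * 20 / v, tolerance = 1e-12)
  expect_equal(geom$r_bc_um[shell], 2, tolerance = 1e-12)
})

test_that("network-to-geometry agrees with brute-force shell summation", {
  net <- gen_network(synthetic_config("psc", seed = 13))
  geom <- network_to_geometry(net)
  ref <- brute_network_geometry(net)
  expect_equal(geom$eps_bc, ref$eps, tolerance = 1e-12)
  expect_equal(geom$A_per_um, ref$A, tolerance = 1e-12)
  expect_equal(geom$r_bc_um, ref$r_bc, tolerance = 1e-12)

  # uniform radii collapse the per-shell mean radius to the common value
  netu <- net
  netu$edges$radius_um <- 0.7
  geomu <- network_to_geometry(netu)
  expect_equal(geomu$r_bc_um, rep(0.7, 11), tolerance = 1e-12)
})

test_that("empty shells are interpolated with a warning", {
  nodes <- tibble::tibble(id = 1:4, x_um = c(60, 80, 480, 500), y_um = 0,
                          z_um = 0)
  edges <- tibble::tibble(from = c(1, 3), to = c(2, 4),
                          radius_um = c(0.5, 0.6))
  net <- canalicular_network(
    nodes, edges,
    landmarks = list(cv_center_um = c(0, 0), cv_radius_um = 50,
                     pv_radius_um = 512),
    tissue_depth_um = 100, sector_angle_rad = 0.2)
  expect_warning(geom <- network_to_geometry(net), "interpolation")
  expect_true(all(is.finite(geom$eps_bc) & geom$eps_bc > 0))
})
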