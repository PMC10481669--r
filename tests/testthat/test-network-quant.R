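test_that("zone assignment bins the normalized CV->PV coordinate", {
  zn <- assign_zones(toy_network())
  z <- setNames(zn$nodes$zone, zn$nodes$id)
  expect_equal(unname(z["1"]), 0L)    # on the CV edge
  expect_equal(unname(z["10"]), 10L)  # on the PV edge (clamped end bin)
  expect_equal(unname(z["5"]), 5L)    # exactly midway: floor(0.5 * 11) = 5
  expect_equal(unname(z["2"]), 1L)
  # edges are assigned by midpoint
  e <- zn$edges
  expect_equal(e$zone[e$from == 1 & e$to == 2], 0L)  # midpoint x = 15
  expect_equal(e$zone[e$from == 9 & e$to == 10], 10L)
})

test_that("all six zone statistics match brute-force enumeration on the toy network", {
  zn <- assign_zones(toy_network())
  got <- suppressWarnings(zone_statistics(zn))
  ref <- suppressWarnings(brute_zone_stats(toy_network()))
  for (col in c("mean_radius_um", "volume_fraction_pct",
                "surface_to_volume_um2_mm3", "connectivity",
                "crossings_per_mm2", "junctions_per_um",
                "network_volume_um3")) {
    expect_equal(got[[col]], ref[[col]], tolerance = 1e-10, label = col)
  }
})

test_that("zone statistics match brute force on a generated network", {
  net <- gen_network(synthetic_config("psc", seed = 17, nodes_per_zone = 30L))
  got <- suppressWarnings(zone_statistics(assign_zones(net)))
  ref <- suppressWarnings(brute_zone_stats(net))
  expect_equal(got$connectivity, ref$connectivity)
  expect_equal(got$crossings_per_mm2, ref$crossings_per_mm2,
               tolerance = 1e-10)
  expect_equal(got$mean_radius_um, ref$mean_radius_um, tolerance = 1e-10)
  expect_equal(got$junctions_per_um, ref$junctions_per_um,
               tolerance = 1e-10)
})

test_that("per-zone network volumes sum to the whole-network volume", {
  net <- gen_network(synthetic_config("psc", seed = 23))
  zs <- suppressWarnings(zone_statistics(assign_zones(net)))
  total <- sum(pi * net$edges$radius_um^2 * net$edges$length_um)
  expect_equal(sum(zs$network_volume_um3), total, tolerance = 1e-12)
})

test_that("zone statistics are invariant under relabelling and rotation about the CV axis", {
  net <- gen_network(synthetic_config("control", seed = 31,
                                      nodes_per_zone = 20L))
  base <- suppressWarnings(zone_statistics(assign_zones(net)))

  # rigid rotation about the CV (z) axis
  th <- 0.7
  rot <- net
  rot$nodes <- dplyr::mutate(net$nodes,
    x0 = .data$x_um, y0 = .data$y_um,
    x_um = cos(th) * .data$x0 - sin(th) * .data$y0,
    y_um = sin(th) * .data$x0 + cos(th) * .data$y0)
  rot$nodes <- rot$nodes[, c("id", "x_um", "y_um", "z_um")]
  rot <- canalicular_network(rot$nodes, net$edges[, c("from", "to", "radius_um")],
                             net$landmarks, net$tissue_depth_um,
                             net$sector_angle_rad)
  rotated <- suppressWarnings(zone_statistics(assign_zones(rot)))
  expect_equal(rotated$mean_radius_um, base$mean_radius_um,
               tolerance = 1e-10)
  expect_equal(rotated$connectivity, base$connectivity)

  # node relabelling (permuted ids)
  perm <- sample(seq_len(nrow(net$nodes)))
  map <- setNames(perm, net$nodes$id)
  relab <- canalicular_network(
    dplyr::mutate(net$nodes, id = unname(map[as.character(.data$id)])),
    dplyr::mutate(net$edges[, c("from", "to", "radius_um")],
                  from = unname(map[as.character(.data$from)]),
                  to = unname(map[as.character(.data$to)])),
    net$landmarks, net$tissue_depth_um, net$sector_angle_rad)
  relabelled <- suppressWarnings(zone_statistics(assign_zones(relab)))
  expect_equal(relabelled$mean_radius_um, base$mean_radius_um,
               tolerance = 1e-10)
  expect_equal(relabelled$connectivity, base$connectivity)
})

test_that("connectivity counts disjoint pieces per zone", {
  # two disjoint 1-edge segments placed in one zone -> connectivity 1/2
  nodes <- tibble::tibble(id = 1:4, x_um = c(60, 64, 60, 64),
                          y_um = c(0, 0, 10, 10), z_um = 0)
  edges <- tibble::tibble(from = c(1, 3), to = c(2, 4), radius_um = 0.5)
  net <- canalicular_network(
    nodes, edges,
    landmarks = list(cv_center_um = c(0, 0), cv_radius_um = 50,
                     pv_radius_um = 160),
    tissue_depth_um = 40, sector_angle_rad = pi / 2)
  zs <- suppressWarnings(zone_statistics(assign_zones(net)))
  expect_equal(zs$connectivity[zs$zone == 1], 0.5)
  # a single connected piece -> connectivity 1
  net1 <- canalicular_network(
    nodes, tibble::tibble(from = c(1, 2, 3), to = c(2, 3, 4),
                          radius_um = 0.5),
    landmarks = net$landmarks, tissue_depth_um = 40,
    sector_angle_rad = pi / 2)
  zs1 <- suppressWarnings(zone_statistics(assign_zones(net1)))
  expect_equal(zs1$connectivity[zs1$zone == 1], 1)
})

test_that("lobule radius summaries use per-sample medians", {
  expect_equal(lobule_radius(500)$per_sample$median_radius_um, 500)
  expect_equal(lobule_radius(c(400, 500, 600))$per_sample$median_radius_um,
               500)
  # even count: mean of the middle pair
  expect_equal(lobule_radius(c(400, 500, 600, 1000))$per_sample$median_radius_um,
               550)
  cohort <- lobule_radius(tibble::tibble(
    sample = rep(c("a", "b"), each = 3),
    distance_um = c(400, 500, 600, 900, 1000, 1100)))
  expect_equal(cohort$per_sample$median_radius_um, c(500, 1000))
  expect_equal(cohort$cohort_mean_um, 750)
  expect_error(lobule_radius(numeric(0)), "no lobule")
  expect_error(lobule_radius(c(500, -1)), "positive")
})

test_that("network validation rejects malformed graphs", {
  nodes <- tibble::tibble(id = 1:2, x_um = c(60, 70), y_um = 0, z_um = 0)
  lms <- list(cv_center_um = c(0, 0), cv_radius_um = 50, pv_radius_um = 160)
  expect_error(canalicular_network(
    nodes, tibble::tibble(from = 1, to = 1, radius_um = 0.5), lms, 40),
    "self-loop")
  expect_error(canalicular_network(
    nodes, tibble::tibble(from = 1, to = 2, radius_um = -0.5), lms, 40),
    "positive")
  expect_error(canalicular_network(
    nodes, tibble::tibble(from = 1, to = 3, radius_um = 0.5), lms, 40),
    "unknown node")
  expect_error(canalicular_network(
    nodes, tibble::tibble(from = 1, to = 2, radius_um = 0.5),
    list(cv_center_um = c(0, 0), cv_radius_um = 50, pv_radius_um = 50), 40),
    "coincide")
})
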