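# Hand-built fixtures shared across test files. All constructed in code;
# coordinates in micrometres.

# A 12-edge toy network spanning the annulus rho0 = 10 .. L = 120 um.
# Nodes sit on the x axis (y = z = 0 unless stated), so the CV->PV
# coordinate of a node is (x - 10) / 110.
toy_network <- function() {
  nodes <- tibble::tribble(
    ~id, ~x_um, ~y_um, ~z_um,
    1, 10, 0, 0,     # on the CV edge          -> zone 0
    2, 20, 0, 0,     # t = 0.0909              -> zone 1
    3, 30, 0, 0,     # t = 0.1818              -> zone 2
    4, 30, 5, 0,     # branch partner of 3
    5, 65, 0, 0,     # t = 0.5                 -> zone 5
    6, 70, 0, 0,
    7, 70, 8, 0,     # disjoint pair in mid zones
    8, 76, 8, 0,
    9, 110, 0, 0,    # t = 0.909               -> zone 10
    10, 120, 0, 0,   # on the PV edge          -> zone 10
    11, 118, 6, 0,   # second component, zone 10
    12, 118, 10, 0
  )
  edges <- tibble::tribble(
    ~from, ~to, ~radius_um,
    1, 2, 0.5,
    2, 3, 0.6,
    3, 4, 0.7,    # creates a junction at node 3
    2, 4, 0.4,    # second junction path
    4, 5, 0.5,
    5, 6, 3.5,    # rosette-calibre edge (diameter 7)
    6, 9, 0.5,
    7, 8, 4.2,    # isolated rosette-calibre edge, disjoint component
    9, 10, 0.8,
    10, 11, 0.5,
    11, 12, 0.6,
    5, 7, 3.6     # adjacent rosette edge, contiguous with 5-6
  )
  canalicular_network(
    nodes, edges,
    landmarks = list(cv_center_um = c(0, 0), cv_radius_um = 10,
                     pv_radius_um = 120),
    tissue_depth_um = 40, sector_angle_rad = pi / 2
  )
}

# Small analytic geometry for fast solver tests.
quick_geom <- function(regime = "control", seed = 1, n_grid = 101L, ...) {
  gen_radial_geometry(synthetic_config(regime, seed = seed, ...),
                      n_grid = n_grid)
}

# Hand-built section table: one row per (lumen, cell).
toy_sections <- function() {
  mk <- function(id, diam, cells, sox9, panck) {
    tibble::tibble(lumen_id = id, diameter_um = diam,
                   n_bounding_cells = cells, cell_id = seq_len(cells),
                   sox9_nuclear_intensity = sox9,
                   panck_cellular_intensity = panck,
                   section_area_mm2 = 2)
  }
  dplyr::bind_rows(
    mk(1, 5, 4, c(300, 20, 20, 20), c(50, 50, 50, 50)),    # too narrow
    mk(2, 8, 2, c(300, 300), c(2000, 2000)),               # only 2 cells
    mk(3, 9, 3, c(250, 30, 30), c(100, 100, 100)),         # rosette, Sox9+
    mk(4, 7, 4, c(150, 100, 50, 20), c(1200, 10, 10, 10)), # rosette, panCK+
    mk(5, 12, 5, c(20, 20, 20, 20, 20), c(10, 10, 10, 10, 10)), # rosette, neg
    mk(6, 6, 3, c(500, 500, 500), c(5000, 5000, 5000)),    # diameter tie: out
    mk(7, 6.5, 3, c(200, 200, 200), c(1000, 1000, 1000))   # intensity ties: neg
  )
}
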