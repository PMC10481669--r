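#' Detect rosette segments in a 3D-reconstructed network
#'
#' Liver cell rosettes appear in the skeletonized network as canalicular
#' segments dilated beyond a diameter threshold (default 6 um, i.e. edge
#' radius > 3 um). Contiguous runs of super-threshold edges are merged into
#' single segments (connected components of the super-threshold subgraph);
#' each segment is characterized by its maximal edge radius and binned by
#' integer radius `j = 3 .. 8` um (a segment with radius in `[j, j+1)`
#' falls into bin `j`; radii of 9 um or more clamp into the top bin with a
#' warning). Counts are resolved by zone, a segment taking the zone of its
#' maximal-radius edge.
#'
#' @param zoned A `zoned_network` from [assign_zones()].
#' @param diameter_threshold_um Diameter above which an edge belongs to a
#'   rosette (default 6).
#' @param merge_runs Merge adjacent super-threshold edges into one segment
#'   (default `TRUE`); with `FALSE` every super-threshold edge counts as
#'   its own rosette.
#' @return A list of class `rosette_counts`: `segments` (tibble: `segment`,
#'   `zone`, `max_radius_um`, `j`, `n_edges`), `counts` (tibble: `zone`,
#'   `j`, `n` for all zone x j = 3..8 combinations) and `n_zones`.
#' @examples
#' zn <- assign_zones(gen_network(synthetic_config("psc", seed = 5)))
#' detect_rosettes(zn)$segments
#' @export
detect_rosettes <- function(zoned, diameter_threshold_um = 6,
                            merge_runs = TRUE) {
  stopifnot(inherits(zoned, "zoned_network"))
  check_number(diameter_threshold_um, "diameter_threshold_um", 0,
               strict_lower = TRUE)
  nz <- zoned$n_zones
  edges <- zoned$edges
  super <- which(2 * edges$radius_um > diameter_threshold_um)

  empty_counts <- tidyr::expand_grid(zone = seq_len(nz) - 1L, j = 3:8) |>
    mutate(n = 0L)

  if (length(super) == 0L) {
    return(structure(list(
      segments = tibble(segment = integer(), zone = integer(),
                        max_radius_um = numeric(), j = integer(),
                        n_edges = integer()),
      counts = empty_counts, n_zones = nz), class = "rosette_counts"))
  }

  es <- edges[super, ]
  if (merge_runs) {
    gs <- igraph::graph_from_data_frame(
      es[, c("from", "to")], directed = FALSE)
    comp <- igraph::components(gs)$membership
    # membership indexed by vertex name; map each edge to its component
    seg_id <- comp[as.character(es$from)]
  } else {
    seg_id <- seq_len(nrow(es))
  }

  segments <- tibble(seg = as.integer(seg_id), zone = es$zone,
                     radius_um = es$radius_um) |>
    group_by(.data$seg) |>
    summarise(max_radius_um = max(.data$radius_um),
              zone = .data$zone[which.max(.data$radius_um)],
              n_edges = n(), .groups = "drop") |>
    arrange(.data$seg) |>
    mutate(segment = row_number(),
           j = as.integer(pmin(floor(.data$max_radius_um), 8))) |>
    select("segment", "zone", "max_radius_um", "j", "n_edges")

  if (any(segments$max_radius_um >= 9)) {
    warn(sprintf("%d rosette segment(s) with radius >= 9 um clamped into bin j = 8.",
                 sum(segments$max_radius_um >= 9)))
  }
  if (any(segments$j < 3)) {
    # sub-3 um radii can only appear with a non-default threshold
    segments$j <- pmax(segments$j, 3L)
  }

  counts <- segments |>
    group_by(.data$zone, .data$j) |>
    summarise(n = n(), .groups = "drop")
  counts <- empty_counts |>
    select("zone", "j") |>
    left_join(counts, by = c("zone", "j")) |>
    mutate(n = if_else(is.na(.data$n), 0L, as.integer(.data$n)))

  structure(list(segments = segments, counts = counts, n_zones = nz),
            class = "rosette_counts")
}

#' @export
print.rosette_counts <- function(x, ...) {
  cat(sprintf("<rosette_counts> %d segment(s) across %d zones\n",
              nrow(x$segments), x$n_zones))
  invisible(x)
}

#' Estimated rosette volume from binned radius counts
#'
#' Rosettes counted with radius in `[j, j+1)` um are on average larger
#' than `j` um, which the offset `j_off` absorbs; the estimated total
#' volume is `V = sum_{j=3}^{8} (4/3) pi (j + j_off)^3 N_j` (um^3), spheres
#' of radius `j + j_off`.
#'
#' @param counts A `rosette_counts` from [detect_rosettes()], or a tibble
#'   with columns `j` and `n` (optionally `zone`).
#' @param j_off Radius offset (um), default 0.2.
#' @param by_zone If `TRUE` return a per-zone tibble, else the total.
#' @return Total volume (um^3), or a tibble `zone`, `volume_um3`.
#' @examples
#' rosette_volume(tibble::tibble(j = 3, n = 1))  # (4/3) pi 3.2^3
#' @export
rosette_volume <- function(counts, j_off = 0.2, by_zone = FALSE) {
  check_number(j_off, "j_off", 0)
  tab <- if (inherits(counts, "rosette_counts")) counts$counts else
    as_tibble(counts)
  if (!all(c("j", "n") %in% names(tab))) {
    abort("`counts` needs columns `j` and `n`.")
  }
  if (any(tab$n < 0)) abort("negative rosette counts.")
  tab$volume_um3 <- (4 / 3) * pi * (tab$j + j_off)^3 * tab$n
  if (by_zone) {
    if (!"zone" %in% names(tab)) abort("`counts` has no `zone` column.")
    tab |>
      group_by(.data$zone) |>
      summarise(volume_um3 = sum(.data$volume_um3), .groups = "drop")
  } else {
    sum(tab$volume_um3)
  }
}

#' Rosette-to-network volume ratio per zone
#'
#' Divides the estimated rosette volume by the total canalicular network
#' volume zone by zone; the ratio is `NA` where the network volume is 0.
#'
#' @param rosette_volume_um3 Numeric vector (or tibble with `zone`,
#'   `volume_um3`) of rosette volumes per zone.
#' @param network_volume_um3 Numeric vector (or `zone_profile` tibble with
#'   `network_volume_um3`) of network volumes on the same zones.
#' @return A tibble with `zone`, `rosette_volume_um3`,
#'   `network_volume_um3`, `ratio`.
#' @export
rosette_network_ratio <- function(rosette_volume_um3, network_volume_um3) {
  rv <- if (is.data.frame(rosette_volume_um3)) {
    rosette_volume_um3$volume_um3
  } else rosette_volume_um3
  nv <- if (is.data.frame(network_volume_um3)) {
    network_volume_um3$network_volume_um3
  } else network_volume_um3
  if (length(rv) != length(nv)) {
    abort(sprintf("zone count mismatch: %d rosette vs %d network zones.",
                  length(rv), length(nv)))
  }
  tibble(zone = seq_along(rv) - 1L, rosette_volume_um3 = rv,
         network_volume_um3 = nv,
         ratio = if_else(nv > 0, rv / nv, NA_real_))
}

#' Count rosettes on 2D tissue sections
#'
#' Applies the manual-annotation rule to a section table: a lumen is a
#' rosette if its diameter exceeds 6 um (strict) and it is bounded by more
#' than 2 hepatocytes (strict). Returns the count, the mean diameter of
#' counted rosettes and their areal density.
#'
#' @param sections A `section_table` (one row per lumen-cell pair; see
#'   [gen_section_table()]).
#' @param diameter_threshold_um Diameter rule (default 6, strict `>`).
#' @param min_cells Bounding-cell rule (default 2, strict `>`).
#' @return A tibble with one row: `n_rosettes`, `mean_diameter_um`,
#'   `per_mm2`, `section_area_mm2`.
#' @export
count_rosettes_2d <- function(sections, diameter_threshold_um = 6,
                              min_cells = 2) {
  sections <- as_tibble(sections)
  need <- c("lumen_id", "diameter_um", "n_bounding_cells",
            "section_area_mm2")
  if (!all(need %in% names(sections))) {
    abort(sprintf("section table needs columns %s.",
                  paste(need, collapse = ", ")))
  }
  lumina <- sections |>
    dplyr::distinct(.data$lumen_id, .data$diameter_um,
                    .data$n_bounding_cells, .data$section_area_mm2)
  area <- sum(unique(lumina$section_area_mm2))
  if (area <= 0) abort("zero total section area.")
  hits <- lumina |>
    filter(.data$diameter_um > diameter_threshold_um,
           .data$n_bounding_cells > min_cells)
  tibble(n_rosettes = nrow(hits),
         mean_diameter_um = if (nrow(hits)) mean(hits$diameter_um)
                            else NA_real_,
         per_mm2 = nrow(hits) / area,
         section_area_mm2 = area)
}

#' Classify rosettes by marker positivity on sections
#'
#' A rosette is Sox9-positive if one or more of its bounding hepatocytes
#' has a Sox9 nuclear intensity strictly above `sox9_threshold` (reference:
#' bile-duct cell nuclei), and pan-CK-positive if any bounding cell has a
#' cellular pan-CK intensity strictly above `panck_threshold`.
#'
#' @inheritParams count_rosettes_2d
#' @param sox9_threshold Sox9 nuclear intensity cut-off (default 200).
#' @param panck_threshold pan-CK cellular intensity cut-off (default 1000).
#' @return A tibble with one row: `n_rosettes`, `sox9_positive`,
#'   `panck_positive`, `sox9_fraction`, `panck_fraction` (fractions `NA`
#'   when no rosettes are detected).
#' @export
classify_rosette_markers <- function(sections, sox9_threshold = 200,
                                     panck_threshold = 1000,
                                     diameter_threshold_um = 6,
                                     min_cells = 2) {
  sections <- as_tibble(sections)
  need <- c("lumen_id", "diameter_um", "n_bounding_cells",
            "sox9_nuclear_intensity", "panck_cellular_intensity")
  if (!all(need %in% names(sections))) {
    abort(sprintf("section table needs columns %s.",
                  paste(need, collapse = ", ")))
  }
  per_rosette <- sections |>
    filter(.data$diameter_um > diameter_threshold_um,
           .data$n_bounding_cells > min_cells) |>
    group_by(.data$lumen_id) |>
    summarise(sox9 = any(.data$sox9_nuclear_intensity > sox9_threshold),
              panck = any(.data$panck_cellular_intensity > panck_threshold),
              .groups = "drop")
  n <- nrow(per_rosette)
  if (n == 0L) {
    warn("no rosettes on the sections; marker fractions undefined.")
  }
  tibble(n_rosettes = n,
         sox9_positive = sum(per_rosette$sox9),
         panck_positive = sum(per_rosette$panck),
         sox9_fraction = if (n) mean(per_rosette$sox9) else NA_real_,
         panck_fraction = if (n) mean(per_rosette$panck) else NA_real_)
}
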