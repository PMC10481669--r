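#' Write and read canalicular networks (GraphML and CSV dialects)
#'
#' Two interchange dialects carry the same graph: GraphML (via igraph)
#' with node coordinates and edge radii as attributes, or a paired
#' node/edge CSV (`<stem>_nodes.csv`: `id,x_um,y_um,z_um`;
#' `<stem>_edges.csv`: `from,to,radius_um`). Landmarks and sampling
#' metadata travel in a JSON sidecar (`<stem>_meta.json` /
#' `<path>.meta.json`). Edge lengths are recomputed from coordinates on
#' read; readers validate (positive radii, no self-loops) rather than
#' coerce.
#'
#' @param net A [canalicular_network()].
#' @param path GraphML file path (`write_network_graphml()`), or CSV stem
#'   (`write_network_csv()` writes `<stem>_nodes.csv`, `<stem>_edges.csv`,
#'   `<stem>_meta.json`).
#' @param seed Optional seed recorded in the metadata sidecar.
#' @return Writers return the path/stem invisibly; readers a
#'   [canalicular_network()].
#' @export
write_network_graphml <- function(net, path, seed = NA) {
  stopifnot(inherits(net, "canalicular_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "radius_um")], directed = FALSE,
    vertices = net$nodes[, c("id", "x_um", "y_um", "z_um")])
  igraph::write_graph(g, path, format = "graphml")
  write_network_meta(net, paste0(path, ".meta.json"), seed)
  invisible(path)
}

write_network_meta <- function(net, meta_path, seed) {
  jsonlite::write_json(list(
    biliflow = as.character(utils::packageVersion("biliflow")),
    seed = seed,
    hash = rlang::hash(list(as.data.frame(net$nodes),
                            as.data.frame(net$edges))),
    landmarks = net$landmarks,
    tissue_depth_um = net$tissue_depth_um,
    sector_angle_rad = net$sector_angle_rad
  ), meta_path, auto_unbox = TRUE, digits = NA)
}

read_network_meta <- function(meta_path) {
  if (!file.exists(meta_path)) {
    abort(sprintf("network metadata sidecar missing: %s", meta_path))
  }
  jsonlite::read_json(meta_path, simplifyVector = TRUE)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  g <- igraph::read_graph(path, format = "graphml")
  meta <- read_network_meta(paste0(path, ".meta.json"))
  nodes <- tibble(
    id = as.integer(igraph::V(g)$name),
    x_um = igraph::V(g)$x_um, y_um = igraph::V(g)$y_um,
    z_um = igraph::V(g)$z_um)
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- tibble(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
                  radius_um = igraph::E(g)$radius_um)
  canalicular_network(nodes, edges,
                      landmarks = meta$landmarks,
                      tissue_depth_um = meta$tissue_depth_um,
                      sector_angle_rad = meta$sector_angle_rad)
}

#' @rdname write_network_graphml
#' @export
write_network_csv <- function(net, path, seed = NA) {
  stopifnot(inherits(net, "canalicular_network"))
  utils::write.csv(as.data.frame(net$nodes[, c("id", "x_um", "y_um", "z_um")]),
                   paste0(path, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(net$edges[, c("from", "to", "radius_um")]),
                   paste0(path, "_edges.csv"), row.names = FALSE)
  write_network_meta(net, paste0(path, "_meta.json"), seed)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_csv <- function(path) {
  nf <- paste0(path, "_nodes.csv"); ef <- paste0(path, "_edges.csv")
  for (f in c(nf, ef)) {
    if (!file.exists(f)) abort(sprintf("no such file: %s", f))
  }
  meta <- read_network_meta(paste0(path, "_meta.json"))
  nodes <- utils::read.csv(nf)
  edges <- utils::read.csv(ef)
  canalicular_network(nodes, edges,
                      landmarks = meta$landmarks,
                      tissue_depth_um = meta$tissue_depth_um,
                      sector_angle_rad = meta$sector_angle_rad)
}

#' Write and read 2D section tables as CSV
#'
#' @param sections A `section_table` (see [gen_section_table()]).
#' @param path CSV file path.
#' @return Writer: the path, invisibly. Reader: a `section_table` tibble.
#' @export
write_section_csv <- function(sections, path) {
  utils::write.csv(as.data.frame(sections), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_section_csv
#' @export
read_section_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- as_tibble(utils::read.csv(path))
  need <- c("lumen_id", "diameter_um", "n_bounding_cells",
            "sox9_nuclear_intensity", "panck_cellular_intensity",
            "section_area_mm2")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("section table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (any(df$diameter_um <= 0)) abort("non-positive lumen diameter.")
  if (any(df$n_bounding_cells < 2)) {
    abort("lumen with fewer than 2 bounding cells.")
  }
  if (any(df$sox9_nuclear_intensity < 0) ||
        any(df$panck_cellular_intensity < 0)) {
    abort("negative staining intensity.")
  }
  structure(df, class = c("section_table", class(df)))
}

#' Read and write the run configuration as JSON
#'
#' The run configuration bundles a [synthetic_config()] block per regime
#' and a [bile_params()] block. Unknown keys are rejected rather than
#' ignored so that typos in hand-edited files surface immediately.
#'
#' @param path JSON file path.
#' @param config A list with elements `control`, `psc` (synthetic_config)
#'   and `params` (bile_params).
#' @return `read_run_config()`: the validated list; `write_run_config()`:
#'   the path, invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("control", "psc", "params")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- list()
  for (regime in intersect(c("control", "psc"), names(raw))) {
    block <- raw[[regime]]
    allowed <- setdiff(names(formals(synthetic_config)), "regime")
    unknown <- setdiff(names(block), allowed)
    if (length(unknown)) {
      abort(sprintf("unknown key(s) in `%s` block: %s", regime,
                    paste(unknown, collapse = ", ")))
    }
    out[[regime]] <- do.call(synthetic_config, c(list(regime = regime), block))
  }
  if (!is.null(raw$params)) {
    allowed <- names(formals(bile_params))
    unknown <- setdiff(names(raw$params), allowed)
    if (length(unknown)) {
      abort(sprintf("unknown key(s) in `params` block: %s",
                    paste(unknown, collapse = ", ")))
    }
    out$params <- do.call(bile_params, raw$params)
  }
  out
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  blocks <- list()
  for (regime in intersect(c("control", "psc"), names(config))) {
    cfg <- config[[regime]]
    stopifnot(inherits(cfg, "synthetic_config"))
    blocks[[regime]] <- cfg[setdiff(names(cfg), "regime")]
  }
  if (!is.null(config$params)) {
    stopifnot(inherits(config$params, "bile_params"))
    blocks$params <- unclass(config$params)
  }
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
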