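# Header-comment dialect shared by the TSV writers: '# key: value' lines
# (provenance + annulus metadata) above a tab-separated table with '.'
# decimals, locale-independent.

provenance_header <- function(extra = character()) {
  c(sprintf("# biliflow: %s",
            as.character(utils::packageVersion("biliflow"))),
    extra)
}

write_commented_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_header_value <- function(lines, key) {
  hit <- grep(sprintf("^# %s:", key), lines, value = TRUE)
  if (!length(hit)) abort(sprintf("header line `# %s:` missing.", key))
  as.numeric(sub(sprintf("^# %s:\\s*", key), "", hit[1]))
}

#' Write and read radial geometry profiles as TSV
#'
#' The geometry dialect is a tab-separated table with columns `rho_um`,
#' `A_per_um`, `eps_bc`, `r_bc_um`, `f` preceded by `# key: value` header
#' comments carrying `tau`, `rho0_um`, `L_um` and provenance. Round-trips
#' are lossless to at least 12 significant digits; readers reject
#' non-monotone grids and missing columns rather than coercing.
#'
#' @param geom A [radial_geometry()].
#' @param path File path.
#' @param seed Optional seed recorded in the provenance header.
#' @return `write_geometry_tsv()` the path, invisibly;
#'   `read_geometry_tsv()` a [radial_geometry()].
#' @export
write_geometry_tsv <- function(geom, path, seed = NA) {
  stopifnot(inherits(geom, "radial_geometry"))
  header <- provenance_header(c(
    sprintf("# seed: %s", seed),
    sprintf("# hash: %s", rlang::hash(as.data.frame(geom))),
    sprintf("# tau: %.12g", geom_tau(geom)),
    sprintf("# rho0_um: %.12g", geom_rho0_um(geom)),
    sprintf("# L_um: %.12g", geom_L_um(geom))
  ))
  write_commented_tsv(as.data.frame(geom), path, header)
}

#' @rdname write_geometry_tsv
#' @export
read_geometry_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  tau <- read_header_value(lines, "tau")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", colClasses = "numeric")
  need <- c("rho_um", "A_per_um", "eps_bc", "r_bc_um", "f")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("geometry file lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  radial_geometry(df$rho_um, df$A_per_um, df$eps_bc, df$r_bc_um, df$f,
                  tau = tau)
}

#' Write a solved pressure profile as TSV
#'
#' Emits the solution table (`rho_um`, `w_m_s`, `p_pa`, `c_mol_m3`,
#' `wc_m_s`) with the solver diagnostics (`p0_pa`, `residual_pa`,
#' `iterations`) and provenance in the header comments.
#'
#' @param sol A `pressure_solution` from [solve_pressure()].
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @return The path, invisibly.
#' @export
write_solution_tsv <- function(sol, path, seed = NA) {
  stopifnot(inherits(sol, "pressure_solution"))
  header <- provenance_header(c(
    sprintf("# seed: %s", seed),
    sprintf("# p0_pa: %.12g", attr(sol, "p0_pa")),
    sprintf("# residual_pa: %.6g", attr(sol, "residual_pa")),
    sprintf("# iterations: %d", attr(sol, "iterations"))
  ))
  write_commented_tsv(as.data.frame(sol), path, header)
}

#' Write a pipeline report to disk
#'
#' Writes the report's tables as CSV and the scalar results plus
#' provenance as JSON under `dir`.
#'
#' @param report A `pipeline_report` from [assemble_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$zone_means, file.path(dir, "zone_means.csv"),
                   row.names = FALSE)
  if (!is.null(report$contrasts)) {
    utils::write.csv(report$contrasts, file.path(dir, "contrasts.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    correlations = setNames(as.list(report$correlations$r),
                            report$correlations$pair),
    pressure_test = report$pressure_test,
    provenance = report$provenance
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
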