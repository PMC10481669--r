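#' Simulate a cohort of lobule axes and run the full pipeline
#'
#' Generates a control + disease cohort of synthetic lobule axes and runs
#' every stage on each sample: network generation, zone assignment, zone
#' statistics, rosette detection and volume estimation, reduction to radial
#' geometry, pressure solve and zone pressure medians. The result is the
#' pooled per-(sample, zone) observation table on which the correlation
#' stage operates.
#'
#' With `effect = TRUE` the disease samples use the PSC-like regime —
#' dilated canaliculi, larger lobule, higher bile-duct pressure (2,000 Pa),
#' pericentrally biased rosette insertion co-varying with network dropout —
#' so rosette burden, pressure and (inversely) connectivity are linked by
#' construction. With `effect = FALSE` every sample is drawn from the
#' control regime (no regime contrast, uniform sparse rosette insertion),
#' a null cohort in which rosette burden varies only by sampling noise.
#'
#' @param n_control,n_disease Patients per arm (defaults 3 and 4).
#' @param axes_control,axes_disease Imaged CV-PV axes per patient
#'   (defaults 1 and 3, mirroring deep-imaging designs where disease
#'   tissue is sampled more densely); every axis is an independent
#'   network draw and contributes its own per-zone rows.
#' @param seed Integer master seed; per-sample seeds are derived from it.
#' @param g Constant osmolyte secretion rate (mol/(m^3 s)) shared by all
#'   samples.
#' @param effect Logical; `FALSE` gives the null cohort.
#' @param nodes_per_zone Network density per sample (default 45).
#' @param n_zones Zones along the axis (default 11).
#' @return A tibble of class `axis_observations`, one row per
#'   (sample, zone): `sample`, `regime`, `zone`, `rosette_ratio`,
#'   `connectivity`, `pressure_pa`, `mean_radius_um`,
#'   `volume_fraction_pct`, `network_volume_um3`.
#' @export
simulate_cohort <- function(n_control = 3L, n_disease = 4L, seed = 1L,
                            g = 0.3, effect = TRUE, nodes_per_zone = 45L,
                            n_zones = 11L, axes_control = 1L,
                            axes_disease = 3L) {
  n_control <- check_count(n_control, "n_control", 1L)
  n_disease <- check_count(n_disease, "n_disease", 1L)
  axes_control <- check_count(axes_control, "axes_control", 1L)
  axes_disease <- check_count(axes_disease, "axes_disease", 1L)
  seed <- check_count(seed, "seed")

  patients <- tibble(
    sample = c(sprintf("control_%d", seq_len(n_control)),
               sprintf("disease_%d", seq_len(n_disease))),
    regime = rep(c("control", "psc"), c(n_control, n_disease)),
    n_axes = rep(c(axes_control, axes_disease), c(n_control, n_disease))
  )
  plan <- patients |>
    tidyr::uncount(.data$n_axes, .id = "axis") |>
    select(-dplyr::any_of("n_axes")) |>
    mutate(idx = row_number())

  obs <- purrr::pmap(plan, function(sample, regime, axis, idx) {
    sample_seed <- seed + 1000L * idx
    cfg <- if (!effect) {
      synthetic_config("control", seed = sample_seed,
                       nodes_per_zone = nodes_per_zone, n_zones = n_zones)
    } else if (regime == "control") {
      synthetic_config("control", seed = sample_seed,
                       nodes_per_zone = nodes_per_zone, n_zones = n_zones)
    } else {
      synthetic_config("psc", seed = sample_seed, rosette_cv_bias = 0.8,
                       nodes_per_zone = nodes_per_zone, n_zones = n_zones)
    }
    pl <- if (effect && regime == "psc") 2000 else 1000
    run_axis(cfg, bile_params(pL = pl, g = g), n_zones = n_zones) |>
      mutate(sample = sample, regime = regime, axis = axis, .before = 1)
  }) |> bind_rows()

  structure(obs, class = c("axis_observations", class(obs)))
}

# one sample through every stage; returns the per-zone observation rows
run_axis <- function(cfg, params, n_zones = 11L) {
  net <- gen_network(cfg)
  zoned <- assign_zones(net, n_zones = n_zones)
  zp <- zone_statistics(zoned)
  ros <- detect_rosettes(zoned)
  rv <- rosette_volume(ros, by_zone = TRUE)
  ratio <- rosette_network_ratio(rv, zp)
  geom <- network_to_geometry(net, n_shells = n_zones)
  sol <- solve_pressure(geom, params)
  zs <- zone_pressure_summary(sol, n_zones = n_zones)
  tibble(zone = zp$zone,
         rosette_ratio = ratio$ratio,
         connectivity = zp$connectivity,
         pressure_pa = zs$zones$median_pa,
         mean_radius_um = zp$mean_radius_um,
         volume_fraction_pct = zp$volume_fraction_pct,
         network_volume_um3 = zp$network_volume_um3)
}

#' Bootstrap confidence interval for a Pearson correlation
#'
#' Nonparametric pairs bootstrap: rows are resampled with replacement and
#' the correlation recomputed; the interval is the percentile interval of
#' the bootstrap distribution.
#'
#' @param x,y Paired observations.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param level Interval level (default 0.95).
#' @param seed Seed for the resampling.
#' @return A list with `r`, `lower`, `upper`, `level`.
#' @export
bootstrap_correlation_ci <- function(x, y, n_boot = 2000L, level = 0.95,
                                     seed = 1L) {
  r <- pearson_correlation(x, y)
  n <- length(x)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (sd(x[i]) == 0 || sd(y[i]) == 0) return(NA_real_)
      cor(x[i], y[i])
    }, numeric(1))
  })
  qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  list(r = r, lower = qs[1], upper = qs[2], level = level)
}

#' Assemble the end-to-end run report
#'
#' Collects the correlation and group-comparison results of a cohort run
#' into one report object: the two headline correlations (rosette/network
#' volume vs predicted pressure, and vs connectivity) over all pooled
#' (sample, zone) observations, per-regime axis summaries, the paired
#' per-zone pressure comparison and percent changes of the zone
#' statistics, plus a provenance block (observation hash, seed).
#'
#' @param obs An `axis_observations` tibble from [simulate_cohort()] (or
#'   built from real per-zone measurements).
#' @param seed Seed recorded in the provenance block.
#' @return A list of class `pipeline_report`.
#' @export
assemble_report <- function(obs, seed = NA_integer_) {
  need <- c("sample", "regime", "zone", "rosette_ratio", "connectivity",
            "pressure_pa")
  if (!all(need %in% names(obs))) {
    abort(sprintf("observations need columns %s.",
                  paste(need, collapse = ", ")))
  }
  ok <- stats::complete.cases(obs[, c("rosette_ratio", "connectivity",
                                      "pressure_pa")])
  oc <- obs[ok, ]
  correlations <- tibble(
    pair = c("rosette_ratio~pressure", "rosette_ratio~connectivity"),
    r = c(pearson_correlation(oc$rosette_ratio, oc$pressure_pa),
          pearson_correlation(oc$rosette_ratio, oc$connectivity)),
    n = nrow(oc)
  )

  regimes <- unique(obs$regime)
  by_zone <- obs |>
    group_by(.data$regime, .data$zone) |>
    summarise(pressure_pa = mean(.data$pressure_pa),
              rosette_ratio = mean(.data$rosette_ratio),
              connectivity = mean(.data$connectivity, na.rm = TRUE),
              mean_radius_um = mean(.data$mean_radius_um, na.rm = TRUE),
              .groups = "drop")
  pressure_test <- NULL
  contrasts <- NULL
  if (length(regimes) == 2L) {
    wide <- tidyr::pivot_wider(by_zone, id_cols = "zone",
                               names_from = "regime",
                               values_from = c("pressure_pa",
                                               "mean_radius_um"))
    pressure_test <- group_tests(wide$pressure_pa_control,
                                 wide$pressure_pa_psc, mode = "paired")
    contrasts <- tibble(
      statistic = c("pressure_pa", "mean_radius_um"),
      control = c(mean(wide$pressure_pa_control),
                  mean(wide$mean_radius_um_control)),
      disease = c(mean(wide$pressure_pa_psc),
                  mean(wide$mean_radius_um_psc))
    ) |>
      mutate(percent_change = percent_change(.data$control, .data$disease))
  }

  structure(list(
    correlations = correlations,
    zone_means = by_zone,
    pressure_test = pressure_test,
    contrasts = contrasts,
    provenance = list(seed = seed, n_obs = nrow(obs),
                      obs_hash = rlang::hash(as.data.frame(obs)))
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$correlations)
  if (!is.null(x$contrasts)) print(x$contrasts)
  invisible(x)
}
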