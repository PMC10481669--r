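#' Generate a synthetic 2D tissue-section table
#'
#' Emulates manual lumen annotations on a stained tissue section: rosette
#' profiles (lumen diameter > 6 um, bounded by more than 2 hepatocytes)
#' mixed with ordinary canalicular lumina, one row per (lumen, bounding
#' cell) with per-cell Sox9 nuclear and pan-CK cellular staining
#' intensities (arbitrary units on the 0-4095 scale of 12-bit acquisition).
#' A rosette is generated Sox9-positive with probability
#' `sox9_positive_fraction` — in which case exactly one of its cells gets a
#' nuclear intensity well above the 200-unit bile-duct reference — and
#' pan-CK-positive independently with `panck_positive_fraction` (cellular
#' intensity above 1,000).
#'
#' @param config A [synthetic_config()]; uses `n_rosettes_2d`,
#'   `n_lumina_2d`, the marker fractions and `section_area_mm2`.
#' @return A tibble of class `section_table` with columns `lumen_id`,
#'   `diameter_um`, `n_bounding_cells`, `cell_id`,
#'   `sox9_nuclear_intensity`, `panck_cellular_intensity`,
#'   `section_area_mm2`.
#' @examples
#' sec <- gen_section_table(synthetic_config("psc", seed = 3))
#' dplyr::n_distinct(sec$lumen_id)
#' @export
gen_section_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 1L, gen_section_table_impl(config))
}

gen_section_table_impl <- function(config) {
  n_ros <- config$n_rosettes_2d
  n_norm <- config$n_lumina_2d

  one_lumen <- function(id, rosette) {
    if (rosette) {
      diam <- runif(1, 6.5, 16)          # rosette diameters, strictly > 6 um
      ncell <- sample(3:6, 1)            # > 2 bounding hepatocytes
    } else {
      diam <- runif(1, 0.8, 5.5)         # ordinary canalicular lumen
      ncell <- 2L                        # canaliculus: two apposed cells
    }
    sox9 <- runif(ncell, 20, 150)        # hepatocyte background, below 200
    panck <- runif(ncell, 50, 800)       # background, below 1,000
    if (rosette && runif(1) < config$sox9_positive_fraction) {
      sox9[sample.int(ncell, 1)] <- runif(1, 250, 900)
    }
    if (rosette && runif(1) < config$panck_positive_fraction) {
      panck[sample.int(ncell, 1)] <- runif(1, 1200, 3500)
    }
    tibble(lumen_id = id, diameter_um = diam, n_bounding_cells = ncell,
           cell_id = seq_len(ncell), sox9_nuclear_intensity = sox9,
           panck_cellular_intensity = panck)
  }

  rows <- purrr::map2(
    seq_len(n_ros + n_norm),
    rep(c(TRUE, FALSE), c(n_ros, n_norm)),
    one_lumen
  )
  out <- bind_rows(rows)
  out$section_area_mm2 <- config$section_area_mm2
  structure(out, class = c("section_table", class(out)))
}
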