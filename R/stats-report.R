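#' Pearson product-moment correlation with validation
#'
#' Thin, validated wrapper around the standard product-moment correlation
#' used for the pooled per-zone association analyses (e.g. rosette/network
#' volume vs predicted pressure).
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite, non-constant).
#' @return The correlation coefficient `r` in `[-1, 1]`.
#' @examples
#' pearson_correlation(1:5, c(2, 4, 5, 4, 7))
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("need at least 3 paired observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("non-finite values in correlation input.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance: correlation undefined.")
  }
  cor(x, y, method = "pearson")
}

#' Two-tailed t test between control and disease summaries
#'
#' Group comparison as used for the zone-resolved profiles: paired
#' two-tailed t test for per-zone means of matched zones, unpaired
#' (pooled-variance) two-tailed t test for the remaining quantifications.
#'
#' @param control,disease Numeric vectors of per-zone (or per-sample)
#'   summaries. Paired mode requires equal lengths.
#' @param mode `"paired"` or `"unpaired"`.
#' @return A one-row tibble: `mode`, `estimate` (mean difference,
#'   disease - control), `statistic`, `df`, `p_value`.
#' @export
group_tests <- function(control, disease, mode = c("paired", "unpaired")) {
  mode <- match.arg(mode)
  if (length(control) < 2L || length(disease) < 2L) {
    abort("need at least 2 observations per group.")
  }
  if (mode == "paired" && length(control) != length(disease)) {
    abort("paired mode requires equal-length groups.")
  }
  if (mode == "paired" && sd(disease - control) == 0) {
    if (all(disease == control)) {
      # identical groups: no effect, by convention t = 0 and p = 1
      return(tibble(mode = mode, estimate = 0, statistic = 0,
                    df = length(control) - 1, p_value = 1))
    }
    abort("zero variance of paired differences: t statistic undefined.")
  }
  if (mode == "unpaired" && sd(control) == 0 && sd(disease) == 0) {
    abort("zero variance in both groups: t statistic undefined.")
  }
  ht <- if (mode == "paired") {
    t.test(disease, control, paired = TRUE, alternative = "two.sided")
  } else {
    t.test(disease, control, var.equal = TRUE, alternative = "two.sided")
  }
  tibble(mode = mode,
         estimate = if (mode == "paired") unname(ht$estimate)
                    else unname(ht$estimate[1] - ht$estimate[2]),
         statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Percent change of a disease summary relative to control
#'
#' `100 * (disease - control) / control`, the reporting convention for
#' regime contrasts of network statistics.
#'
#' @param control,disease Numeric scalars or equal-length vectors;
#'   `control` must be nonzero.
#' @return Percent change (same length as the inputs).
#' @examples
#' percent_change(10, 11.16)  # +11.6
#' @export
percent_change <- function(control, disease) {
  if (any(control == 0)) abort("zero control value: percent change undefined.")
  100 * (disease - control) / control
}
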