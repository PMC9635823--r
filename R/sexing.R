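#' Genetic sexing from sex-chromosome read counts
#'
#' Computes `R_Y = n_Y / (n_X + n_Y)`, the fraction of sex-chromosome reads
#' mapping to the Y, with a normal-approximation 95% confidence interval,
#' and compares the interval to the XX and XY thresholds (defaults 0.016 and
#' 0.075, the values used with shotgun data). The verdict uses the interval,
#' not the point estimate, so low-count libraries yield the intermediate
#' verdicts "consistent with XY but not XX" / "consistent with XX but not
#' XY" rather than a hard call.
#'
#' @param n_y Reads mapped to Y (vectorized).
#' @param n_xy Reads mapped to X or Y.
#' @param xx_max R_Y below which a library is XX-consistent (default 0.016).
#' @param xy_min R_Y above which a library is XY-consistent (default 0.075).
#' @param conf Confidence level of the interval (default 0.95).
#' @return Tibble with `n_y`, `n_xy`, `r_y`, `ci_low`, `ci_high`, `verdict`.
#' @export
determine_sex_ry <- function(n_y, n_xy, xx_max = 0.016, xy_min = 0.075,
                             conf = 0.95) {
  if (any(n_y < 0 | n_xy < 0)) stop_pk("read counts must be non-negative")
  if (any(n_y > n_xy)) stop_pk("n_y cannot exceed n_xy")
  z <- qnorm(1 - (1 - conf) / 2)
  r <- ifelse(n_xy > 0, n_y / n_xy, NA_real_)
  se <- ifelse(n_xy > 0, sqrt(r * (1 - r) / n_xy), NA_real_)
  lo <- pmax(0, r - z * se)
  hi <- pmin(1, r + z * se)
  verdict <- dplyr::case_when(
    n_xy == 0 ~ "undetermined",
    hi < xx_max ~ "XX",
    lo > xy_min ~ "XY",
    lo > xx_max & hi >= xy_min ~ "consistent with XY but not XX",
    hi < xy_min & lo <= xx_max ~ "consistent with XX but not XY",
    TRUE ~ "undetermined"
  )
  tibble(n_y = n_y, n_xy = n_xy, r_y = r, ci_low = lo, ci_high = hi,
         verdict = verdict)
}
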