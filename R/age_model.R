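# The HEAA epigenetic clock.
#
# The Humpback Epigenetic Age Assay (HEAA) is a three-site linear clock:
#
#   age = 5.4717 x + 3.9705 y - 0.6793 z + 1.4695
#
# where x, y, z are the DNA methylation frequencies (%) at GRIA2+202,
# CDKN2A+297 and TET2+31. The coefficients are taken as published constants
# (the clock was calibrated on known-age whales elsewhere; no refitting is
# done here). Estimation uncertainty is attached as a fixed-half-width 95%
# confidence interval.

#' HEAA clock coefficients
#'
#' Named vector of the published clock coefficients: slopes for x (GRIA2+202),
#' y (CDKN2A+297), z (TET2+31), and the intercept.
#' @export
heaa_coefficients <- c(x = 5.4717, y = 3.9705, z = -0.6793, intercept = 1.4695)

#' Fixed half-width of the HEAA 95% confidence interval, in years
#'
#' All published intervals are exactly the point age plus/minus 4.47 years;
#' the assay's reported 95% CI width. Configurable in the functions that
#' attach intervals.
#' @export
HEAA_CI_HALF_WIDTH <- 4.47

#' Estimate age from DNAm frequencies with the HEAA clock
#'
#' @param x,y,z DNAm frequencies in percent (0–100) at GRIA2+202,
#'   CDKN2A+297 and TET2+31; vectorised.
#' @return estimated age in years, full precision (round with
#'   [round_report()] at the reporting boundary). Estimates can be negative
#'   for high z; they are returned as computed.
#' @examples
#' heaa_age(1.60, 2.04, 7.34)  # 13.337978 -> reported as 13.34
#' @export
heaa_age <- function(x, y, z) {
  for (v in list(x, y, z)) {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 100)) {
      stop("DNAm frequencies must be percentages in [0, 100]")
    }
  }
  b <- heaa_coefficients
  b[["x"]] * x + b[["y"]] * y + b[["z"]] * z + b[["intercept"]]
}

# Invert the clock for x given age, y and z (used by the cohort generator).
solve_heaa_x <- function(age, y, z) {
  b <- heaa_coefficients
  (age - b[["intercept"]] - b[["y"]] * y - b[["z"]] * z) / b[["x"]]
}

#' Attach the fixed-width 95% confidence interval to point ages
#'
#' The lower bound is clamped at 0; point ages themselves are not clamped
#' (reported estimates can fall below the interval half-width, giving a
#' lower bound of 0.00).
#'
#' @param age point age(s) in years, typically already rounded to 2 decimals.
#' @param half_width interval half-width in years (default
#'   [HEAA_CI_HALF_WIDTH]).
#' @return `data.frame` with `ci_low` and `ci_high`, rounded to 2 decimals.
#' @examples
#' attach_ci(13.34)  # 8.87 - 17.81
#' attach_ci(4.00)   # 0.00 - 8.47
#' @export
attach_ci <- function(age, half_width = HEAA_CI_HALF_WIDTH) {
  stopifnot(all(is.finite(age)))
  data.frame(ci_low = pmax(0, round_report(age - half_width)),
             ci_high = round_report(age + half_width))
}

#' Estimate ages with confidence intervals for a table of samples
#'
#' The reporting layer of the clock: takes per-sample assay-site frequencies
#' and emits the estimates table (one row per biopsy sample with x, y, z,
#' the 2-decimal point age, and the 95% CI bounds).
#'
#' @param freqs `data.frame` with columns `sample_id`, `x`, `y`, `z`
#'   (frequencies in percent), e.g. from [sample_frequencies()] or
#'   [hachijojima_frequencies()].
#' @param half_width CI half-width in years.
#' @return `data.frame`: `sample_id`, `x`, `y`, `z`, `age` (2-decimal),
#'   `ci_low`, `ci_high`, `negative_age` flag.
#' @export
estimate_ages <- function(freqs, half_width = HEAA_CI_HALF_WIDTH) {
  stopifnot(all(c("sample_id", "x", "y", "z") %in% names(freqs)))
  age <- round_report(heaa_age(freqs$x, freqs$y, freqs$z))
  ci <- attach_ci(age, half_width)
  data.frame(sample_id = freqs$sample_id,
             x = freqs$x, y = freqs$y, z = freqs$z,
             age = age, ci_low = ci$ci_low, ci_high = ci$ci_high,
             negative_age = age < 0,
             stringsAsFactors = FALSE)
}
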