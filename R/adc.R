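#' ADC from a pair of diffusion-weighted signals
#'
#' Under the mono-exponential decay model
#' \eqn{S_2 = S_1 \exp(-(b_2 - b_1)\,\mathrm{ADC})}, the apparent
#' diffusion coefficient recovered from two signal intensities is
#' \deqn{\mathrm{ADC} = \frac{\ln(S_1/S_2)}{b_2 - b_1},}
#' reported here in units of 10^-3 mm^2/s (the scale on which clinical
#' thresholds are quoted). The sign convention divides the log of the
#' *ratio of the less- to the more-weighted signal* so that decaying
#' signal yields a positive coefficient.
#'
#' @param s1,s2 Signal intensities (> 0) at diffusion weightings `b1`
#'   and `b2`; vectors are recycled.
#' @param b1,b2 Diffusion weightings in s/mm^2 with `b2 > b1`;
#'   defaults 0 and 750.
#' @return ADC in 10^-3 mm^2/s; non-negative whenever `s2 <= s1`.
#' @export
#' @examples
#' adc_from_signals(1000, 1000 * exp(-0.75))   # 1.0
adc_from_signals <- function(s1, s2, b1 = 0, b2 = 750) {
  if (any(s1 <= 0) || any(s2 <= 0)) {
    abort("signal intensities must be positive", class = "dwidx_domain_error")
  }
  if (any(b2 <= b1)) {
    abort("b2 must exceed b1", class = "dwidx_domain_error")
  }
  1000 * log(s1 / s2) / (b2 - b1)
}

#' Forward mono-exponential signal decay
#'
#' The generative counterpart of [adc_from_signals()]: the signal at
#' weighting `b2` produced by a tissue with a given ADC. Used as the
#' oracle in round-trip tests and to build digital phantoms.
#'
#' @param s1 Signal at `b1` (> 0).
#' @param adc ADC in 10^-3 mm^2/s (>= 0).
#' @inheritParams adc_from_signals
#' @return Signal at `b2`.
#' @export
decay_signal <- function(s1, adc, b1 = 0, b2 = 750) {
  s1 * exp(-(b2 - b1) * adc / 1000)
}

#' Per-lesion ADC from repeated ROI measurements
#'
#' At least three regions of interest are measured per lesion and the
#' lowest ADC is taken as the lesion's value (the most cellular, hence
#' most suspicious, region drives the call).
#'
#' @param adc_values Numeric vector of per-ROI ADC measurements
#'   (10^-3 mm^2/s), length >= 1, all > 0.
#' @return The minimum measurement.
#' @export
#' @examples
#' lesion_adc(c(1.10, 0.95, 1.02))
lesion_adc <- function(adc_values) {
  if (length(adc_values) < 1 || anyNA(adc_values)) {
    abort("at least one non-missing ADC measurement is required",
          class = "dwidx_domain_error")
  }
  if (any(adc_values <= 0)) {
    abort("ADC measurements must be positive", class = "dwidx_domain_error")
  }
  min(adc_values)
}

#' Voxelwise ADC map from two signal images
#'
#' Applies [adc_from_signals()] elementwise to a pair of equally shaped
#' signal matrices. Voxels where the more-weighted signal exceeds the
#' less-weighted one (noise) would give negative ADC; they are clamped to
#' 0 and flagged in the `"clamped"` attribute, keeping the map in the
#' valid domain for downstream dichotomization.
#'
#' @param signal_b1,signal_b2 Numeric matrices of positive signals at
#'   weightings `b1` and `b2`, identical dimensions.
#' @inheritParams adc_from_signals
#' @return A matrix of ADC values (10^-3 mm^2/s) with a logical matrix
#'   attribute `"clamped"` marking the zeroed voxels.
#' @export
adc_map <- function(signal_b1, signal_b2, b1 = 0, b2 = 750) {
  if (!identical(dim(signal_b1), dim(signal_b2))) {
    abort("signal images must have identical dimensions",
          class = "dwidx_domain_error")
  }
  adc <- adc_from_signals(as.numeric(signal_b1), as.numeric(signal_b2),
                          b1 = b1, b2 = b2)
  clamped <- adc < 0
  adc[clamped] <- 0
  out <- matrix(adc, nrow = nrow(signal_b1), ncol = ncol(signal_b1))
  attr(out, "clamped") <- matrix(clamped, nrow = nrow(signal_b1))
  out
}
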