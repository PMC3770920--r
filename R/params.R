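# Detection parameter objects.  Defaults are the values used throughout for
# cultured hippocampal networks; every coefficient is exposed.

#' Spike detection parameters
#'
#' Parameters of the median-normalized amplitude threshold `T = n_s * sigma`,
#' `sigma = median(|x|) / 0.6745`, applied to the band-pass filtered signal.
#'
#' @param band_low,band_high Pass band edges in Hz (defaults 300 and 8000).
#' @param n_s Threshold coefficient (default 4, detecting spikes above
#'   roughly 4 noise standard deviations).
#' @param min_isi Minimal interspike interval per channel in seconds
#'   (default 1 ms); later peaks within `min_isi` of an accepted spike are
#'   discarded.
#' @param normalization_constant Divisor converting the median absolute
#'   deviation of a Gaussian signal to its standard deviation
#'   (`qnorm(0.75)`, 0.6745).
#' @return A `spike_detection_params` list.
#' @export
spike_detection_params <- function(band_low = 300, band_high = 8000,
                                   n_s = 4, min_isi = 0.001,
                                   normalization_constant = 0.6745) {
  stopifnot_scalar(band_low, "band_low", 0, strict = TRUE)
  stopifnot_scalar(band_high, "band_high", band_low, strict = TRUE)
  stopifnot_scalar(n_s, "n_s", 0, strict = TRUE)
  stopifnot_scalar(min_isi, "min_isi", 0)
  stopifnot_scalar(normalization_constant, "normalization_constant", 0,
                   strict = TRUE)
  structure(
    list(band_low = band_low, band_high = band_high, n_s = n_s,
         min_isi = min_isi, normalization_constant = normalization_constant),
    class = "spike_detection_params"
  )
}

#' Burst and superburst detection parameters
#'
#' @param burst_coeff Burst threshold coefficient: the burst threshold is
#'   `burst_coeff * sd(TSR)` (default 0.1, chosen to exclude basal activity).
#' @param superburst_coeff Superburst threshold coefficient applied to the
#'   standard deviation of the Gaussian-window indicator (default 0.4).
#' @param gaussian_effective_width Effective width of the Gaussian window in
#'   seconds (default 50).
#' @param width_convention How `gaussian_effective_width` maps to the Gaussian
#'   standard deviation: `"fwhm"` (full width at half maximum,
#'   `sigma = width / 2.3548`), `"sigma"` (the width *is* the sd), or
#'   `"window"` (width is the length of a tapered window whose sd is
#'   `width / 5`, the usual discrete Gaussian-window convention).  See the
#'   methods vignette for why `"window"` is the default.
#' @param indicator_step Evaluation step of the indicator in seconds
#'   (default 10 ms).
#' @param indicator_center Baseline convention for superburst thresholding:
#'   `"mean"` places the threshold at `mean(indicator) +
#'   superburst_coeff * sd(indicator)` (thresholding the fluctuation about the
#'   mean); `"none"` thresholds the raw indicator values at
#'   `superburst_coeff * sd(indicator)`.
#' @return A `burst_detection_params` list.
#' @export
burst_detection_params <- function(burst_coeff = 0.1, superburst_coeff = 0.4,
                                   gaussian_effective_width = 50,
                                   width_convention = c("window", "fwhm",
                                                        "sigma"),
                                   indicator_step = 0.01,
                                   indicator_center = c("mean", "none")) {
  width_convention <- match.arg(width_convention)
  indicator_center <- match.arg(indicator_center)
  stopifnot_scalar(burst_coeff, "burst_coeff", 0, strict = TRUE)
  stopifnot_scalar(superburst_coeff, "superburst_coeff", 0, strict = TRUE)
  stopifnot_scalar(gaussian_effective_width, "gaussian_effective_width", 0,
                   strict = TRUE)
  stopifnot_scalar(indicator_step, "indicator_step", 0, strict = TRUE)
  structure(
    list(burst_coeff = burst_coeff, superburst_coeff = superburst_coeff,
         gaussian_effective_width = gaussian_effective_width,
         width_convention = width_convention,
         indicator_step = indicator_step,
         indicator_center = indicator_center),
    class = "burst_detection_params"
  )
}

# Gaussian sd implied by the configured effective width.
gaussian_sigma <- function(params) {
  switch(params$width_convention,
    fwhm   = params$gaussian_effective_width / (2 * sqrt(2 * log(2))),
    sigma  = params$gaussian_effective_width,
    window = params$gaussian_effective_width / 5
  )
}

#' Calcium event detection parameters
#'
#' @param pulse_coeff Detection accuracy coefficient for ordinary calcium
#'   pulses; the derivative threshold is `pulse_coeff * sd(derivative)`
#'   (default 0.45).
#' @param superosc_coeff Detection accuracy coefficient for superoscillations
#'   (default 0.8).
#' @param lowpass_cutoff Cutoff of the elliptic low-pass filter used before
#'   superoscillation detection, in Hz (default 0.2; removes ordinary short
#'   pulses).
#' @param derivative_avg_pairs Number of subsequent point-pair differences
#'   averaged into each derivative sample for superoscillation detection
#'   (default 20).
#' @param smoothing_points Number of neighboring points averaged before pulse
#'   detection (default 2).
#' @param ellip_order,ellip_rp,ellip_rs Elliptic filter order, passband ripple
#'   (dB) and stopband attenuation (dB); defaults 4, 0.1, 40.
#' @param min_superosc_duration Minimum duration (s) for a detected
#'   superoscillation (default 11, the lower end of the superoscillation
#'   duration class); shorter derivative excursions — including the filtered
#'   footprints of ordinary ~6 s pulses — are discarded.
#' @return A `ca_detection_params` list.
#' @export
ca_detection_params <- function(pulse_coeff = 0.45, superosc_coeff = 0.8,
                                lowpass_cutoff = 0.2,
                                derivative_avg_pairs = 20,
                                smoothing_points = 2,
                                ellip_order = 4, ellip_rp = 0.1,
                                ellip_rs = 40,
                                min_superosc_duration = 11) {
  stopifnot_scalar(pulse_coeff, "pulse_coeff", 0, strict = TRUE)
  stopifnot_scalar(superosc_coeff, "superosc_coeff", 0, strict = TRUE)
  stopifnot_scalar(lowpass_cutoff, "lowpass_cutoff", 0, strict = TRUE)
  stopifnot_scalar(derivative_avg_pairs, "derivative_avg_pairs", 1)
  stopifnot_scalar(smoothing_points, "smoothing_points", 1)
  stopifnot_scalar(min_superosc_duration, "min_superosc_duration", 0)
  structure(
    list(pulse_coeff = pulse_coeff, superosc_coeff = superosc_coeff,
         lowpass_cutoff = lowpass_cutoff,
         derivative_avg_pairs = as.integer(derivative_avg_pairs),
         smoothing_points = as.integer(smoothing_points),
         ellip_order = ellip_order, ellip_rp = ellip_rp, ellip_rs = ellip_rs,
         min_superosc_duration = min_superosc_duration),
    class = "ca_detection_params"
  )
}
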