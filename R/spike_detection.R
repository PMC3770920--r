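# Extracellular spike detection: zero-phase band-pass filtering and a
# median-normalized amplitude threshold per channel.

#' Band-pass filter a recording
#'
#' Applies a Butterworth band-pass (default 0.3--8 kHz) forward-backward
#' (zero-phase) to every channel, preserving spike timing for raster
#' alignment.  The DC component is removed, so a constant input maps to ~0.
#'
#' @param rec A [recording()].
#' @param params A [spike_detection_params()].
#' @param order Butterworth prototype order (default 4).
#' @return A filtered [recording()] of the same shape and units.
#' @export
bandpass_filter <- function(rec, params = spike_detection_params(),
                            order = 4) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sampling_rate / 2
  if (params$band_high >= nyq) {
    stop("`band_high` must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(order, c(params$band_low, params$band_high) / nyq,
                       type = "pass")
  out <- rec$voltage
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- signal::filtfilt(bf, rec$voltage[ch, ])
  }
  recording(out, rec$sampling_rate, rec$channel_ids)
}

#' Robust noise standard deviation of a filtered trace
#'
#' Estimates the noise standard deviation as `median(|x|) / 0.6745`.  The
#' median of the absolute signal is insensitive to sparse large-amplitude
#' spikes, and 0.6745 (the 0.75 quantile of the standard normal) normalizes
#' it to the standard deviation of the spike-free Gaussian noise.
#'
#' @param x Numeric vector, a single band-pass filtered channel.
#' @param normalization_constant Divisor (default 0.6745).
#' @return The noise sigma estimate (same units as `x`).
#' @export
#' @examples
#' estimate_noise_sigma(rnorm(1e5)) # ~1
estimate_noise_sigma <- function(x, normalization_constant = 0.6745) {
  if (length(x) == 0L) stop("`x` must be non-empty", call. = FALSE)
  stats::median(abs(x)) / normalization_constant
}

#' Detect spikes with a median-normalized amplitude threshold
#'
#' Per channel, computes the threshold `T = n_s * sigma` with
#' `sigma = median(|x|) / 0.6745`, finds maximal excursions where `|x| > T`,
#' timestamps each at its absolute-value peak (earliest sample on ties), and
#' enforces the minimal interspike interval per channel: a peak closer than
#' `min_isi` to an already accepted earlier peak is discarded.  Both signal
#' polarities are detected; the amplitude is recorded as the signed value at
#' the peak.
#'
#' @param rec A [recording()].
#' @param params A [spike_detection_params()].
#' @param filter If `TRUE` (default), [bandpass_filter()] is applied first;
#'   set `FALSE` when `rec` is already filtered.
#' @return A [spike_events()] table.  Channels with zero noise sigma yield no
#'   detections (with a warning).
#' @export
detect_spikes <- function(rec, params = spike_detection_params(),
                          filter = TRUE) {
  stopifnot(inherits(rec, "recording"))
  if (ncol(rec$voltage) == 0L) stop("empty recording", call. = FALSE)
  if (filter) rec <- bandpass_filter(rec, params)
  fs <- rec$sampling_rate
  out <- vector("list", nrow(rec$voltage))
  zero_sigma <- character()
  for (ch in seq_len(nrow(rec$voltage))) {
    x <- rec$voltage[ch, ]
    sigma <- estimate_noise_sigma(x, params$normalization_constant)
    if (sigma == 0) {
      zero_sigma <- c(zero_sigma, as.character(rec$channel_ids[ch]))
      next
    }
    thr <- params$n_s * sigma
    runs <- true_runs(abs(x) > thr)
    if (nrow(runs) == 0L) next
    peak_idx <- vapply(seq_len(nrow(runs)), function(i) {
      seg <- runs$i0[i]:runs$i1[i]
      seg[which.max(abs(x[seg]))]   # which.max -> earliest on ties
    }, integer(1))
    tt <- (peak_idx - 1) / fs
    keep <- logical(length(tt))
    last <- -Inf
    for (i in seq_along(tt)) {      # earlier-peak-wins refractoriness
      if (tt[i] - last >= params$min_isi) {
        keep[i] <- TRUE
        last <- tt[i]
      }
    }
    out[[ch]] <- data.frame(channel = rec$channel_ids[ch],
                            time_s = tt[keep],
                            amplitude_uv = x[peak_idx[keep]])
  }
  if (length(zero_sigma) > 0) {
    warning("zero noise sigma on channel(s) ",
            paste(zero_sigma, collapse = ", "),
            "; no spikes detected there", call. = FALSE)
  }
  out <- do.call(rbind, c(out, list(data.frame(channel = integer(),
                                               time_s = numeric(),
                                               amplitude_uv = numeric()))))
  spike_events(out$channel, out$time_s, out$amplitude_uv)
}
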