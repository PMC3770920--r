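# Core data containers.  All are light S3 wrappers around base structures so
# that they print sensibly and can be round-tripped through plain-text files.

#' Construct a multichannel voltage recording
#'
#' @param voltage Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_ids Optional channel labels (default `1:nrow(voltage)`).
#' @return A `recording` object (list with `voltage`, `sampling_rate`,
#'   `channel_ids`).
#' @export
recording <- function(voltage, sampling_rate, channel_ids = NULL) {
  if (is.vector(voltage)) voltage <- matrix(voltage, nrow = 1L)
  if (!is.matrix(voltage) || !is.numeric(voltage)) {
    stop("`voltage` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (anyNA(voltage) || any(!is.finite(voltage))) {
    stop("`voltage` must contain only finite samples", call. = FALSE)
  }
  stopifnot_scalar(sampling_rate, "sampling_rate", 0, strict = TRUE)
  if (is.null(channel_ids)) channel_ids <- seq_len(nrow(voltage))
  if (length(channel_ids) != nrow(voltage)) {
    stop("`channel_ids` must have one label per channel", call. = FALSE)
  }
  structure(
    list(voltage = voltage, sampling_rate = sampling_rate,
         channel_ids = channel_ids),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$voltage), ncol(x$voltage), x$sampling_rate,
              ncol(x$voltage) / x$sampling_rate))
  invisible(x)
}

#' Construct a spike-event table
#'
#' @param channel Channel labels (one per spike).
#' @param time_s Spike times in seconds.
#' @param amplitude_uv Signed peak amplitudes in microvolts (default `NA`).
#' @return A `spike_events` data.frame with columns `channel`, `time_s`,
#'   `amplitude_uv`, sorted by channel then time.
#' @export
spike_events <- function(channel = integer(), time_s = numeric(),
                         amplitude_uv = NULL) {
  if (is.null(amplitude_uv)) amplitude_uv <- rep(NA_real_, length(time_s))
  stopifnot(length(channel) == length(time_s),
            length(amplitude_uv) == length(time_s))
  df <- data.frame(channel = channel, time_s = as.numeric(time_s),
                   amplitude_uv = as.numeric(amplitude_uv))
  df <- df[order(df$channel, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spike_events", "data.frame")
  df
}

#' Construct a labeled interval set
#'
#' Detected bursts, superbursts, calcium pulses and superoscillations are all
#' represented as labeled half-open `[start, end)` intervals.
#'
#' @param label Interval class labels (e.g. `"burst"`, `"superburst"`).
#' @param start,end Interval boundaries in seconds (`start < end` unless the
#'   interval degenerates to a single event).
#' @param n_spikes Optional spike count per interval.
#' @param n_sub_bursts Optional count of constituent small bursts.
#' @return An `interval_set` data.frame sorted by start time.
#' @export
interval_set <- function(label = character(), start = numeric(),
                         end = numeric(), n_spikes = NULL,
                         n_sub_bursts = NULL) {
  n <- length(start)
  stopifnot(length(end) == n, length(label) %in% c(1L, n) || n == 0L)
  if (n > 0L && length(label) == 1L) label <- rep(label, n)
  if (n == 0L) label <- character()
  if (is.null(n_spikes)) n_spikes <- rep(NA_real_, n)
  if (is.null(n_sub_bursts)) n_sub_bursts <- rep(NA_integer_, n)
  if (any(end < start)) stop("interval `end` must be >= `start`", call. = FALSE)
  df <- data.frame(label = as.character(label), start = as.numeric(start),
                   end = as.numeric(end), n_spikes = as.numeric(n_spikes),
                   n_sub_bursts = as.integer(n_sub_bursts))
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Construct a single-cell fluorescence trace
#'
#' ROI-averaged fluorescence in relative units (0--255) sampled at a fixed
#' frame rate, tagged with a neuron/astrocyte label.
#'
#' @param values Numeric vector of fluorescence values in `[0, 255]`.
#' @param sampling_rate Frame rate in Hz (default 4).
#' @param cell_id Cell label.
#' @param cell_type `"neuron"` or `"astrocyte"`.
#' @return A `fluorescence_trace` object.
#' @export
fluorescence_trace <- function(values, sampling_rate = 4,
                               cell_id = "cell1",
                               cell_type = c("neuron", "astrocyte")) {
  cell_type <- match.arg(cell_type)
  stopifnot_scalar(sampling_rate, "sampling_rate", 0, strict = TRUE)
  values <- as.numeric(values)
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  if (any(values < 0 | values > 255)) {
    stop("fluorescence `values` must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(values = values, sampling_rate = sampling_rate, cell_id = cell_id,
         cell_type = cell_type),
    class = "fluorescence_trace"
  )
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %s (%s): %d frames @ %g Hz (%.1f s)\n",
              x$cell_id, x$cell_type, length(x$values), x$sampling_rate,
              length(x$values) / x$sampling_rate))
  invisible(x)
}

# Times of a trace's samples, first frame at t = 0.
trace_times <- function(trace) {
  (seq_along(trace$values) - 1) / trace$sampling_rate
}
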