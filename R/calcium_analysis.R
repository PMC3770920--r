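# Calcium transient detection from ROI-averaged fluorescence: ordinary
# pulses from the raw derivative, long superoscillations from the derivative
# of an elliptic low-pass filtered trace.

#' Extract an ROI-averaged fluorescence trace from an image stack
#'
#' @param stack Numeric array `height x width x frames`.
#' @param mask Logical matrix `height x width`; `TRUE` pixels belong to the
#'   cell region.
#' @param sampling_rate Frame rate in Hz (default 4).
#' @param cell_id,cell_type Forwarded to [fluorescence_trace()].
#' @return A [fluorescence_trace()] whose value in each frame is the
#'   arithmetic mean of the in-mask pixels.
#' @export
extract_trace <- function(stack, mask, sampling_rate = 4,
                          cell_id = "cell1", cell_type = "neuron") {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    stop("`stack` must be a height x width x frames array", call. = FALSE)
  }
  if (!is.matrix(mask) || !identical(dim(mask), dim(stack)[1:2])) {
    stop("`mask` must be a logical matrix matching the frame size",
         call. = FALSE)
  }
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  n_frames <- dim(stack)[3]
  vals <- vapply(seq_len(n_frames), function(f) {
    mean(stack[, , f][mask])
  }, numeric(1))
  fluorescence_trace(vals, sampling_rate, cell_id, cell_type)
}

# Pair signed threshold crossings of a derivative into [onset, end) events.
# Onset: d rises above +theta.  End: completion of the next excursion below
# -theta (the transient's falling phase), i.e. the last point of that run.
# An onset with no completed negative excursion before the trace ends is
# closed at the final sample and flagged as truncated.
pair_derivative_events <- function(d, theta, fs) {
  n <- length(d)
  starts <- integer(); ends <- integer(); trunc <- logical()
  i <- 1L
  while (i <= n) {
    if (d[i] > theta) {
      onset <- i
      j <- onset
      while (j <= n && !(d[j] < -theta)) j <- j + 1L
      if (j > n) {
        starts <- c(starts, onset); ends <- c(ends, n)
        trunc <- c(trunc, TRUE)
        break
      }
      while (j < n && d[j + 1L] < -theta) j <- j + 1L
      starts <- c(starts, onset); ends <- c(ends, j)
      trunc <- c(trunc, FALSE)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts / fs, end = ends / fs, truncated = trunc)
}

#' Detect ordinary calcium pulses
#'
#' The trace is smoothed by averaging two neighboring points, differenced
#' into a simple derivative, and thresholded at
#' `pulse_coeff * sd(derivative)` (default coefficient 0.45).  Suprathreshold
#' points of the derivative mark the beginnings (rise, `> +threshold`) and
#' endings (completion of the fall, `< -threshold`) of the pulses.
#'
#' @param trace A [fluorescence_trace()].
#' @param params A [ca_detection_params()].
#' @return A `ca_events` data.frame with columns `cell_id`, `kind`
#'   (`"pulse"`), `start`, `end`, `duration` (seconds) and `truncated`
#'   (`TRUE` for an onset closed at the trace end).  A constant trace yields
#'   no events (with a warning).
#' @export
detect_ca_pulses <- function(trace, params = ca_detection_params()) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  x <- trace$values
  if (length(x) <= params$smoothing_points + 1L) {
    stop("trace too short for pulse detection", call. = FALSE)
  }
  k <- params$smoothing_points
  y <- stats::filter(x, rep(1 / k, k), sides = 1)
  y <- y[!is.na(y)]
  d <- diff(y)
  sdd <- stats::sd(d)
  if (is.na(sdd) || sdd == 0) {
    warning("constant trace: no pulses detected", call. = FALSE)
    return(ca_events_frame(trace$cell_id, "pulse"))
  }
  theta <- params$pulse_coeff * sdd
  ev <- pair_derivative_events(d, theta, trace$sampling_rate)
  ca_events_frame(trace$cell_id, "pulse", ev)
}

# Low-pass filter a trace with mirror padding so that the forward-backward
# elliptic filter sees no step at the trace boundaries (the filter state
# starts at zero, so an unpadded constant baseline produces a large spurious
# edge transient).
lowpass_trace <- function(x, fs, params) {
  ef <- signal::ellip(params$ellip_order, params$ellip_rp, params$ellip_rs,
                      params$lowpass_cutoff / (fs / 2), type = "low")
  np <- min(length(x) - 1L, ceiling(10 * fs / params$lowpass_cutoff))
  xp <- c(x[(np + 1L):2L], x, x[(length(x) - 1L):(length(x) - np)])
  mu <- mean(xp)
  xf <- signal::filtfilt(ef, xp - mu) + mu
  xf[(np + 1L):(np + length(x))]
}

# Pair excursions of the slow (m-pair averaged, causal) derivative D into
# superoscillation intervals.  D[i] = (xf[i+m] - xf[i]) / m, so a rising
# edge starting at sample s produces a positive excursion beginning at
# s - m (the look-ahead window first touches the edge); the onset is
# therefore the first suprathreshold sample + m.  A falling edge ending at
# sample e produces a negative excursion ending at e itself.  The matching
# negative excursion is the first one after which the filtered signal has
# given back at least half of its elevation above the onset level
# (level closure); this skips brief dips caused by short transients riding
# on a long plateau.  Unmatched onsets are closed at the trace end and
# flagged as truncated.
so_pair_events <- function(D, xf, theta, m, fs) {
  n <- length(D)
  r <- rle(D < -theta)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  neg_start <- run_start[r$values]
  neg_end <- run_end[r$values]
  starts <- numeric(); ends <- numeric(); trunc <- logical()
  i <- 1L
  while (i <= n) {
    if (D[i] > theta) {
      onset_i <- min(i + m, length(xf))
      level <- xf[onset_i]
      cand <- which(neg_start > i)
      end_i <- NA_integer_
      for (k in cand) {
        ei <- min(neg_end[k], length(xf))
        peak <- max(xf[onset_i:ei])
        if (xf[ei] <= level + 0.5 * (peak - level)) {
          end_i <- neg_end[k]
          break
        }
      }
      if (is.na(end_i)) {
        starts <- c(starts, onset_i / fs)
        ends <- c(ends, length(xf) / fs)
        trunc <- c(trunc, TRUE)
        break
      }
      starts <- c(starts, onset_i / fs)
      ends <- c(ends, end_i / fs)
      trunc <- c(trunc, FALSE)
      i <- end_i + 1L
    } else {
      i <- i + 1L
    }
  }
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep],
             truncated = trunc[keep])
}

#' Detect calcium superoscillations
#'
#' The trace is low-pass filtered with a zero-phase elliptic filter (cutoff
#' 0.2 Hz by default), which removes regular short calcium pulses.  Each
#' point of the derivative is the average of the differences of the next
#' `derivative_avg_pairs` (20) pairs of points; this slow derivative is
#' thresholded at `superosc_coeff * sd(derivative)` (default coefficient
#' 0.8).  An onset is the start of the rising edge implied by a positive
#' excursion (first suprathreshold sample plus the averaging window, since
#' the causal window "sees" an edge one window early); the end is the last
#' sample of the matching negative excursion, i.e. the first one after
#' which the filtered signal has returned at least halfway to the onset
#' level, so that brief dips from short transients riding on a plateau do
#' not split it.  Events shorter than `min_superosc_duration` (default 11 s,
#' the lower end of the superoscillation duration class) are discarded;
#' this is what makes the detector insensitive to ordinary short (~6 s)
#' pulses, whose filtered footprint stays well below that floor.
#'
#' @param trace A [fluorescence_trace()].
#' @param params A [ca_detection_params()].
#' @return A `ca_events` data.frame as in [detect_ca_pulses()], with kind
#'   `"superoscillation"`.
#' @export
detect_superoscillations <- function(trace, params = ca_detection_params()) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  fs <- trace$sampling_rate
  if (params$lowpass_cutoff >= fs / 2) {
    stop("`lowpass_cutoff` must be below the Nyquist frequency",
         call. = FALSE)
  }
  x <- trace$values
  min_len <- ceiling(10 * fs / params$lowpass_cutoff)
  if (length(x) < min_len) {
    stop("trace too short for the low-pass filter warm-up", call. = FALSE)
  }
  xf <- lowpass_trace(x, fs, params)
  dd <- diff(xf)
  m <- params$derivative_avg_pairs
  if (length(dd) <= m) stop("trace too short", call. = FALSE)
  # causal sliding mean over the next m first differences
  cs <- c(0, cumsum(dd))
  idx <- seq_len(length(dd) - m + 1L)
  D <- (cs[idx + m] - cs[idx]) / m
  sdD <- stats::sd(D)
  if (is.na(sdD) || sdD == 0) {
    warning("constant trace: no superoscillations detected", call. = FALSE)
    return(ca_events_frame(trace$cell_id, "superoscillation"))
  }
  theta <- params$superosc_coeff * sdD
  ev <- so_pair_events(D, xf, theta, m, fs)
  ev <- ev[ev$end - ev$start >= params$min_superosc_duration, , drop = FALSE]
  ca_events_frame(trace$cell_id, "superoscillation", ev)
}

ca_events_frame <- function(cell_id, kind, ev = NULL) {
  if (is.null(ev) || nrow(ev) == 0L) {
    df <- data.frame(cell_id = character(), kind = character(),
                     start = numeric(), end = numeric(),
                     duration = numeric(), truncated = logical())
  } else {
    df <- data.frame(cell_id = cell_id, kind = kind, start = ev$start,
                     end = ev$end, duration = ev$end - ev$start,
                     truncated = ev$truncated)
  }
  class(df) <- c("ca_events", "data.frame")
  df
}

#' Calcium event statistics by cell type
#'
#' @param events A `ca_events` data.frame (rows from one or more cells,
#'   possibly both kinds).
#' @param traces A list of [fluorescence_trace()]s covering every `cell_id`
#'   in `events`; supplies each cell's type and recording length.
#' @param window Span in seconds used for the per-10-min rate normalization;
#'   defaults to the longest trace.
#' @return A data.frame with one row per (cell_type, kind) present: `n_cells`,
#'   `mean_duration`, `sem_duration`, `events_per_10min`, `sem_events`
#'   (mean +/- SEM across cells).  Cell types with no cells are absent, not
#'   zero.
#' @export
ca_statistics <- function(events, traces, window = NULL) {
  types <- vapply(traces, function(tr) tr$cell_type, character(1))
  ids <- vapply(traces, function(tr) tr$cell_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate cell ids in `traces`", call. = FALSE)
  if (nrow(events) > 0 && !all(events$cell_id %in% ids)) {
    stop("`events` refers to cells absent from `traces`", call. = FALSE)
  }
  if (is.null(window)) {
    window <- max(vapply(traces, function(tr) {
      length(tr$values) / tr$sampling_rate
    }, numeric(1)))
  }
  out <- list()
  for (ty in unique(types)) {
    cells <- ids[types == ty]
    for (kind in unique(events$kind)) {
      per_cell_dur <- numeric(); per_cell_n <- numeric()
      for (cid in cells) {
        ev <- events[events$cell_id == cid & events$kind == kind, ,
                     drop = FALSE]
        per_cell_n <- c(per_cell_n, nrow(ev) / window * 600)
        per_cell_dur <- c(per_cell_dur,
                          if (nrow(ev)) mean(ev$duration) else NA_real_)
      }
      out[[length(out) + 1L]] <- data.frame(
        cell_type = ty, kind = kind, n_cells = length(cells),
        mean_duration = mean(per_cell_dur, na.rm = TRUE),
        sem_duration = sem(per_cell_dur),
        events_per_10min = mean(per_cell_n),
        sem_events = sem(per_cell_n))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cell_type = character(), kind = character(),
                      n_cells = integer(), mean_duration = numeric(),
                      sem_duration = numeric(), events_per_10min = numeric(),
                      sem_events = numeric()))
  }
  do.call(rbind, out)
}
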