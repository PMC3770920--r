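# Brute-force reference implementations used for oracle-equivalence tests.
# Deliberately written as plain index-walking loops, structurally independent
# of the rle/vectorized production code.

# Threshold-scan burst oracle on a TSR count vector (bin-edge intervals).
oracle_bursts <- function(counts, bin_width, threshold, start_time = 0) {
  starts <- numeric(); ends <- numeric()
  in_run <- FALSE
  for (i in seq_along(counts)) {
    if (counts[i] > threshold && !in_run) {
      in_run <- TRUE
      run_start <- i
    }
    if (in_run && (i == length(counts) || counts[i] <= threshold)) {
      run_end <- if (counts[i] > threshold) i else i - 1L
      starts <- c(starts, start_time + (run_start - 1L) * bin_width)
      ends <- c(ends, start_time + run_end * bin_width)
      in_run <- FALSE
    }
  }
  data.frame(start = starts, end = ends)
}

# Signed-pairing pulse oracle: onset where d > +theta, end at the last
# point of the first subsequent excursion below -theta.
oracle_pulses <- function(d, theta, fs) {
  starts <- numeric(); ends <- numeric(); trunc <- logical()
  i <- 1L
  n <- length(d)
  while (i <= n) {
    if (d[i] > theta) {
      j <- i
      while (j <= n && d[j] >= -theta) j <- j + 1L
      if (j > n) {
        starts <- c(starts, i / fs); ends <- c(ends, n / fs)
        trunc <- c(trunc, TRUE)
        break
      }
      while (j + 1L <= n && d[j + 1L] < -theta) j <- j + 1L
      starts <- c(starts, i / fs); ends <- c(ends, j / fs)
      trunc <- c(trunc, FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends, truncated = trunc)
}

# Superoscillation oracle on the slow derivative D and filtered trace xf:
# onset = first suprathreshold sample + m (causal window geometry); end =
# last sample of the first negative excursion after which xf has returned
# at least halfway from its running peak to the onset level.
oracle_superosc <- function(D, xf, theta, m, fs) {
  starts <- numeric(); ends <- numeric(); trunc <- logical()
  i <- 1L
  n <- length(D)
  while (i <= n) {
    if (D[i] > theta) {
      onset_i <- min(i + m, length(xf))
      level <- xf[onset_i]
      j <- i
      end_i <- NA_integer_
      while (j <= n) {
        if (D[j] < -theta) {
          k <- j
          while (k + 1L <= n && D[k + 1L] < -theta) k <- k + 1L
          ei <- min(k, length(xf))
          peak <- max(xf[onset_i:ei])
          if (xf[ei] <= level + 0.5 * (peak - level)) {
            end_i <- k
            break
          }
          j <- k + 1L
        } else j <- j + 1L
      }
      if (is.na(end_i)) {
        starts <- c(starts, onset_i / fs); ends <- c(ends, length(xf) / fs)
        trunc <- c(trunc, TRUE)
        break
      }
      starts <- c(starts, onset_i / fs); ends <- c(ends, end_i / fs)
      trunc <- c(trunc, FALSE)
      i <- end_i + 1L
    } else i <- i + 1L
  }
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep], truncated = trunc[keep])
}

# Recompute the slow derivative and filtered trace the way the detector
# documents them, for feeding the superoscillation oracle.
slow_derivative <- function(trace, params = ca_detection_params()) {
  xf <- meaburst:::lowpass_trace(trace$values, trace$sampling_rate, params)
  dd <- diff(xf)
  m <- params$derivative_avg_pairs
  cs <- c(0, cumsum(dd))
  idx <- seq_len(length(dd) - m + 1L)
  list(D = (cs[idx + m] - cs[idx]) / m, xf = xf, m = m)
}

# Simple synthetic trace builders (independent of the package generator).
flat_trace <- function(duration = 600, fs = 4, baseline = 60,
                       cell_id = "c1", cell_type = "neuron") {
  fluorescence_trace(rep(baseline, duration * fs), fs, cell_id, cell_type)
}

add_pulse <- function(values, fs, onset, len, amp = 40, rise_frac = 0.2) {
  tt <- (seq_along(values) - 1) / fs
  rise <- rise_frac * len
  tau <- (len - rise) / 3
  rel <- tt - onset
  shape <- ifelse(rel < 0 | rel >= len, 0,
                  ifelse(rel < rise, rel / rise, exp(-(rel - rise) / tau)))
  values + amp * shape
}

add_plateau <- function(values, fs, onset, len, amp = 50, ramp = 2) {
  tt <- (seq_along(values) - 1) / fs
  rel <- tt - onset
  shape <- ifelse(rel < 0 | rel >= len, 0,
                  pmin(1, pmin(rel / ramp, (len - rel) / ramp)))
  values + amp * shape
}

# Build a spike_events table with given pooled spike times on one channel.
spikes_at <- function(times, channel = 1L, amplitude = -40) {
  spike_events(channel = rep(channel, length(times)), time_s = times,
               amplitude_uv = rep(amplitude, length(times)))
}

# "No additional detections" check for interval detectors: every interval
# detected at a stricter coefficient must overlap an interval detected at
# the looser one, and the total detected time must not grow.  (The *count*
# of detected intervals is provably non-monotone in the threshold: raising
# it can split one merged run into two.)
expect_nested_detections <- function(loose, strict) {
  if (nrow(strict) > 0 && nrow(loose) > 0) {
    covered <- vapply(seq_len(nrow(strict)), function(i) {
      any(loose$start < strict$end[i] & loose$end > strict$start[i])
    }, logical(1))
    expect_true(all(covered))
  } else {
    expect_equal(nrow(strict), 0L)
  }
  expect_lte(sum(strict$end - strict$start),
             sum(loose$end - loose$start) + 1e-9)
}

# "No additional detections" check for excursion-pairing detectors whose
# interval END is tied to a matching negative crossing of the same
# threshold (calcium superoscillations): nestedness does not hold there,
# because raising the threshold can disqualify the previously matched
# negative excursion and extend the interval past the looser one.  The
# faithful monotone property is trigger containment: every event detected
# at the stricter coefficient must *begin* inside the span of an event
# detected at the looser one.  `tol` allows two samples of grid slack at
# 4 Hz.
expect_trigger_containment <- function(loose, strict, tol = 0.5) {
  if (nrow(strict) == 0) {
    succeed()
    return(invisible())
  }
  expect_gt(nrow(loose), 0)
  ok <- vapply(strict$start, function(o) {
    any(loose$start - tol <= o & o <= loose$end)
  }, logical(1))
  expect_true(all(ok))
}
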