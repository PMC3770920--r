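# Network burst and superburst detection from the pooled total spiking rate
# (TSR), and the burst-train statistics used to characterize seizure-like
# activity.

#' Compute the total spiking rate (TSR)
#'
#' Pools spike times over all electrodes and counts them in consecutive
#' half-open bins `[t, t + bin_width)` (default 50 ms).
#'
#' @param spikes A [spike_events()] table (or any data.frame with `time_s`).
#' @param bin_width Bin width in seconds (default 0.05).
#' @param span Analyzed span `c(start, end)` in seconds; defaults to
#'   `c(0, max(time))` rounded up to a whole bin.
#' @return A `tsr` object: list with integer `counts`, `bin_width` and
#'   `start_time`.  `sum(counts)` equals the number of spikes inside the span.
#' @export
compute_tsr <- function(spikes, bin_width = 0.05, span = NULL) {
  stopifnot_scalar(bin_width, "bin_width", 0, strict = TRUE)
  t <- spikes$time_s
  if (is.null(span)) {
    end <- if (length(t)) max(t) + bin_width else bin_width
    span <- c(0, end)
  }
  if (span[2] <= span[1]) stop("empty span", call. = FALSE)
  n_bins <- ceiling((span[2] - span[1]) / bin_width - 1e-9)
  t <- t[t >= span[1] & t < span[1] + n_bins * bin_width]
  counts <- tabulate(floor((t - span[1]) / bin_width) + 1L, nbins = n_bins)
  structure(list(counts = as.integer(counts), bin_width = bin_width,
                 start_time = span[1]),
            class = "tsr")
}

#' @export
print.tsr <- function(x, ...) {
  cat(sprintf("<tsr> %d bins x %g ms from t = %g s (%d spikes)\n",
              length(x$counts), 1000 * x$bin_width, x$start_time,
              sum(x$counts)))
  invisible(x)
}

# Bin center times of a TSR.
tsr_centers <- function(tsr) {
  tsr$start_time + (seq_along(tsr$counts) - 0.5) * tsr$bin_width
}

#' Detect network bursts from the TSR
#'
#' The burst threshold is `burst_coeff * sd(TSR)` over the full analyzed span
#' (default coefficient 0.1, chosen to exclude basal activity).  Maximal runs
#' of bins with `TSR > threshold` become bursts.  With `refine = "bins"` a
#' burst spans from the left edge of its first suprathreshold bin to the
#' right edge of its last; with `refine = "spikes"` (requires `spikes`) the
#' boundaries are snapped to the first and last pooled spike inside that bin
#' range --- the burst initiation and ending points as recognized in the
#' raster diagram.  Bin-edge intervals overestimate short burst durations by
#' up to one bin per edge (see the methods vignette); spike refinement
#' removes that quantization.
#'
#' @param tsr A [compute_tsr()] result.
#' @param params A [burst_detection_params()].
#' @param spikes Optional [spike_events()] table, required for
#'   `refine = "spikes"`.
#' @param refine Boundary convention, `"bins"` (default) or `"spikes"`.
#' @return An [interval_set()] with label `"burst"` and `n_spikes` = sum of
#'   TSR counts in each burst's bins.  A zero-variance TSR yields no bursts
#'   (with a warning).
#' @export
detect_bursts <- function(tsr, params = burst_detection_params(),
                          spikes = NULL, refine = c("bins", "spikes")) {
  stopifnot(inherits(tsr, "tsr"))
  refine <- match.arg(refine)
  if (refine == "spikes" && is.null(spikes)) {
    stop("`refine = \"spikes\"` requires the `spikes` table", call. = FALSE)
  }
  sigma <- stats::sd(tsr$counts)
  if (is.na(sigma) || sigma == 0) {
    warning("zero-variance TSR: no bursts detected", call. = FALSE)
    return(interval_set())
  }
  thr <- params$burst_coeff * sigma
  runs <- true_runs(tsr$counts > thr)
  if (nrow(runs) == 0L) return(interval_set())
  start <- tsr$start_time + (runs$i0 - 1L) * tsr$bin_width
  end <- tsr$start_time + runs$i1 * tsr$bin_width
  n_spikes <- vapply(seq_len(nrow(runs)), function(i) {
    sum(tsr$counts[runs$i0[i]:runs$i1[i]])
  }, numeric(1))
  if (refine == "spikes") {
    t <- sort(spikes$time_s)
    for (i in seq_along(start)) {
      inside <- t[t >= start[i] & t < end[i]]
      if (length(inside) > 0L) {
        start[i] <- inside[1L]
        end[i] <- inside[length(inside)]
      }
    }
    keep <- end > start
    start <- start[keep]; end <- end[keep]; n_spikes <- n_spikes[keep]
  }
  out <- interval_set("burst", start, end, n_spikes = n_spikes)
  attr(out, "threshold") <- thr
  out
}

#' Gaussian-window superburst indicator
#'
#' Slides a Gaussian window (effective width 50 s by default) along the
#' recording in `indicator_step` (10 ms) increments and evaluates the
#' weight-normalized Gaussian-weighted average of the TSR at each position ---
#' the cross-correlation of the window with the TSR, expressed in TSR units
#' so that a constant TSR gives a constant indicator.  Window weights are
#' truncated and renormalized at the recording edges.
#'
#' @param tsr A [compute_tsr()] result; its span must be at least the
#'   window's effective width.
#' @param params A [burst_detection_params()].
#' @return An `sb_indicator` object: list with `time`, `value`, `step`,
#'   `sigma_g` (the Gaussian sd in seconds).
#' @export
superburst_indicator <- function(tsr, params = burst_detection_params()) {
  stopifnot(inherits(tsr, "tsr"))
  span <- length(tsr$counts) * tsr$bin_width
  if (span < params$gaussian_effective_width) {
    stop("recording span is shorter than the Gaussian window", call. = FALSE)
  }
  sig <- gaussian_sigma(params)
  bw <- tsr$bin_width
  half <- ceiling(4 * sig / bw)
  kern <- stats::dnorm(seq(-half, half) * bw, sd = sig)
  counts <- as.numeric(tsr$counts)
  n <- length(counts)
  # truncated-renormalized Gaussian average on the bin grid via FFT
  # convolution of both the counts and the edge-normalization mass
  num <- conv_same(counts, kern)
  den <- conv_same(rep(1, n), kern)
  vals_bins <- num / den
  centers <- tsr_centers(tsr)
  t_out <- seq(tsr$start_time, tsr$start_time + span,
               by = params$indicator_step)
  v_out <- stats::approx(centers, vals_bins, xout = t_out, rule = 2)$y
  structure(list(time = t_out, value = v_out, step = params$indicator_step,
                 sigma_g = sig),
            class = "sb_indicator")
}

# "Same"-length linear convolution of x with a symmetric kernel centered on
# each sample.
conv_same <- function(x, kern) {
  half <- (length(kern) - 1L) / 2L
  full <- stats::convolve(x, rev(kern), type = "open")
  full[(half + 1L):(half + length(x))]
}

#' @export
print.sb_indicator <- function(x, ...) {
  cat(sprintf(
    "<sb_indicator> %d points, step %g ms, Gaussian sigma %.2f s\n",
    length(x$value), 1000 * x$step, x$sigma_g))
  invisible(x)
}

#' Detect superbursts from the indicator
#'
#' Thresholds the indicator at `superburst_coeff * sd(indicator)` (default
#' coefficient 0.4).  With the default `indicator_center = "mean"` the
#' threshold is referred to the indicator mean (crossings of
#' `mean + 0.4 * sd`); with `"none"` the raw indicator values are compared
#' with `0.4 * sd` directly.  Maximal suprathreshold runs become superbursts;
#' the time points that cross the threshold are the beginnings and endings.
#'
#' @param indicator A [superburst_indicator()] result.
#' @param params A [burst_detection_params()].
#' @param bursts Optional [interval_set()] of small bursts; when given, each
#'   superburst is annotated with `n_sub_bursts`, the number of bursts whose
#'   midpoint lies inside it.
#' @param refine Boundary convention.  `"none"` (default) reports the raw
#'   threshold crossings.  `"bursts"` (requires `bursts`) exploits the
#'   defining property of a superburst --- a dense run of network bursts with
#'   a short interburst interval --- to remove the smoothing bias of the wide
#'   Gaussian window: within each crossing window, the superburst is the
#'   largest run of consecutive bursts whose gaps are all
#'   `<= max_intra_ibi`, and its boundaries are that run's first burst onset
#'   and last burst end.  Windows containing no run of at least
#'   `min_sub_bursts` bursts are discarded as threshold-skimming
#'   fluctuations.
#' @param max_intra_ibi Largest within-superburst interburst gap in seconds
#'   (default 0.5, well below typical out-of-superburst interburst intervals
#'   of 1--2.5 s).
#' @param min_sub_bursts Minimal number of bursts in a superburst run
#'   (default 5; a superburst consists of a large number of bursts, while
#'   chance runs of short gaps in ordinary activity rarely exceed 3--4).
#' @return An [interval_set()] with label `"superburst"`.  A zero-variance
#'   indicator yields none (with a warning).
#' @export
detect_superbursts <- function(indicator, params = burst_detection_params(),
                               bursts = NULL,
                               refine = c("none", "bursts"),
                               max_intra_ibi = 0.5, min_sub_bursts = 5) {
  refine <- match.arg(refine)
  if (refine == "bursts" && is.null(bursts)) {
    stop("`refine = \"bursts\"` requires the `bursts` interval set",
         call. = FALSE)
  }
  stopifnot(inherits(indicator, "sb_indicator"))
  v <- indicator$value
  sigma <- stats::sd(v)
  if (is.na(sigma) || sigma == 0) {
    warning("zero-variance indicator: no superbursts detected",
            call. = FALSE)
    return(interval_set())
  }
  base <- if (params$indicator_center == "mean") mean(v) else 0
  thr <- base + params$superburst_coeff * sigma
  runs <- true_runs(v > thr)
  if (nrow(runs) == 0L) return(interval_set())
  start <- indicator$time[runs$i0]
  end <- indicator$time[runs$i1] + indicator$step
  n_sub <- rep(NA_integer_, length(start))
  n_spk <- rep(NA_real_, length(start))
  if (!is.null(bursts) && nrow(bursts) > 0) {
    mid <- (bursts$start + bursts$end) / 2
    if (refine == "bursts") {
      keep <- logical(length(start))
      for (i in seq_along(start)) {
        inside <- which(mid >= start[i] & mid < end[i])
        run <- densest_burst_run(bursts[inside, , drop = FALSE],
                                 max_intra_ibi, min_sub_bursts)
        if (is.null(run)) next
        keep[i] <- TRUE
        start[i] <- run$start
        end[i] <- run$end
        n_sub[i] <- run$n
        n_spk[i] <- run$n_spikes
      }
      start <- start[keep]; end <- end[keep]
      n_sub <- n_sub[keep]; n_spk <- n_spk[keep]
    } else {
      for (i in seq_along(start)) {
        inside <- mid >= start[i] & mid < end[i]
        n_sub[i] <- sum(inside)
        n_spk[i] <- sum(bursts$n_spikes[inside])
      }
    }
  } else if (refine == "bursts") {
    return(interval_set())
  }
  out <- interval_set("superburst", start, end, n_spikes = n_spk,
                      n_sub_bursts = n_sub)
  attr(out, "threshold") <- thr
  out
}

# Largest run of consecutive bursts whose end->start gaps are all
# <= max_gap; NULL when no run reaches min_n bursts.
densest_burst_run <- function(bursts, max_gap, min_n) {
  n <- nrow(bursts)
  if (n < min_n) return(NULL)
  gaps <- bursts$start[-1L] - bursts$end[-n]
  grp <- cumsum(c(0, gaps > max_gap))
  sizes <- table(grp)
  best <- as.integer(names(sizes)[which.max(sizes)])
  if (max(sizes) < min_n) return(NULL)
  idx <- which(grp == best)
  list(start = bursts$start[idx[1L]], end = bursts$end[idx[length(idx)]],
       n = length(idx), n_spikes = sum(bursts$n_spikes[idx]))
}

#' Burst-train statistics
#'
#' Summarizes detected bursts and superbursts the way culture activity is
#' reported: counts per 10 minutes, mean durations, mean interburst interval
#' (gap between consecutive burst end and next burst start) and mean spikes
#' per burst.
#'
#' @param intervals An [interval_set()] containing `"burst"` and/or
#'   `"superburst"` rows (concatenate with `rbind` if detected separately).
#' @param window Analyzed span in seconds used for rate normalization.
#' @return A `burst_stats` list with `bursts_per_10min`,
#'   `mean_burst_duration`, `mean_interburst_interval`,
#'   `mean_spikes_per_burst`, `superbursts_per_10min`,
#'   `mean_superburst_duration`.  With fewer than two bursts the interburst
#'   interval is `NA`.
#' @export
burst_statistics <- function(intervals, window) {
  stopifnot_scalar(window, "window", 0, strict = TRUE)
  b <- intervals[intervals$label == "burst", , drop = FALSE]
  s <- intervals[intervals$label == "superburst", , drop = FALSE]
  ibi <- if (nrow(b) >= 2L) {
    mean(b$start[-1L] - b$end[-nrow(b)])
  } else NA_real_
  structure(list(
    bursts_per_10min = nrow(b) / window * 600,
    mean_burst_duration = if (nrow(b)) mean(b$end - b$start) else NA_real_,
    mean_interburst_interval = ibi,
    mean_spikes_per_burst = if (nrow(b)) mean(b$n_spikes) else NA_real_,
    superbursts_per_10min = nrow(s) / window * 600,
    mean_superburst_duration =
      if (nrow(s)) mean(s$end - s$start) else NA_real_
  ), class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat("<burst_stats>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
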