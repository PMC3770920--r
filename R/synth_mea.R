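# Synthetic MEA activity: nested point-process simulation of background
# spiking, network bursts and seizure-like superbursts, plus optional
# voltage-level synthesis for end-to-end testing of spike detection.

#' Configuration for synthetic MEA spike/voltage generation
#'
#' Rates follow the reporting convention of culture electrophysiology:
#' bursts and superbursts are configured per 10 minutes of recording,
#' per-electrode spiking in spikes per second.
#'
#' @param n_electrodes Number of electrodes (default 64, an 8 x 8 array).
#' @param sampling_rate Voltage sampling rate in Hz (default 20000).
#' @param duration Recording length in seconds (default 600).
#' @param background_rate Basal stochastic firing rate, spikes/s/electrode.
#' @param burst_rate Network bursts per 10 min occurring *outside*
#'   superbursts; bursts inside superbursts are generated on top of this (see
#'   `expected_burst_count()`).
#' @param burst_duration_mean,burst_duration_sd Burst duration distribution
#'   in seconds.
#' @param burst_duration_dist `"normal"` (truncated at `min_burst_duration`)
#'   or `"uniform"` (on `mean +/- sqrt(3) * sd`).
#' @param within_burst_rate Firing rate inside a burst, spikes/s/electrode.
#' @param superburst_rate Superbursts per 10 min.
#' @param superburst_duration_mean,superburst_duration_sd Superburst duration
#'   distribution in seconds.
#' @param intra_superburst_burst_interval Gap between consecutive bursts
#'   inside a superburst, seconds (the short interburst interval that makes a
#'   superburst a dense run of bursts).
#' @param min_burst_gap Minimal gap between bursts outside superbursts,
#'   seconds; keeps distinct bursts resolvable at the 50 ms analysis bin.
#' @param spike_amplitude_mean,spike_amplitude_sd Spike peak amplitude
#'   distribution in microvolts; draws are truncated below at
#'   `spike_amplitude_floor`.
#' @param spike_amplitude_floor Smallest generated spike amplitude in
#'   microvolts (default 20, the smallest amplitude reliably detected at a
#'   4-sigma threshold over a 5 uV noise floor).
#' @param noise_sigma Voltage noise standard deviation in microvolts.
#' @param seed Integer seed; all sub-streams (event placement, spike times,
#'   amplitudes, noise) derive from it.
#' @return A `mea_synth_config` list.
#' @seealso [mea_preset()] for configurations matching the experimental
#'   regimes, [generate_spike_trains()], [generate_voltage()].
#' @export
mea_synth_config <- function(n_electrodes = 64, sampling_rate = 20000,
                             duration = 600,
                             background_rate = 0.1,
                             burst_rate = 250,
                             burst_duration_mean = 0.2,
                             burst_duration_sd = 0.05,
                             burst_duration_dist = c("normal", "uniform"),
                             within_burst_rate = 50,
                             superburst_rate = 0,
                             superburst_duration_mean = 10.5,
                             superburst_duration_sd = 2,
                             intra_superburst_burst_interval = 0.2,
                             min_burst_gap = 0.1,
                             spike_amplitude_mean = 60,
                             spike_amplitude_sd = 15,
                             spike_amplitude_floor = 20,
                             noise_sigma = 5,
                             seed = 1L) {
  burst_duration_dist <- match.arg(burst_duration_dist)
  stopifnot_scalar(n_electrodes, "n_electrodes", 1)
  stopifnot_scalar(sampling_rate, "sampling_rate", 0, strict = TRUE)
  stopifnot_scalar(duration, "duration", 0, strict = TRUE)
  for (nm in c("background_rate", "burst_rate", "burst_duration_mean",
               "burst_duration_sd", "within_burst_rate", "superburst_rate",
               "superburst_duration_mean", "superburst_duration_sd",
               "intra_superburst_burst_interval", "min_burst_gap",
               "spike_amplitude_mean", "spike_amplitude_sd",
               "spike_amplitude_floor", "noise_sigma")) {
    stopifnot_scalar(get(nm), nm, 0)
  }
  stopifnot_scalar(seed, "seed")
  structure(
    list(n_electrodes = as.integer(n_electrodes),
         sampling_rate = sampling_rate, duration = duration,
         background_rate = background_rate, burst_rate = burst_rate,
         burst_duration_mean = burst_duration_mean,
         burst_duration_sd = burst_duration_sd,
         burst_duration_dist = burst_duration_dist,
         within_burst_rate = within_burst_rate,
         superburst_rate = superburst_rate,
         superburst_duration_mean = superburst_duration_mean,
         superburst_duration_sd = superburst_duration_sd,
         intra_superburst_burst_interval = intra_superburst_burst_interval,
         min_burst_gap = min_burst_gap,
         spike_amplitude_mean = spike_amplitude_mean,
         spike_amplitude_sd = spike_amplitude_sd,
         spike_amplitude_floor = spike_amplitude_floor,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "mea_synth_config"
  )
}

#' Preset configurations for the experimental regimes
#'
#' Returns an [mea_synth_config()] whose burst/superburst statistics match the
#' group means reported for cultured hippocampal networks: control cultures
#' show ~257 bursts/10 min with rare short superbursts (1.5 per 10 min,
#' mean duration 10.5 s on DIV 26), while hyaluronidase-treated cultures
#' develop more bursts (513.3, 712 and 827 per 10 min on DIV 19, 20 and 26)
#' and, by DIV 26, frequent long seizure-like superbursts (3.3 per 10 min,
#' mean duration 36.5 s).  The configured `burst_rate` is the out-of-
#' superburst rate chosen so that the *total* expected burst count (see
#' `expected_burst_count()`) matches the reported group mean.
#'
#' @param name One of `"intact-div17"`, `"control-div26"`, `"hyase-div19"`,
#'   `"hyase-div20"`, `"hyase-div26"`.
#' @param drug Optional acute pharmacology modifier applied on top of the
#'   regime: `"dzm"` (L-type calcium channel blocker; abolishes superbursts
#'   and halves burst rate), `"cpp"` (NMDA receptor antagonist; no effect on
#'   superbursts), `"cnqx"` (AMPA/kainate antagonist; abolishes superbursts
#'   and strongly suppresses bursting).
#' @param ... Overrides forwarded to [mea_synth_config()] (e.g. `duration`,
#'   `seed`).
#' @return An `mea_synth_config`.
#' @export
mea_preset <- function(name = c("intact-div17", "control-div26",
                                "hyase-div19", "hyase-div20", "hyase-div26"),
                       drug = c("none", "dzm", "cpp", "cnqx"), ...) {
  name <- match.arg(name)
  drug <- match.arg(drug)
  base <- switch(name,
    "intact-div17" = list(burst_rate = 250, superburst_rate = 0),
    "control-div26" = list(burst_rate = 233, superburst_rate = 1.5,
                           superburst_duration_mean = 10.5,
                           superburst_duration_sd = 2),
    "hyase-div19" = list(burst_rate = 513.3, superburst_rate = 0),
    "hyase-div20" = list(burst_rate = 712, superburst_rate = 0),
    "hyase-div26" = list(burst_rate = 526, superburst_rate = 3.3,
                         superburst_duration_mean = 36.5,
                         superburst_duration_sd = 8)
  )
  if (drug == "dzm") {
    base$superburst_rate <- 0
    base$burst_rate <- base$burst_rate * 0.5
  } else if (drug == "cnqx") {
    base$superburst_rate <- 0
    base$burst_rate <- base$burst_rate * 0.2
  } # cpp: no change
  args <- utils::modifyList(base, list(...))
  do.call(mea_synth_config, args)
}

#' Expected total burst count implied by a configuration
#'
#' Total bursts per 10 min = out-of-superburst bursts (`burst_rate`) plus the
#' bursts packed into the expected superburst time at the intra-superburst
#' period.
#'
#' @param config An [mea_synth_config()].
#' @return Expected bursts per 10 minutes.
#' @export
expected_burst_count <- function(config) {
  period <- config$burst_duration_mean + config$intra_superburst_burst_interval
  in_sb <- if (config$superburst_rate > 0 && period > 0) {
    config$superburst_rate * config$superburst_duration_mean / period
  } else 0
  config$burst_rate + in_sb
}

# Draw one burst duration.
draw_burst_duration <- function(config, n = 1L) {
  if (config$burst_duration_dist == "uniform") {
    half <- sqrt(3) * config$burst_duration_sd
    runif(n, max(1e-3, config$burst_duration_mean - half),
          config$burst_duration_mean + half)
  } else {
    pmax(0.02, rnorm(n, config$burst_duration_mean, config$burst_duration_sd))
  }
}

# Hard-core renewal train of [start, end) intervals on [0, span) calibrated so
# that the expected count is rate_per_s * span: inter-onset interval =
# duration + min_gap + Exp(mean = 1/rate - mean_duration - min_gap) (the
# exponential term is dropped when the rate saturates the hard core).
renewal_intervals <- function(span, rate_per_s, draw_duration, mean_duration,
                              min_gap) {
  if (rate_per_s <= 0 || span <= 0) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  slack <- 1 / rate_per_s - mean_duration - min_gap
  starts <- numeric(); ends <- numeric()
  # random phase so the first event is not pinned to t = 0
  t <- runif(1, 0, 1 / rate_per_s)
  repeat {
    dur <- draw_duration(1L)
    if (t + dur > span) break
    starts <- c(starts, t); ends <- c(ends, t + dur)
    gap <- min_gap + if (slack > 0) rexp(1, 1 / slack) else 0
    t <- t + dur + gap
  }
  data.frame(start = starts, end = ends)
}

#' Generate ground-truth-annotated synthetic spike trains
#'
#' Simulates per-electrode spike times as an inhomogeneous Poisson process:
#' basal stochastic firing everywhere, elevated to `within_burst_rate` during
#' network bursts.  Superbursts are realized as dense runs of bursts separated
#' by `intra_superburst_burst_interval`, filling an interval drawn from the
#' superburst duration distribution; ordinary bursts are placed in the
#' remaining time as a hard-core renewal train calibrated to `burst_rate`.
#'
#' @param config An [mea_synth_config()].
#' @return A list with elements `spikes` (a [spike_events()] table) and
#'   `truth` (list with `burst_intervals` and `superburst_intervals`, both
#'   [interval_set()]s).  Identical configs give identical output.
#' @export
#' @examples
#' sim <- generate_spike_trains(mea_synth_config(
#'   n_electrodes = 8, duration = 60, burst_rate = 100, seed = 42))
#' nrow(sim$spikes)
#' head(sim$truth$burst_intervals)
generate_spike_trains <- function(config) {
  stopifnot(inherits(config, "mea_synth_config"))
  dur <- config$duration

  sb <- with_seed(child_seed(config$seed, "superbursts"), {
    renewal_intervals(
      span = dur, rate_per_s = config$superburst_rate / 600,
      draw_duration = function(n) {
        pmax(1, rnorm(n, config$superburst_duration_mean,
                      config$superburst_duration_sd))
      },
      mean_duration = config$superburst_duration_mean,
      min_gap = 20)  # superbursts stay resolvable after ~10 s smoothing
  })

  bursts <- with_seed(child_seed(config$seed, "bursts"), {
    # bursts inside superbursts: dense, short-IBI runs spanning the interval
    in_sb <- lapply(seq_len(nrow(sb)), function(i) {
      s <- sb$start[i]; e <- sb$end[i]
      starts <- numeric(); ends <- numeric()
      t <- s
      while (t < e) {
        d <- draw_burst_duration(config, 1L)
        bend <- min(t + d, e)
        starts <- c(starts, t); ends <- c(ends, bend)
        t <- bend + config$intra_superburst_burst_interval
      }
      data.frame(start = starts, end = ends)
    })
    in_sb <- do.call(rbind, c(in_sb, list(data.frame(start = numeric(),
                                                     end = numeric()))))
    # ordinary bursts in the complement of superburst time, rate referred to
    # total recording time
    free <- dur - sum(sb$end - sb$start)
    out <- if (free > 0 && config$burst_rate > 0) {
      rate_free <- (config$burst_rate / 600) * dur / free
      iv <- renewal_intervals(free, rate_free,
                              function(n) draw_burst_duration(config, n),
                              config$burst_duration_mean,
                              config$min_burst_gap)
      map_into_complement(iv, sb, dur)
    } else data.frame(start = numeric(), end = numeric())
    rbind(in_sb, out)
  })
  bursts <- bursts[order(bursts$start), , drop = FALSE]

  spikes <- with_seed(child_seed(config$seed, "spikes"), {
    res <- vector("list", config$n_electrodes)
    for (el in seq_len(config$n_electrodes)) {
      t_bg <- if (config$background_rate > 0) {
        sort(runif(rpois(1, config$background_rate * dur), 0, dur))
      } else numeric()
      extra <- config$within_burst_rate - config$background_rate
      t_b <- if (nrow(bursts) > 0 && extra > 0) {
        lens <- bursts$end - bursts$start
        counts <- rpois(nrow(bursts), extra * lens)
        unlist(lapply(seq_len(nrow(bursts)), function(i) {
          runif(counts[i], bursts$start[i], bursts$end[i])
        }))
      } else numeric()
      tt <- sort(c(t_bg, t_b))
      res[[el]] <- data.frame(channel = rep(el, length(tt)), time_s = tt)
    }
    do.call(rbind, res)
  })

  amps <- with_seed(child_seed(config$seed, "amplitudes"), {
    if (nrow(spikes) > 0) {
      -pmax(config$spike_amplitude_floor,
            rnorm(nrow(spikes), config$spike_amplitude_mean,
                  config$spike_amplitude_sd))
    } else numeric()
  })

  truth <- list(
    burst_intervals = interval_set(
      label = if (nrow(bursts)) "burst" else character(),
      start = bursts$start, end = bursts$end),
    superburst_intervals = interval_set(
      label = if (nrow(sb)) "superburst" else character(),
      start = sb$start, end = sb$end)
  )
  list(spikes = spike_events(spikes$channel, spikes$time_s, amps),
       truth = truth)
}

# Map intervals generated in collapsed "free time" (the complement of the
# blocked intervals) back into recording time.  Intervals that would straddle
# a blocked region are shifted past it rather than split.
map_into_complement <- function(iv, blocked, span) {
  if (nrow(blocked) == 0L || nrow(iv) == 0L) return(iv)
  blocked <- blocked[order(blocked$start), , drop = FALSE]
  # free segments
  fs <- c(0, blocked$end); fe <- c(blocked$start, span)
  keep <- fe > fs
  fs <- fs[keep]; fe <- fe[keep]
  lens <- fe - fs
  offs <- cumsum(c(0, lens))[seq_along(lens)]
  out <- iv[0, ]
  for (i in seq_len(nrow(iv))) {
    k <- findInterval(iv$start[i], offs)
    s <- fs[k] + (iv$start[i] - offs[k])
    e <- s + (iv$end[i] - iv$start[i])
    if (e <= fe[k]) out <- rbind(out, data.frame(start = s, end = e))
    # bursts that would straddle a superburst edge are dropped (rare; the
    # renewal calibration test tolerates the ~1% loss)
  }
  out
}

# Stereotyped biphasic extracellular spike waveform, ~1 ms total, dominant
# negative phase, unit negative peak.
spike_template <- function(sampling_rate) {
  n <- max(5L, round(0.001 * sampling_rate))
  t <- seq(0, 0.001, length.out = n)
  w <- -exp(-((t - 3e-4)^2) / (2 * (1e-4)^2)) +
    0.4 * exp(-((t - 6.5e-4)^2) / (2 * (1.8e-4)^2))
  w / abs(min(w))
}

#' Synthesize a voltage recording from spike events
#'
#' Builds per-channel traces as Gaussian noise plus a stereotyped biphasic
#' spike waveform (~1 ms, dominant negative phase) scaled by each event's
#' amplitude, inserted at each spike time.  Intended for end-to-end testing of
#' threshold spike detection; simulation at the spike-train level is the
#' default path for burst statistics because full-scale voltage synthesis
#' (64 channels x 20 kHz x 10 min) is memory-heavy.
#'
#' @param spikes A [spike_events()] table.  Missing amplitudes default to the
#'   configured amplitude distribution's mean.
#' @param config An [mea_synth_config()]; `n_electrodes`, `sampling_rate`,
#'   `duration`, `noise_sigma` and `seed` are used.
#' @return A [recording()].
#' @export
generate_voltage <- function(spikes, config) {
  stopifnot(inherits(config, "mea_synth_config"))
  fs <- config$sampling_rate
  if (fs < 4000) {
    stop("sampling rate too low to represent a 1 ms spike waveform",
         call. = FALSE)
  }
  if (nrow(spikes) > 0 && any(spikes$time_s >= config$duration)) {
    stop("spike times must lie within [0, duration)", call. = FALSE)
  }
  n <- round(config$duration * fs)
  tpl <- spike_template(fs)
  v <- with_seed(child_seed(config$seed, "noise"), {
    m <- matrix(0, nrow = config$n_electrodes, ncol = n)
    if (config$noise_sigma > 0) {
      for (ch in seq_len(config$n_electrodes)) {
        m[ch, ] <- rnorm(n, 0, config$noise_sigma)
      }
    }
    m
  })
  if (nrow(spikes) > 0) {
    amp <- ifelse(is.na(spikes$amplitude_uv),
                  -config$spike_amplitude_mean, spikes$amplitude_uv)
    for (i in seq_len(nrow(spikes))) {
      ch <- spikes$channel[i]
      if (ch < 1 || ch > config$n_electrodes) next
      i0 <- round(spikes$time_s[i] * fs) + 1L
      idx <- i0:(i0 + length(tpl) - 1L)
      ok <- idx >= 1L & idx <= n
      # template has unit negative peak; scale by |amplitude|, sign carried
      # by the template's dominant phase
      v[ch, idx[ok]] <- v[ch, idx[ok]] + abs(amp[i]) * tpl[ok]
    }
  }
  recording(v, fs)
}
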