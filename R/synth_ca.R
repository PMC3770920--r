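# Synthetic calcium fluorescence: noisy drifting baselines carrying ordinary
# oscillations (fast rise, exponential decay) and long plateau-like
# superoscillations, with ground-truth event intervals per cell.

#' Configuration for synthetic calcium trace generation
#'
#' Defaults follow the reported activity of cultured hippocampal networks:
#' neuronal oscillations of ~6 s, astrocytic oscillations of ~10 s, and,
#' after hyaluronidase treatment, long superoscillations (tens of seconds,
#' up to ~100 s).
#'
#' @param n_neurons,n_astrocytes Number of cells of each type.
#' @param sampling_rate Frame rate in Hz (default 4).
#' @param duration Recording length in seconds (default 600).
#' @param neuron_osc_duration_mean Mean ordinary oscillation duration in
#'   neurons, seconds (default 6).
#' @param astro_osc_duration_mean Mean ordinary oscillation duration in
#'   astrocytes, seconds (default 10).
#' @param osc_duration_sd Event-to-event sd of ordinary durations, seconds.
#' @param osc_rate Ordinary oscillations per 10 min per cell.
#' @param superosc_duration_mean,superosc_duration_sd Superoscillation
#'   duration distribution, seconds.
#' @param superosc_rate Superoscillations per 10 min per cell (0 disables).
#' @param baseline Baseline fluorescence in relative units (0--255).
#' @param transient_amplitude Peak elevation of ordinary transients,
#'   relative units.
#' @param superosc_amplitude Plateau elevation of superoscillations,
#'   relative units.
#' @param noise_sd Additive Gaussian noise sd, relative units.
#' @param drift_amplitude Amplitude of a slow sinusoidal baseline drift,
#'   relative units.
#' @param drift_period Drift period in seconds (default 300).
#' @param seed Integer seed.
#' @return A `ca_synth_config` list.
#' @seealso [ca_preset()], [generate_calcium_traces()].
#' @export
ca_synth_config <- function(n_neurons = 5, n_astrocytes = 5,
                            sampling_rate = 4, duration = 600,
                            neuron_osc_duration_mean = 6,
                            astro_osc_duration_mean = 10,
                            osc_duration_sd = 1,
                            osc_rate = 20,
                            superosc_duration_mean = 0,
                            superosc_duration_sd = 0,
                            superosc_rate = 0,
                            baseline = 60,
                            transient_amplitude = 40,
                            superosc_amplitude = 50,
                            noise_sd = 1.5,
                            drift_amplitude = 3,
                            drift_period = 300,
                            seed = 1L) {
  for (nm in c("n_neurons", "n_astrocytes", "neuron_osc_duration_mean",
               "astro_osc_duration_mean", "osc_duration_sd", "osc_rate",
               "superosc_duration_mean", "superosc_duration_sd",
               "superosc_rate", "transient_amplitude", "superosc_amplitude",
               "noise_sd", "drift_amplitude")) {
    stopifnot_scalar(get(nm), nm, 0)
  }
  stopifnot_scalar(sampling_rate, "sampling_rate", 0, strict = TRUE)
  stopifnot_scalar(duration, "duration", 0, strict = TRUE)
  stopifnot_scalar(baseline, "baseline", 0)
  if (baseline > 255) stop("`baseline` must be <= 255", call. = FALSE)
  stopifnot_scalar(drift_period, "drift_period", 0, strict = TRUE)
  stopifnot_scalar(seed, "seed")
  fields <- c("n_neurons", "n_astrocytes", "sampling_rate", "duration",
              "neuron_osc_duration_mean", "astro_osc_duration_mean",
              "osc_duration_sd", "osc_rate", "superosc_duration_mean",
              "superosc_duration_sd", "superosc_rate", "baseline",
              "transient_amplitude", "superosc_amplitude", "noise_sd",
              "drift_amplitude", "drift_period", "seed")
  cfg <- mget(fields, envir = environment())
  cfg$n_neurons <- as.integer(cfg$n_neurons)
  cfg$n_astrocytes <- as.integer(cfg$n_astrocytes)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "ca_synth_config")
}

#' Calcium presets for the experimental regimes
#'
#' Superoscillation durations follow the reported time course after
#' hyaluronidase: 94.78 s two days after treatment (DIV 19), 50.95 s on
#' DIV 20 and 28.54 s on DIV 26; astrocytic ordinary oscillations lengthen
#' from ~10 s to ~17--18 s.  Control regimes have no superoscillations.
#' The `"dzm"` drug modifier (L-type calcium channel blocker) abolishes
#' superoscillations and thins ordinary events; `"cpp"` has no effect;
#' `"cnqx"` abolishes superoscillations.
#'
#' @param name One of `"intact-div17"`, `"control-div26"`, `"hyase-div19"`,
#'   `"hyase-div20"`, `"hyase-div26"`.
#' @param drug `"none"`, `"dzm"`, `"cpp"` or `"cnqx"`.
#' @param ... Overrides forwarded to [ca_synth_config()].
#' @return A `ca_synth_config`.
#' @export
ca_preset <- function(name = c("intact-div17", "control-div26",
                               "hyase-div19", "hyase-div20", "hyase-div26"),
                      drug = c("none", "dzm", "cpp", "cnqx"), ...) {
  name <- match.arg(name)
  drug <- match.arg(drug)
  base <- switch(name,
    "intact-div17" = list(),
    "control-div26" = list(osc_rate = 15.75),
    "hyase-div19" = list(superosc_rate = 2, superosc_duration_mean = 94.78,
                         superosc_duration_sd = 12,
                         astro_osc_duration_mean = 16.78),
    "hyase-div20" = list(superosc_rate = 2, superosc_duration_mean = 50.95,
                         superosc_duration_sd = 6,
                         astro_osc_duration_mean = 18.03),
    "hyase-div26" = list(superosc_rate = 2, superosc_duration_mean = 28.54,
                         superosc_duration_sd = 4,
                         astro_osc_duration_mean = 17.75, osc_rate = 10.3)
  )
  if (drug %in% c("dzm", "cnqx")) {
    base$superosc_rate <- 0
    if (drug == "dzm") base$osc_rate <- 0.5 * (base$osc_rate %||% 20)
  }
  args <- utils::modifyList(base, list(...))
  do.call(ca_synth_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ordinary transient: linear rise then exponential decay, truncated to L.
pulse_shape <- function(tt, onset, L, amp) {
  rise <- min(1, 0.2 * L)
  tau <- max(0.5, (L - rise) / 3)
  s <- numeric(length(tt))
  i_rise <- tt >= onset & tt < onset + rise
  i_dec <- tt >= onset + rise & tt < onset + L
  s[i_rise] <- amp * (tt[i_rise] - onset) / rise
  s[i_dec] <- amp * exp(-(tt[i_dec] - onset - rise) / tau)
  s
}

# Superoscillation: fast-rise plateau with fast fall.
plateau_shape <- function(tt, onset, L, amp, ramp = 2) {
  r <- min(ramp, L / 4)
  s <- numeric(length(tt))
  rel <- tt - onset
  i <- rel >= 0 & rel < L
  s[i] <- amp * pmin(1, pmin(rel[i] / r, (L - rel[i]) / r))
  s
}

#' Generate ground-truth-annotated synthetic calcium traces
#'
#' Each trace is baseline + slow sinusoidal drift + Gaussian noise +
#' transients.  Ordinary oscillations are fast-rise/exponential-decay events
#' with cell-type-specific mean durations; superoscillations are long
#' plateau-like elevations with independently drawn durations.  Events of
#' each class are placed by a hard-core renewal process calibrated to the
#' configured rate, so intervals never overlap within a class.  Values are
#' clipped to `[0, 255]`.
#'
#' @param config A [ca_synth_config()].
#' @return A list with `traces` (list of [fluorescence_trace()]) and `truth`
#'   (data.frame `cell_id`, `kind`, `start`, `end`).  Identical configs give
#'   identical output.
#' @export
generate_calcium_traces <- function(config) {
  stopifnot(inherits(config, "ca_synth_config"))
  fs <- config$sampling_rate
  dur <- config$duration
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  n_cells <- config$n_neurons + config$n_astrocytes
  types <- c(rep("neuron", config$n_neurons),
             rep("astrocyte", config$n_astrocytes))
  traces <- vector("list", n_cells)
  truth <- list()
  for (ci in seq_len(n_cells)) {
    ty <- types[ci]
    cid <- sprintf("%s%02d", substr(ty, 1, 1), ci)
    osc_mean <- if (ty == "neuron") config$neuron_osc_duration_mean else
      config$astro_osc_duration_mean

    so <- with_seed(child_seed(config$seed, paste0("so-", ci)), {
      renewal_intervals(dur, config$superosc_rate / 600, function(n) {
        pmax(4, rnorm(n, config$superosc_duration_mean,
                      config$superosc_duration_sd))
      }, config$superosc_duration_mean, min_gap = 30)
    })
    osc <- with_seed(child_seed(config$seed, paste0("osc-", ci)), {
      if (config$osc_rate > 0 && osc_mean > 0) {
        renewal_intervals(dur, config$osc_rate / 600, function(n) {
          pmax(1, rnorm(n, osc_mean, config$osc_duration_sd))
        }, osc_mean, min_gap = 2)
      } else data.frame(start = numeric(), end = numeric())
    })

    sig <- rep(config$baseline, length(tt))
    phase <- with_seed(child_seed(config$seed, paste0("drift-", ci)),
                       runif(1, 0, 2 * pi))
    if (config$drift_amplitude > 0) {
      sig <- sig + config$drift_amplitude *
        sin(2 * pi * tt / config$drift_period + phase)
    }
    for (k in seq_len(nrow(osc))) {
      sig <- sig + pulse_shape(tt, osc$start[k], osc$end[k] - osc$start[k],
                               config$transient_amplitude)
    }
    for (k in seq_len(nrow(so))) {
      sig <- sig + plateau_shape(tt, so$start[k], so$end[k] - so$start[k],
                                 config$superosc_amplitude)
    }
    if (config$noise_sd > 0) {
      sig <- sig + with_seed(child_seed(config$seed, paste0("noise-", ci)),
                             rnorm(length(tt), 0, config$noise_sd))
    }
    sig <- pmin(255, pmax(0, sig))
    traces[[ci]] <- fluorescence_trace(sig, fs, cid, ty)
    if (nrow(osc)) {
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = cid, kind = "pulse", start = osc$start, end = osc$end)
    }
    if (nrow(so)) {
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = cid, kind = "superoscillation", start = so$start,
        end = so$end)
    }
  }
  truth <- do.call(rbind, c(truth, list(data.frame(
    cell_id = character(), kind = character(), start = numeric(),
    end = numeric()))))
  list(traces = traces, truth = truth)
}

#' Generate a synthetic image stack realizing a fluorescence trace
#'
#' Builds a small frame sequence in which every pixel inside the mask follows
#' the trace value (plus optional pixel noise) and background pixels hold a
#' constant, for round-trip testing of [extract_trace()].  Configure
#' `dim = c(256, 256)` to match full acquisition geometry.
#'
#' @param trace A [fluorescence_trace()]; one frame per sample.
#' @param mask Logical matrix of in-cell pixels; must be non-empty and match
#'   `dim`.
#' @param dim Frame size, default `c(64, 64)`.
#' @param background Background pixel value (default 10).
#' @param pixel_noise_sd Per-pixel Gaussian noise sd (default 0).
#' @param seed Seed for the pixel noise.
#' @return Numeric array `dim[1] x dim[2] x length(trace$values)`.
#' @export
generate_image_stack <- function(trace, mask, dim = c(64, 64),
                                 background = 10, pixel_noise_sd = 0,
                                 seed = 1L) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (!is.matrix(mask) || !identical(base::dim(mask), as.integer(dim))) {
    stop("`mask` must be a logical matrix of size `dim`", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  n_frames <- length(trace$values)
  stack <- array(background, c(dim, n_frames))
  for (f in seq_len(n_frames)) {
    frame <- stack[, , f]
    frame[mask] <- trace$values[f]
    stack[, , f] <- frame
  }
  if (pixel_noise_sd > 0) {
    stack <- stack + with_seed(child_seed(seed, "pixels"),
                               array(rnorm(length(stack), 0, pixel_noise_sd),
                                     base::dim(stack)))
  }
  stack
}
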