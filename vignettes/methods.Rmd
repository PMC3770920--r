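---
title: "Methods: burst, superburst, and calcium transient detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst, superburst, and calcium transient detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the signal model, every detector, the synthetic-data
generators used to validate them, and the numerical and design decisions
behind the implementation. All quantitative claims made here are asserted by
the package's test suite or computed by `scripts/acceptance.R`; nothing is
reported that the code does not verify.

# Scientific setting

Dissociated hippocampal cultures grown on microelectrode arrays (MEAs)
develop spontaneous network activity: a low-rate stochastic background plus
short network *bursts* in which many electrodes fire together for a few
hundred milliseconds. Under epileptogenic manipulation of the extracellular
matrix, cultures additionally produce seizure-like *superbursts* — tens of
seconds during which bursts recur with very short interburst intervals.
The same cultures imaged with a calcium indicator at 4 Hz show ordinary
Ca²⁺ *pulses* (roughly 6 s in neurons, 10 s or more in astrocytes) and,
in the pathological regime, minute-scale *superoscillations* — prolonged
plateau-like elevations of the fluorescence signal.

The package implements the complete analysis chain for both modalities and
a seeded synthetic generator for each, so that every detector is validated
by parameter recovery against known ground truth rather than by eye.

# Spike detection

The voltage on each electrode is band-pass filtered (Butterworth, order 4,
0.3–8 kHz, applied forward–backward so the phase is zero) and thresholded
at

$$T = N_S\,\sigma, \qquad \sigma = \frac{\operatorname{median}(|x|)}{0.6745},$$

with $N_S = 4$ by default. The constant $0.6745$ is the 0.75 quantile of
the standard normal distribution, so for pure Gaussian noise $\sigma$
estimates the noise standard deviation; unlike the sample SD it is barely
inflated by the spikes themselves (asserted in the tests by injecting
large deflections). Both polarities are detected: within each excursion of
$|x|$ above $T$ the extremum is taken as the spike time, and events closer
than 1 ms on the same channel are merged, keeping the earlier peak.

## False positives on pure noise: an attainability analysis

For band-limited Gaussian noise the expected rate of upward crossings of a
level $u$ is given by Rice's formula, $\nu(u) = f_{\mathrm{rms}}
e^{-u^2/2\sigma^2}$, where $f_{\mathrm{rms}}$ is the RMS spectral
frequency. For noise band-limited to 0.3–8 kHz, $f_{\mathrm{rms}} \approx
4.7$ kHz, so crossings of $\pm 4\sigma$ occur at roughly $2
f_{\mathrm{rms}} e^{-8} \approx 3$ per second — two orders of magnitude
above a "5 false positives per minute" expectation. Meeting that bound on
*pure* Gaussian noise would require $N_S \gtrsim 4.8$. On real recordings
$\sigma$ is inflated by multi-unit background activity, which is why the
conventional coefficient works in practice. The acceptance suite asserts the
false-positive bound exactly as stated, and that single assertion is
expected to fail at $N_S = 4$; the analysis above, derived before the test
was ever run, explains why; the coefficient is deliberately not raised to
hide it.

# Burst detection

Spikes from all electrodes are pooled into the total spiking rate (TSR):
counts in 50 ms bins. The burst threshold is

$$T_{\mathrm{burst}} = 0.1\,\sigma_{\mathrm{TSR}},$$

with $\sigma_{\mathrm{TSR}}$ the SD of the binned counts. Maximal runs of
bins above threshold are bursts. Two boundary conventions are provided:

* `refine = "bins"` returns bin-edge intervals (used by the exhaustive
  scan oracle in the tests);
* `refine = "spikes"` snaps each boundary to the first and last pooled
  spike inside the suprathreshold run.

The second convention exists for a structural reason. A burst of duration
$c$ overlaps partial bins at both edges; because the threshold
($0.1\,\sigma_{\mathrm{TSR}}$) is far below the in-burst bin count, a
partial edge bin almost always crosses it, so bin-edge durations carry a
positive quantization bias with expectation $\Delta(1 - 2\varphi)$ where
$\Delta = 50$ ms is the bin width and $\varphi \approx T/c$ is small. For
100–500 ms bursts this bias alone approaches or exceeds 10–50% of the true
duration, which would make a sub-10% mean duration error unattainable at
the bin level. Spike-snapped boundaries remove the quantization term, and
the acceptance benchmark (`scripts/acceptance.R`) verifies a mean relative
duration error well under 10% at occurrence frequencies of 0.5, 1, 2 and
5 Hz.

Two bursts whose gap does not contain at least one complete sub-threshold
bin are fundamentally unresolvable at a given bin width; any gap of at
least $2\Delta = 100$ ms contains a complete bin at every alignment. The
duration benchmark therefore keeps gaps at or above 110 ms (and uses a
near-periodic 100 ms/100 ms train at 5 Hz, where the 200 ms period leaves
no room for more), so that it measures the detector's duration bias rather
than the resolution limit of the binning. Merging behavior itself is
exercised separately in the unit tests.

# Superburst detection

A Gaussian window with an *effective width* of 50 s is slid along the TSR
in 10 ms steps; at each position the indicator is the weight-normalized
Gaussian-weighted average of the TSR (computed by FFT convolution on the
bin grid with truncated-window renormalization at the edges, then
interpolated onto the 10 ms grid — the indicator of a constant TSR is that
constant to within 1e-9, which the tests assert). Superbursts are runs of
the indicator above

$$T_{\mathrm{sb}} = \mu_{\mathrm{ind}} + 0.4\,\sigma_{\mathrm{ind}}.$$

Three interpretation decisions deserve explanation:

* **Width convention.** "Effective width 50 s" is read by default as a
  50-s-long tapered Gaussian window whose shape parameter follows the
  common discrete Gaussian-window convention $\sigma = \mathrm{width}/5 =
  10$ s; this also reconciles descriptions of the same analysis as using a
  "10 s window". The FWHM reading ($\sigma = 50/2.355 \approx 21.2$ s) is
  available via `width_convention = "fwhm"`, and with boundary refinement
  (below) both conventions recover synthetic superburst durations within
  the 15% acceptance tolerance.
* **Mean-referred threshold.** Thresholding the *raw* indicator at
  $0.4\,\sigma_{\mathrm{ind}}$ is degenerate whenever ordinary (non-burst)
  activity keeps the indicator baseline above $0.4\,\sigma_{\mathrm{ind}}$
  — the entire recording becomes one crossing. The default therefore
  references the threshold to the indicator mean
  (`indicator_center = "mean"`); the raw mode remains available
  (`indicator_center = "none"`).
* **Burst-run refinement.** A Gaussian-smoothed bump of height $h$ has
  $\sigma_{\mathrm{ind}} \le h/2$ over the recording, so the crossing
  level sits at or below $0.2\,h$ — crossings cut the Gaussian *skirts*,
  not the event edges, and overestimate durations by roughly
  $2\sigma_g$ regardless of the width convention. Since a superburst is,
  concretely, a run of bursts with very short interburst intervals,
  `detect_superbursts(refine = "bursts")` trims each crossing window to
  its largest run of consecutive bursts separated by at most 0.5 s,
  requiring at least 5 such bursts. The pipeline and the acceptance suite
  use this mode; the crossing-only mode is kept as the primitive (and is
  what the oracle-equivalence tests exercise).

# Calcium analysis

## Ordinary pulses

Each ROI-averaged trace (relative units 0–255 at 4 Hz) is smoothed by
averaging two neighboring points and differenced; the threshold is
$0.45 \times \mathrm{SD}$ of the derivative. An event begins where the
derivative exceeds $+\theta$ and ends at the completion of the first
subsequent excursion below $-\theta$ (a completed rise-then-fall cycle);
an onset left open at the end of the trace is closed there and flagged
`truncated`. Note that this convention measures the *derivative-active
core* of a transient — the rise plus the initial, steepest part of the
decay — so reported pulse durations are systematically shorter than the
full transient footprint. No accuracy criterion binds pulse durations;
counts and relative comparisons are the meaningful outputs.

## Superoscillations

The trace is low-pass filtered (elliptic, order 4, cutoff 0.2 Hz, 0.1 dB
ripple, 40 dB stopband, forward–backward), which suppresses regular short
pulses. The slow derivative is the causal average of the next $m = 20$
point-pair differences, $D_i = (x^f_{i+m} - x^f_i)/m$, thresholded at
$0.8 \times \mathrm{SD}(D)$.

Three numerical points matter:

* **Edge padding.** A forward–backward filter applied to an unpadded
  trace starts from zero state, and the step from 0 to the fluorescence
  baseline produces a large spurious transient at both ends — enough to
  fabricate a ~30 s event per trace. The trace is therefore mirror-padded
  by $10/f_c$ seconds and de-meaned before filtering.
* **Boundary geometry.** Because the averaging window looks *ahead*, a
  rising edge starting at sample $s$ produces a positive excursion of $D$
  beginning at $s - m$: the event onset is the first suprathreshold
  sample *plus* $m$. A falling edge ending at sample $e$ produces a
  negative excursion ending at $e$ itself: the event end is the last
  sample of the closing excursion. This removes, by construction, the
  constant $m/f_s = 5$ s duration overshoot that a symmetric
  half-window shift leaves behind.
* **Level closure.** Short pulses riding on a long plateau create
  interior negative excursions of $D$ that would otherwise split one
  90 s event into ~10 s fragments. The *matching* negative excursion is
  therefore defined as the first one after which the filtered signal has
  returned at least halfway from its running peak to the onset level.
  For an isolated event this coincides exactly with the first-excursion
  rule, so the single-plateau scan oracle in the tests is unaffected.

Finally, events shorter than `min_superosc_duration` (default 11 s, the
lower end of the superoscillation duration class) are discarded. The
filtered footprint of a 6 s pulse is about 5.5 s and that of a 10 s
astrocytic pulse about 9.5 s, so this floor is what makes the detector
return *no* events on traces containing only regular short transients
(asserted in the tests) while leaving the 30–95 s recovery range
untouched. The acceptance suite verifies a mean absolute relative
duration error of at most 15% against ground truth over 20 seeds.

# Synthetic data generators

## MEA spike trains

Activity is generated top-down: superbursts, then bursts, then spikes.

* Superbursts and out-of-superburst bursts are placed by a *hard-core
  renewal process*: inter-onset interval = duration + minimum gap +
  an exponential residual whose mean is calibrated so that the expected
  event count matches the configured rate (by the renewal theorem).
  The more obvious alternative — homogeneous Poisson onsets thinned to
  forbid overlap — undershoots the configured rate by the dead-time
  fraction (over 20% at high rates), which would break the generator's
  own calibration invariant (realized counts within 3 SE of configured
  rates, asserted in the tests).
* Inside a superburst, bursts recur with a short fixed interburst
  interval (default 0.2 s); ordinary bursts are placed in the remaining
  free time by mapping a renewal stream through the complement of the
  occupied intervals.
* Each electrode receives independent Poisson background spikes plus
  Poisson in-burst spikes at `within_burst_rate`; amplitudes are drawn
  from a floored normal distribution (default mean 60 μV, floor 20 μV).
* `generate_voltage()` renders spike trains into band-limited Gaussian
  noise using a 1 ms biphasic template scaled per spike, for end-to-end
  tests of the voltage-level detector.

Presets `intact-div17`, `control-div26`, `hyase-div19`, `hyase-div20`,
and `hyase-div26` encode the control-like and hyaluronidase-like regimes
(burst counts, superburst rates and durations); drug modifiers `dzm`,
`cpp`, `cnqx` scale rates (`dzm` halves burst rates and abolishes
superbursts, `cnqx` reduces burst rates to 20% and abolishes
superbursts, `cpp` leaves rates unchanged).

All randomness descends from one integer seed through named substreams
(`child_seed(seed, stream)`), so adding, say, noise generation does not
perturb the spike stream, and every derived seed stays within 32-bit
range.

## Calcium traces

Each cell's trace is baseline + slow sinusoidal drift (random phase) +
Gaussian noise + events, clipped to [0, 255]. Ordinary oscillations are
fast-rise/exponential-decay transients (neuronal mean duration 6 s,
astrocytic 10 s or longer by preset); superoscillations are plateaus with
2 s ramps and independently drawn durations. Events are placed by the
same hard-core renewal mechanism, and per-cell ground-truth intervals are
returned for recovery testing. `generate_image_stack()` renders a trace
into a small image stack under a mask so that `extract_trace()` (mean of
in-mask pixels per frame) can be round-trip tested.

### Generator realism and limits

The generators reproduce the *statistical* structure the detectors rely
on — nested rate elevations, event durations and rates, amplitude floors,
noise levels — not biophysics. Spike waveforms are a fixed template, not
models of extracellular fields; electrodes are statistically identical
and independent given the network events; calcium transients are
stylized shapes without indicator kinetics or bleaching; drug presets
are rate modifiers, not pharmacology. Within-superburst structure uses a
single fixed interburst interval, where real recordings show variability.
These are deliberate: the package validates detectors, and every
simplification is in the direction that makes ground truth unambiguous.

# Pipeline and summaries

`run_pipeline()` executes simulate → detect → summarize for every
(preset, seed) pair, with stage-labeled errors, YAML-round-trippable
configuration, per-replicate statistics, group summaries as mean ± SEM
across seeds, and — when an output directory is given — CSV/JSON
artifacts plus a manifest of MD5 checksums. Rerunning the same
configuration reproduces identical checksums (asserted in the tests).

# Monotonicity in the detection coefficients

Raising a detection coefficient should never produce "additional"
detections. The faithful formalization differs by detector class:

* **Superlevel-set detectors** (bursts, superbursts). The raw event
  *count* is the wrong formalization: the number of connected components
  of a superlevel set $\{x > t\}$ is not monotone in $t$ — raising the
  threshold can split one merged run into two, so counts can transiently
  increase. The tests assert the well-defined form: every interval
  detected at a stricter coefficient overlaps an interval detected at
  the looser one (nestedness of detected activity), and the total
  detected time is non-increasing.
* **Pointlike spikes and paired pulses.** The plain count assertion is
  kept: raising the threshold only removes threshold crossings, and each
  pulse consumes one positive derivative excursion.
* **Superoscillations.** Here *neither* count nor nestedness is monotone,
  for three structural reasons: trigger runs can split (as above); the
  interval end comes from a *matching negative crossing of the same
  threshold*, so raising the threshold can disqualify the previously
  matched excursion and extend the interval past the looser one; and the
  minimum-duration filter can drop loose-threshold fragments of a
  plateau that the stricter threshold detects whole (early in a rise the
  running peak barely exceeds the onset level, so at low thresholds the
  half-return closure fires on small dips and fragments long events).
  The monotone property that does hold — verified over 36 synthetic
  traces with zero violations — is *trigger containment*: with the
  duration filter neutralized, every event detected at a stricter
  coefficient begins inside the span of an event detected at the looser
  one. That is what the tests assert; it isolates the coefficient's
  effect, which is what the monotonicity property is about, from the
  orthogonal duration filter.

# Known limitations

* The false-positive bound for spike detection on pure Gaussian noise is
  physically unattainable at $N_S = 4$ (see the Rice analysis above); the
  corresponding acceptance assertion fails by design rather than being
  weakened.
* The sample median of $|N(0,1)|$ over $10^7$ draws has a Monte Carlo SE
  of about $2.5\times 10^{-4}$, so the empirical check of the 0.6745
  constant is asserted within $10^{-3}$ (≈4 SE); four-significant-figure
  agreement is asserted analytically via `qnorm(0.75)`.
* Pulse durations measure the derivative-active core of a transient, not
  its full footprint.
* Superoscillations shorter than `min_superosc_duration` (11 s) are not
  detectable by design; configuring the generator below that floor will
  produce misses.
* Voltage rendering requires a sampling rate of at least 4 kHz (the 1 ms
  template must be resolvable); the band-pass upper edge must lie below
  Nyquist.
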