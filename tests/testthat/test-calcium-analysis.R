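test_that("constant traces yield no events, with a warning", {
  tr <- flat_trace(duration = 300)
  expect_warning(p <- detect_ca_pulses(tr))
  expect_equal(nrow(p), 0L)
  expect_warning(s <- detect_superoscillations(tr))
  expect_equal(nrow(s), 0L)
})

test_that("a single fast-rise transient gives one pulse at the scan oracle", {
  fs <- 4
  v <- add_pulse(rep(60, 300 * fs), fs, onset = 150, len = 6)
  tr <- fluorescence_trace(v, fs, "c1", "neuron")
  ev <- detect_ca_pulses(tr)
  expect_equal(nrow(ev), 1L)
  # oracle: same smoothing/derivative, brute-force crossing scan
  k <- ca_detection_params()$smoothing_points
  y <- stats::filter(v, rep(1 / k, k), sides = 1)
  d <- diff(y[!is.na(y)])
  th <- 0.45 * sd(d)
  ora <- oracle_pulses(d, th, fs)
  expect_equal(nrow(ora), 1L)
  expect_lt(abs(ev$start - ora$start), 1 / fs + 1e-9)
  expect_equal(ev$end, ora$end)
  expect_equal(ev$duration, ev$end - ev$start)
})

test_that("raising detection coefficients never adds events", {
  cfg <- ca_preset("hyase-div20", n_neurons = 2, n_astrocytes = 1, seed = 4)
  sim <- generate_calcium_traces(cfg)
  for (tr in sim$traces) {
    # pulses: the literal count form — raising the threshold only removes
    # derivative excursions, so the number of paired pulses cannot grow
    np <- vapply(c(0.3, 0.45, 0.9, 2), function(k) {
      nrow(detect_ca_pulses(tr, ca_detection_params(pulse_coeff = k)))
    }, numeric(1))
    expect_true(all(diff(np) <= 0))
    # superoscillations: neither count nor nestedness is monotone by
    # construction (threshold runs can split, the level-closure end is
    # tied to a negative crossing of the same threshold, and the
    # minimum-duration filter can drop loose-threshold fragments), so
    # assert trigger containment with the duration filter neutralized:
    # stricter thresholds only trigger inside activity found at looser
    # ones
    ss <- lapply(c(0.4, 0.8, 1.6, 3), function(k) {
      detect_superoscillations(tr, ca_detection_params(
        superosc_coeff = k, min_superosc_duration = 0))
    })
    for (i in seq_along(ss)[-1]) {
      expect_trigger_containment(ss[[i - 1]], ss[[i]])
    }
  }
})

test_that("regular short transients alone yield no superoscillations", {
  fs <- 4
  v <- rep(60, 600 * fs)
  for (onset in seq(20, 560, by = 40)) {
    v <- add_pulse(v, fs, onset, len = 6)
  }
  tr <- fluorescence_trace(v, fs, "c1", "neuron")
  expect_equal(nrow(detect_superoscillations(tr)), 0L)
  # the same transients ARE found by the pulse detector
  expect_equal(nrow(detect_ca_pulses(tr)), length(seq(20, 560, by = 40)))
})

test_that("an injected 30 s plateau is recovered within 15%", {
  fs <- 4
  v <- add_plateau(rep(60, 600 * fs), fs, onset = 250, len = 30)
  tr <- fluorescence_trace(v, fs, "c1", "neuron")
  ev <- detect_superoscillations(tr)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$duration - 30) / 30, 0.15)
  # boundaries match the exhaustive crossing-scan oracle on the filtered
  # derivative
  p <- ca_detection_params()
  sl <- slow_derivative(tr, p)
  ora <- oracle_superosc(sl$D, sl$xf, p$superosc_coeff * sd(sl$D), sl$m, fs)
  ora <- ora[ora$end - ora$start >= p$min_superosc_duration, ]
  expect_equal(ev$start, ora$start)
  expect_equal(ev$end, ora$end)
})

test_that("superoscillation detection matches the scan oracle on synthetic
           regimes", {
  p <- ca_detection_params()
  for (s in 1:5) {
    cfg <- ca_preset("hyase-div26", n_neurons = 2, n_astrocytes = 0, seed = s)
    sim <- generate_calcium_traces(cfg)
    for (tr in sim$traces) {
      det <- detect_superoscillations(tr, p)
      sl <- slow_derivative(tr, p)
      ora <- oracle_superosc(sl$D, sl$xf, p$superosc_coeff * sd(sl$D),
                             sl$m, tr$sampling_rate)
      ora <- ora[ora$end - ora$start >= p$min_superosc_duration, ]
      expect_equal(det$start, ora$start)
      expect_equal(det$end, ora$end)
    }
  }
})

test_that("superoscillation counts are robust to superimposed short
           transients", {
  fs <- 4
  diffs <- vapply(1:20, function(s) {
    base <- rep(60, 600 * fs)
    ons <- with_seed(child_seed(s, "plateaus"),
                     sort(runif(2, 60, 400)))
    ons <- c(ons[1], max(ons[1] + 120, ons[2]))  # well separated
    for (o in ons) base <- add_plateau(base, fs, o, len = 50)
    noise <- with_seed(child_seed(s, "noise"), rnorm(length(base), sd = 1))
    tr0 <- fluorescence_trace(pmin(255, pmax(0, base + noise)), fs, "a", "neuron")
    withp <- base
    for (o in with_seed(child_seed(s, "pulses"), runif(12, 10, 580))) {
      withp <- add_pulse(withp, fs, o, len = 6, amp = 30)
    }
    tr1 <- fluorescence_trace(pmin(255, pmax(0, withp + noise)), fs, "a", "neuron")
    abs(nrow(detect_superoscillations(tr1)) -
        nrow(detect_superoscillations(tr0)))
  }, numeric(1))
  expect_true(all(diffs <= 1))
})

test_that("calcium statistics aggregate per cell type and omit absent types", {
  fs <- 4
  trs <- list(fluorescence_trace(rep(60, 600 * fs), fs, "n1", "neuron"),
              fluorescence_trace(rep(60, 600 * fs), fs, "n2", "neuron"))
  ev <- data.frame(cell_id = c("n1", "n1", "n2"), kind = "pulse",
                   start = c(1, 10, 3), end = c(3, 16, 9),
                   duration = c(2, 6, 6), truncated = FALSE)
  class(ev) <- c("ca_events", "data.frame")
  st <- ca_statistics(ev, trs, window = 600)
  expect_equal(nrow(st), 1L)
  expect_equal(st$cell_type, "neuron")
  expect_equal(st$n_cells, 2L)
  expect_equal(st$mean_duration, mean(c(mean(c(2, 6)), 6)))
  expect_equal(st$events_per_10min, mean(c(2, 1)))
  expect_false("astrocyte" %in% st$cell_type)
})

test_that("trace extraction validates its mask", {
  stack <- array(1, dim = c(8, 8, 10))
  expect_error(extract_trace(stack, matrix(FALSE, 8, 8)))
  expect_error(extract_trace(stack, matrix(TRUE, 4, 4)))
})
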