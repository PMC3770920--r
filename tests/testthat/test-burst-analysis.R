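test_that("TSR conserves the total spike count", {
  cfg <- mea_preset("control-div26", n_electrodes = 8, duration = 120,
                    seed = 1)
  sim <- generate_spike_trains(cfg)
  tsr <- compute_tsr(sim$spikes, span = c(0, cfg$duration))
  expect_equal(sum(tsr$counts), nrow(sim$spikes))
})

test_that("a rectangular elevation over bins [20, 30) gives [1.0 s, 1.5 s)", {
  # 10 spikes in every 50 ms bin of [1.0, 1.5) on a 5 s span, nothing else
  times <- as.vector(outer(seq(0, 0.45, by = 0.05)[1:10] * 0 +
                           seq(1.0, 1.45, by = 0.05),
                           seq(0.001, 0.046, by = 0.005), `+`))
  spikes <- spikes_at(sort(times))
  tsr <- compute_tsr(spikes, bin_width = 0.05, span = c(0, 5))
  bursts <- detect_bursts(tsr, burst_detection_params())
  expect_equal(nrow(bursts), 1L)
  expect_equal(bursts$start, 1.0)
  expect_equal(bursts$end, 1.5)
})

test_that("all-zero TSR yields an empty interval set with a warning", {
  spikes <- spikes_at(numeric(0))
  tsr <- compute_tsr(spikes, span = c(0, 10))
  expect_warning(b <- detect_bursts(tsr, burst_detection_params()))
  expect_equal(nrow(b), 0L)
})

test_that("burst detection matches the exhaustive scan oracle", {
  set.seed(10)
  for (rep in 1:15) {
    n_bins <- sample(c(100, 1000, 10000), 1)
    counts <- rpois(n_bins, lambda = 0.3) +
      rpois(n_bins, 20) * (runif(n_bins) < 0.05)
    spikes <- spikes_at(rep((seq_len(n_bins) - 0.5) * 0.05,
                            times = counts))
    tsr <- compute_tsr(spikes, bin_width = 0.05, span = c(0, n_bins * 0.05))
    expect_equal(sum(tsr$counts), sum(counts))
    det <- detect_bursts(tsr, burst_detection_params())
    thr <- 0.1 * sd(tsr$counts)
    ora <- oracle_bursts(tsr$counts, 0.05, thr)
    expect_equal(nrow(det), nrow(ora))
    expect_equal(det$start, ora$start)
    expect_equal(det$end, ora$end)
  }
})

test_that("raising burst and superburst coefficients never adds detections", {
  cfg <- mea_preset("hyase-div26", n_electrodes = 8, duration = 300, seed = 3)
  sim <- generate_spike_trains(cfg)
  tsr <- compute_tsr(sim$spikes, span = c(0, cfg$duration))
  bs <- lapply(c(0.05, 0.1, 0.3, 1, 3), function(k) {
    detect_bursts(tsr, burst_detection_params(burst_coeff = k))
  })
  for (i in seq_along(bs)[-1]) expect_nested_detections(bs[[i - 1]], bs[[i]])
  sbs <- lapply(c(0.2, 0.4, 0.8, 1.6), function(k) {
    p <- burst_detection_params(superburst_coeff = k)
    detect_superbursts(superburst_indicator(tsr, p), p)
  })
  for (i in seq_along(sbs)[-1]) {
    expect_nested_detections(sbs[[i - 1]], sbs[[i]])
  }
})

test_that("spike-refined burst boundaries snap to pooled spike times", {
  cfg <- mea_preset("control-div26", n_electrodes = 8, duration = 120,
                    seed = 4)
  sim <- generate_spike_trains(cfg)
  tsr <- compute_tsr(sim$spikes, span = c(0, cfg$duration))
  ref <- detect_bursts(tsr, burst_detection_params(), spikes = sim$spikes,
                       refine = "spikes")
  expect_true(all(ref$start %in% sim$spikes$time_s))
  expect_true(all(ref$end %in% sim$spikes$time_s))
  expect_true(all(ref$start <= ref$end))
})

test_that("the superburst indicator is weight-normalized and linear", {
  p <- burst_detection_params()
  n_bins <- 4000
  const <- compute_tsr(spikes_at(rep((seq_len(n_bins) - 0.5) * 0.05, 3)),
                       bin_width = 0.05, span = c(0, n_bins * 0.05))
  ind <- superburst_indicator(const, p)
  interior <- ind$value[ind$time > 60 & ind$time < n_bins * 0.05 - 60]
  expect_equal(max(abs(interior - 3)) / 3, 0, tolerance = 1e-9)

  # single nonzero bin -> Gaussian bump peaking at that bin's center
  counts1 <- integer(n_bins); counts1[2000] <- 50
  sp1 <- spikes_at(rep((2000 - 0.5) * 0.05, 50))
  tsr1 <- compute_tsr(sp1, bin_width = 0.05, span = c(0, n_bins * 0.05))
  ind1 <- superburst_indicator(tsr1, p)
  expect_equal(ind1$time[which.max(ind1$value)], (2000 - 0.5) * 0.05,
               tolerance = 0.02)
  # linearity: indicator(a + b) = indicator(a) + indicator(b)
  spab <- spikes_at(c(rep((seq_len(n_bins) - 0.5) * 0.05, 3),
                      rep((2000 - 0.5) * 0.05, 50)))
  tsrab <- compute_tsr(spab, bin_width = 0.05, span = c(0, n_bins * 0.05))
  indab <- superburst_indicator(tsrab, p)
  expect_equal(indab$value, ind$value + ind1$value, tolerance = 1e-8)
})

test_that("indicator evaluation uses 10 ms steps", {
  cfg <- mea_preset("control-div26", n_electrodes = 4, duration = 120,
                    seed = 5)
  sim <- generate_spike_trains(cfg)
  tsr <- compute_tsr(sim$spikes, span = c(0, 120))
  ind <- superburst_indicator(tsr, burst_detection_params())
  expect_equal(unique(round(diff(ind$time), 9)), 0.01)
})

test_that("burst statistics compute the documented quantities", {
  iv <- interval_set(label = c("burst", "burst", "superburst"),
                     start = c(1, 5, 10), end = c(2, 6.5, 40),
                     n_spikes = c(10, 20, NA))
  st <- burst_statistics(iv, window = 600)
  expect_equal(st$bursts_per_10min, 2)
  expect_equal(st$mean_burst_duration, mean(c(1, 1.5)))
  expect_equal(st$mean_interburst_interval, 3)  # 5 - 2
  expect_equal(st$mean_spikes_per_burst, 15)
  expect_equal(st$superbursts_per_10min, 1)
  expect_equal(st$mean_superburst_duration, 30)
})

test_that("superburst detection requires a span at least one window long", {
  sp <- spikes_at(runif(100, 0, 20))
  tsr <- compute_tsr(sp, span = c(0, 20))
  expect_error(superburst_indicator(tsr, burst_detection_params()))
})
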