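test_that("noise sigma estimate matches the robust median identity", {
  x <- with_seed(1, rnorm(2e5, sd = 3))
  expect_equal(estimate_noise_sigma(x), 3, tolerance = 0.02)
  # robustness: 1% large deflections barely move the estimate
  x2 <- x
  x2[seq(1, length(x2), by = 100)] <- 80
  expect_equal(estimate_noise_sigma(x2), 3, tolerance = 0.05)
  expect_gt(sd(x2), 3 * 2)  # the plain SD is blown up by the same spikes
})

test_that("detection threshold is N_S times the robust sigma", {
  x <- with_seed(2, rnorm(1e5, sd = 5))
  sigma <- estimate_noise_sigma(x)
  expect_equal(sigma, median(abs(x)) / 0.6745)
  p <- spike_detection_params(n_s = 4)
  expect_equal(p$n_s * sigma, 4 * median(abs(x)) / 0.6745)
})

test_that("detected spikes respect the 1 ms refractory interval", {
  cfg <- mea_synth_config(n_electrodes = 2, duration = 10,
                          background_rate = 20, burst_rate = 0,
                          superburst_rate = 0, noise_sigma = 4, seed = 8)
  sim <- generate_spike_trains(cfg)
  rec <- generate_voltage(sim$spikes, cfg)
  det <- detect_spikes(rec)
  for (ch in unique(det$channel)) {
    isi <- diff(det$time_s[det$channel == ch])
    expect_true(all(isi >= 0.001 - 1e-9))
  }
})

test_that("both spike polarities are detected", {
  fs <- 20000
  x <- with_seed(3, rnorm(fs, sd = 2))
  x[5000] <- -40   # negative-going spike
  x[15000] <- 40   # positive-going spike
  rec <- recording(matrix(x, nrow = 1), fs)
  det <- detect_spikes(rec, filter = FALSE)
  expect_true(any(abs(det$time_s - 5000 / fs) < 0.001))
  expect_true(any(abs(det$time_s - 15000 / fs) < 0.001))
  expect_true(any(det$amplitude_uv < 0) && any(det$amplitude_uv > 0))
})

test_that("a zero-variance channel warns and yields no events", {
  rec <- recording(matrix(0, nrow = 1, ncol = 20000), 20000)
  expect_warning(det <- detect_spikes(rec, filter = FALSE))
  expect_equal(nrow(det), 0L)
})

test_that("spike detection is deterministic on fixed input", {
  cfg <- mea_synth_config(n_electrodes = 2, duration = 5, background_rate = 5,
                          burst_rate = 0, superburst_rate = 0, seed = 4)
  sim <- generate_spike_trains(cfg)
  rec <- generate_voltage(sim$spikes, cfg)
  expect_identical(detect_spikes(rec), detect_spikes(rec))
})

test_that("raising N_S never increases the number of detections", {
  cfg <- mea_synth_config(n_electrodes = 2, duration = 10,
                          background_rate = 10, burst_rate = 0,
                          superburst_rate = 0, seed = 6)
  sim <- generate_spike_trains(cfg)
  rec <- generate_voltage(sim$spikes, cfg)
  counts <- vapply(c(3, 4, 5, 6, 8), function(ns) {
    nrow(detect_spikes(rec, spike_detection_params(n_s = ns)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("band edges are validated against the sampling rate", {
  rec <- recording(matrix(rnorm(1000), nrow = 1), 1000)
  expect_error(detect_spikes(rec))  # 8 kHz band edge above 500 Hz Nyquist
})
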