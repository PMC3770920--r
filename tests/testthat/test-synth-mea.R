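test_that("spike-train generation is deterministic in the seed", {
  cfg <- mea_preset("control-div26", n_electrodes = 8, duration = 120,
                    seed = 5)
  a <- generate_spike_trains(cfg)
  b <- generate_spike_trains(cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$truth, b$truth)
  c2 <- generate_spike_trains(mea_preset("control-div26", n_electrodes = 8,
                                         duration = 120, seed = 6))
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("ground-truth intervals are sane and spikes lie inside the span", {
  cfg <- mea_preset("hyase-div26", n_electrodes = 8, duration = 300, seed = 2)
  sim <- generate_spike_trains(cfg)
  for (tab in list(sim$truth$burst_intervals, sim$truth$superburst_intervals)) {
    expect_true(all(tab$start < tab$end))
    expect_true(all(tab$start >= 0 & tab$end <= cfg$duration))
    if (nrow(tab) > 1) {
      expect_true(all(tab$start[-1] >= tab$end[-nrow(tab)]))  # non-overlap
    }
  }
  expect_true(all(sim$spikes$time_s >= 0 & sim$spikes$time_s < cfg$duration))
  # sorted by channel then time, as documented
  for (ch in unique(sim$spikes$channel)) {
    expect_false(is.unsorted(sim$spikes$time_s[sim$spikes$channel == ch]))
  }
  expect_true(all(abs(sim$spikes$amplitude_uv) >= cfg$spike_amplitude_floor))
})

test_that("realized burst counts match the configured rate within 3 SE", {
  for (preset in c("control-div26", "hyase-div26")) {
    cfg <- mea_preset(preset, n_electrodes = 8, seed = 11)
    sim <- generate_spike_trains(cfg)
    expected <- expected_burst_count(cfg) * cfg$duration / 600
    got <- nrow(sim$truth$burst_intervals)
    expect_lt(abs(got - expected), 3 * sqrt(expected))
  }
})

test_that("drug modifiers scale rates as documented", {
  base <- mea_preset("hyase-div26", seed = 1)
  dzm <- mea_preset("hyase-div26", drug = "dzm", seed = 1)
  cnqx <- mea_preset("hyase-div26", drug = "cnqx", seed = 1)
  cpp <- mea_preset("hyase-div26", drug = "cpp", seed = 1)
  expect_equal(dzm$burst_rate, base$burst_rate * 0.5)
  expect_equal(cnqx$burst_rate, base$burst_rate * 0.2)
  expect_equal(dzm$superburst_rate, 0)
  expect_equal(cnqx$superburst_rate, 0)
  expect_equal(cpp$burst_rate, base$burst_rate)
})

test_that("zero rates produce an empty recording", {
  cfg <- mea_synth_config(n_electrodes = 4, duration = 30,
                          background_rate = 0, burst_rate = 0,
                          superburst_rate = 0, seed = 1)
  sim <- generate_spike_trains(cfg)
  expect_equal(nrow(sim$spikes), 0L)
  expect_equal(nrow(sim$truth$burst_intervals), 0L)
})

test_that("voltage synthesis embeds spikes at their ground-truth times", {
  cfg <- mea_synth_config(n_electrodes = 2, duration = 5, sampling_rate = 20000,
                          background_rate = 2, burst_rate = 0,
                          superburst_rate = 0, noise_sigma = 0,
                          spike_amplitude_mean = 60, spike_amplitude_sd = 0,
                          seed = 3)
  sim <- generate_spike_trains(cfg)
  rec <- generate_voltage(sim$spikes, cfg)
  expect_equal(dim(rec$voltage), c(2L, 5 * 20000))
  for (i in head(seq_len(nrow(sim$spikes)), 10)) {
    ch <- sim$spikes$channel[i]
    s0 <- round(sim$spikes$time_s[i] * 20000)
    seg <- rec$voltage[ch, max(1, s0 - 10):min(ncol(rec$voltage), s0 + 30)]
    expect_lt(min(seg), -50)  # negative peak close to the drawn amplitude
  }
})

test_that("invalid configurations raise configuration errors", {
  expect_error(mea_synth_config(burst_rate = -1))
  expect_error(mea_synth_config(duration = 0))
  expect_error(mea_preset("no-such-preset"))
})
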