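test_that("calcium generation is deterministic and bounded to [0, 255]", {
  cfg <- ca_preset("hyase-div19", n_neurons = 3, n_astrocytes = 2, seed = 7)
  a <- generate_calcium_traces(cfg)
  b <- generate_calcium_traces(cfg)
  expect_identical(lapply(a$traces, `[[`, "values"),
                   lapply(b$traces, `[[`, "values"))
  expect_identical(a$truth, b$truth)
  for (tr in a$traces) {
    expect_true(all(tr$values >= 0 & tr$values <= 255))
  }
})

test_that("zero rates, noise, and drift give a constant baseline trace", {
  cfg <- ca_synth_config(n_neurons = 1, n_astrocytes = 0, duration = 120,
                         osc_rate = 0, superosc_rate = 0, noise_sd = 0,
                         drift_amplitude = 0, seed = 1)
  sim <- generate_calcium_traces(cfg)
  expect_equal(length(unique(sim$traces[[1]]$values)), 1L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("neuron preset draws ordinary-event durations near 6 s", {
  cfg <- ca_preset("intact-div17", n_neurons = 6, n_astrocytes = 0, seed = 3)
  sim <- generate_calcium_traces(cfg)
  durs <- with(subset(sim$truth, kind == "pulse"), end - start)
  expect_gt(length(durs), 20)
  expect_gt(mean(durs), 5)
  expect_lt(mean(durs), 7)
})

test_that("event counts stay within 4 SD of the configured rate", {
  cfg <- ca_synth_config(n_neurons = 8, n_astrocytes = 0, duration = 600,
                         osc_rate = 20, superosc_rate = 0, seed = 9)
  sim <- generate_calcium_traces(cfg)
  n <- nrow(subset(sim$truth, kind == "pulse"))
  expected <- 8 * 20  # 8 cells x 20 events / 10 min
  expect_lt(abs(n - expected), 4 * sqrt(expected))
})

test_that("per-cell truth intervals do not overlap within a kind", {
  cfg <- ca_preset("hyase-div26", n_neurons = 4, n_astrocytes = 3, seed = 5)
  sim <- generate_calcium_traces(cfg)
  for (cid in unique(sim$truth$cell_id)) {
    for (k in unique(sim$truth$kind)) {
      tab <- subset(sim$truth, cell_id == cid & kind == k)
      tab <- tab[order(tab$start), ]
      if (nrow(tab) > 1) {
        expect_true(all(tab$start[-1] >= tab$end[-nrow(tab)]))
      }
    }
  }
})

test_that("image stacks round-trip through ROI extraction", {
  cfg <- ca_synth_config(n_neurons = 1, n_astrocytes = 0, duration = 30,
                         noise_sd = 0, drift_amplitude = 0, osc_rate = 10,
                         superosc_rate = 0, seed = 2)
  tr <- generate_calcium_traces(cfg)$traces[[1]]
  mask <- matrix(FALSE, 16, 16)
  mask[5:9, 6:10] <- TRUE
  stack <- generate_image_stack(tr, mask, dim = c(16, 16),
                                background = 10, pixel_noise_sd = 0)
  back <- extract_trace(stack, mask, sampling_rate = tr$sampling_rate)
  expect_equal(back$values, tr$values, tolerance = 1e-8)
})

test_that("invalid calcium configurations raise errors", {
  expect_error(ca_synth_config(osc_rate = -1))
  expect_error(ca_synth_config(duration = -5))
})
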