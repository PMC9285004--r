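small_cfg <- function(...) {
  scenario_config(grid_rows = 3, grid_cols = 3, duration_s = 120,
                  sle_onset_s = NA, spike_rate_hz = 0, ...)
}

test_that("background noise is seeded, calibrated, and order-independent", {
  cfg <- small_cfg(seed = 42)
  a <- generate_background(cfg)
  b <- generate_background(cfg)
  expect_identical(a$traces, b$traces)
  expect_false(identical(a$traces, generate_background(small_cfg(seed = 43))$traces))
  sds <- apply(a$traces, 2, sd)
  expect_true(all(sds > 0.018 & sds < 0.022))
  zero <- generate_background(small_cfg(noise_sd_mv = 0))
  expect_true(all(zero$traces == 0))
  # per-channel substreams: a channel's trace does not depend on grid size
  big <- generate_background(scenario_config(grid_rows = 4, grid_cols = 4,
                                             duration_s = 120,
                                             sle_onset_s = NA,
                                             spike_rate_hz = 0, seed = 42))
  expect_identical(a$traces[, a$channels$linear_index == 2],
                   big$traces[, big$channels$linear_index == 2])
})

test_that("interictal spike counts follow the configured Poisson rate", {
  cfg <- scenario_config(grid_rows = 1, grid_cols = 1, duration_s = 120,
                         sle_onset_s = NA, spike_rate_hz = 0.1, seed = 1)
  zero_rate <- scenario_config(grid_rows = 1, grid_cols = 1,
                               duration_s = 120, sle_onset_s = NA,
                               spike_rate_hz = 0, seed = 1)
  rec <- generate_background(zero_rate)
  out0 <- inject_interictal_spikes(rec, zero_rate)
  expect_identical(out0$recording$traces, rec$traces)

  total <- 0
  for (seed in 1:50) {
    cfg$seed <- seed
    res <- inject_interictal_spikes(generate_background(cfg), cfg)
    total <- total + length(res$truth$spike_times[[1]])
  }
  # 50 seeds x Poisson(12), 99% interval (collisions remove a few)
  expect_gt(total, qpois(0.005, 600) - 30)
  expect_lt(total, qpois(0.995, 600))
  expect_error(inject_interictal_spikes(
    rec, scenario_config(grid_rows = 1, grid_cols = 1, duration_s = 120,
                         sle_onset_s = NA, spike_rate_hz = 15,
                         spike_width_s = 0.05)), "too high")
})

test_that("peak detection at defaults recovers injected spike times", {
  cfg <- scenario_config(grid_rows = 2, grid_cols = 2, duration_s = 120,
                         sle_onset_s = NA, spike_rate_hz = 0.1, seed = 77)
  res <- inject_interictal_spikes(generate_background(cfg), cfg)
  hits <- 0
  truths <- 0
  for (j in seq_len(4)) {
    pk <- detect_lfp_peaks(res$recording$traces[, j], 300,
                           detection_params())
    tt <- res$truth$spike_times[[j]]
    truths <- truths + length(tt)
    for (t0 in tt) {
      if (any(abs(pk$time_s - t0) <= 0.02)) hits <- hits + 1
    }
  }
  expect_gte(hits / truths, 0.95)
})

test_that("the traveling wave lags channels by distance over speed", {
  cfg <- scenario_config(grid_rows = 5, grid_cols = 5, duration_s = 140,
                         sle_onset_s = 100, sle_duration_s = 20,
                         sle_speed_um_s = 1000, noise_sd_mv = 0,
                         spike_rate_hz = 0, sle_spike_rate_hz = 0, seed = 5)
  sc <- generate_scenario(cfg)
  truth <- sc$truth$channels
  # (row 3, col 3) origin; channel at 2 units -> 120 um -> 0.12 s lag
  i <- which(truth$row == 3 & truth$col == 5)
  expect_equal(truth$onset_s[i] - cfg$sle_onset_s, 120 / 1000)
  expect_equal(truth$lag_s, truth$distance_um / 1000)
  # waveform/truth consistency: first non-zero sample within 1 sample of onset
  for (j in c(1, 7, 13, 25)) {
    first <- which(abs(sc$recording$traces[, j]) > 1e-12)[1]
    expect_lt(abs((first - 1) / 300 - truth$onset_s[j]), 2 / 300)
  }
  # near-infinite speed: all onsets collapse to the origin onset
  fast <- scenario_config(grid_rows = 3, grid_cols = 3, duration_s = 140,
                          sle_onset_s = 100, sle_duration_s = 20,
                          sle_speed_um_s = 1e12, spike_rate_hz = 0, seed = 5)
  tf <- generate_scenario(fast)$truth$channels
  expect_true(all(abs(tf$onset_s - 100) < 1e-6))
  # wave leaving the recording is rejected
  expect_error(generate_scenario(
    scenario_config(grid_rows = 3, grid_cols = 3, duration_s = 110,
                    sle_onset_s = 100, sle_duration_s = 20,
                    spike_rate_hz = 0)), "exits")
})

test_that("scenarios are deterministic and round trip through HDF5", {
  cfg <- scenario_config(grid_rows = 3, grid_cols = 3, duration_s = 140,
                         sle_onset_s = 100, sle_duration_s = 20, seed = 9)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$recording$traces, b$recording$traces)
  expect_identical(a$truth$channels, b$truth$channels)
  path <- withr::local_tempfile(fileext = ".h5")
  write_recording(a$recording, path)
  back <- read_recording(path)
  expect_equal(n_channels(back), 9)
  expect_lt(max(abs(back$traces - a$recording$traces)), 1e-6)
  validate_recording(back)
})

test_that("scenario validation rejects inconsistent configurations", {
  expect_error(scenario_config(grid_rows = 70), "64 x 64")
  expect_error(scenario_config(sle_origin = c(30, 30), grid_rows = 20,
                               grid_cols = 20), "origin")
  expect_error(scenario_config(duration_s = -5), "positive")
  expect_error(scenario_config(sle_speed_um_s = 0), "positive")
})

test_that("truth-derived network metrics are internally consistent", {
  cfg <- scenario_config(duration_s = 140, sle_onset_s = 90,
                         sle_duration_s = 20, sle_speed_um_s = 500,
                         spike_rate_hz = 0, noise_sd_mv = 0.02, seed = 2)
  sc <- generate_scenario(cfg)
  tm <- truth_network_metrics(sc$truth, tie_tolerance_s = 0.25)
  expect_true(sc$truth$origin$linear_index %in% tm$initiators$linear_index)
  expect_equal(tm$mean_duration_s, 20)
  # the statistic equals speed x (max distance / mean non-initiator distance)
  ch <- sc$truth$channels
  non_init <- !(ch$linear_index %in% tm$initiators$linear_index)
  expected <- tm$max_distance_um /
    (mean(ch$distance_um[non_init]) / 500)
  expect_equal(tm$speed_um_s, expected)
})
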