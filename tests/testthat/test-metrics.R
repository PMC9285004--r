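fake_metrics <- function(linear_index, peak_count,
                         mean_amp = NA_real_, mean_dur = NA_real_) {
  tab <- linear_to_channel(linear_index)
  data.frame(row = tab$row, col = tab$col, linear_index = linear_index,
             peak_count = peak_count,
             peak_count_per_s = peak_count / 60,
             mean_amplitude_mv = mean_amp, mean_duration_s = mean_dur,
             delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0)
}

test_that("channel metrics average peak properties and normalise by time", {
  tr <- time_range(0, 60)
  m0 <- channel_metrics(mealfp:::empty_peaks(), rnorm(18000, 0, 0.01),
                        300, tr)
  expect_equal(m0$peak_count, 0)
  expect_true(is.na(m0$mean_amplitude_mv))
  expect_true(is.na(m0$mean_duration_s))

  pk <- data.frame(time_s = c(10, 20), amplitude_mv = c(0.1, 0.3),
                   width_s = c(0.02, 0.04), polarity = c(1L, -1L),
                   index = c(1L, 2L))
  m <- channel_metrics(pk, rnorm(18000, 0, 0.01), 300, tr)
  expect_equal(m$mean_amplitude_mv, 0.2)
  expect_equal(m$mean_duration_s, 0.03)

  pk30 <- data.frame(time_s = seq(1, 59, length.out = 30),
                     amplitude_mv = 0.1, width_s = 0.02, polarity = 1L,
                     index = seq_len(30))
  m30 <- channel_metrics(pk30, rnorm(18000, 0, 0.01), 300, tr)
  expect_equal(m30$peak_count_per_s, 0.5)

  expect_error(channel_metrics(pk30, rnorm(18000), 300, time_range(0, 30)),
               "longer than the analysed")
})

test_that("the active-channel rule is strictly greater than the cut", {
  m <- fake_metrics(1:3, c(21, 20, 19), mean_amp = 0.1, mean_dur = 0.02)
  g <- channel_group("g", 1:3)
  s <- group_summary(m, g, duration_s = 60)
  expect_equal(s$active_channels, 1)
  expect_equal(s$total_channels, 3)
})

test_that("group means follow the stated per-channel averaging formula", {
  m <- fake_metrics(1:3, c(30, 30, 30), mean_amp = c(0.1, 0.2, 0.3),
                    mean_dur = c(0.01, 0.02, 0.03))
  s <- group_summary(m, channel_group("g", 1:3), duration_s = 60)
  expect_equal(s$mean_amplitude_mv, 0.2)
  expect_equal(s$topN_mean_amplitude_mv, 0.2)
  expect_equal(s$mean_duration_s, 0.02)
  expect_equal(s$total_peak_count_per_s, 90 / 60)
})

test_that("top-N statistics use the N most active channels with deterministic ties", {
  n <- 25
  m <- fake_metrics(1:n, peak_count = 100 + seq_len(n),
                    mean_amp = seq_len(n) / 100, mean_dur = 0.02)
  s <- group_summary(m, channel_group("g", 1:n), duration_s = 60, N = 20)
  expect_equal(s$N, 20)
  # the 20 largest counts are channels 6..25
  expect_equal(s$topN_peak_count_per_s, sum(100 + 6:25) / 60)
  expect_equal(s$topN_mean_amplitude_mv, mean(6:25 / 100))
  # tie at the boundary: all equal counts, lower linear index first
  m2 <- fake_metrics(1:25, peak_count = rep(50, 25),
                     mean_amp = seq_len(25) / 100, mean_dur = 0.02)
  s2 <- group_summary(m2, channel_group("g", 1:25), duration_s = 60, N = 20)
  expect_equal(s2$topN_mean_amplitude_mv, mean(1:20 / 100))
  expect_error(group_summary(m2, channel_group("g", c(1, 99)), 60),
               "missing")
})

test_that("group summary invariant: total rate equals summed member rate", {
  set.seed(9)
  for (k in 1:10) {
    n <- sample(3:30, 1)
    counts <- rpois(n, 25)
    m <- fake_metrics(seq_len(n), counts, mean_amp = runif(n),
                      mean_dur = runif(n, 0, 0.1))
    dur <- runif(1, 10, 300)
    s <- group_summary(m, channel_group("g", seq_len(n)), duration_s = dur)
    expect_equal(s$total_peak_count_per_s, sum(counts) / dur)
    expect_lte(s$active_channels, s$total_channels)
  }
})

test_that("rasters conserve event counts and order channels by linear index", {
  empty <- build_raster(list(`5` = numeric(), `2` = numeric()),
                        time_range(0, 10))
  expect_equal(sum(empty$counts), 0)
  expect_equal(empty$linear_index, c(2L, 5L))

  r <- build_raster(list(`1` = data.frame(time_s = 5.2)), time_range(0, 10),
                    bin_s = 1)
  expect_equal(sum(r$counts), 1)
  expect_equal(which(r$counts[1, ] > 0), 6)  # bin [5, 6)

  set.seed(4)
  for (k in 1:10) {
    peaks <- lapply(1:5, function(i) sort(runif(rpois(1, 20), 0, 60)))
    names(peaks) <- sample(4096, 5)
    r <- build_raster(peaks, time_range(0, 60), bin_s = runif(1, 0.5, 7))
    expect_equal(sum(r$counts), sum(lengths(peaks)))
  }
  expect_error(build_raster(list(`1` = 11), time_range(0, 10)), "outside")
})

test_that("per-channel CSV export has the documented schema and is deterministic", {
  m <- fake_metrics(c(1, 2, 65), c(0, 12, 40),
                    mean_amp = c(NA, 0.1, 0.2), mean_dur = c(NA, 0.02, 0.03))
  groups <- list(channel_group("Group1", c(1, 2)),
                 channel_group("Group2", 65))
  tr <- time_range(0, 60)
  path <- withr::local_tempfile(fileext = ".csv")
  export_channel_metrics_csv(m, groups, tr, path)
  got <- read.csv(path)
  expect_equal(nrow(got), 3)
  expect_equal(names(got),
               c("lfp_peak_count", "mean_peak_amplitude_mv",
                 "mean_peak_duration_s", "delta_power_v2hz",
                 "theta_power_v2hz", "alpha_power_v2hz", "beta_power_v2hz",
                 "gamma_power_v2hz", "channel", "group",
                 "time_start_s", "time_end_s"))
  expect_equal(got$channel, c(1, 2, 65))
  expect_equal(got$group, c(1, 1, 2))
  # zero-peak channel exports empty (NA on read back), not 0
  expect_true(is.na(got$mean_peak_amplitude_mv[1]))
  expect_equal(got$lfp_peak_count[1], 0)
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_channel_metrics_csv(m, groups, tr, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  expect_error(export_channel_metrics_csv(m, groups[1], tr, path),
               "no group")
})

test_that("recording metrics combine detection, band power and peak logs", {
  set.seed(21)
  fs <- 300
  n <- fs * 30
  traces <- matrix(rnorm(2 * n, 0, 0.01), n, 2)
  # channel 1 gets 40 clear spikes
  at <- round(seq(2, 28, length.out = 40) * fs)
  w <- round(0.04 * fs)
  for (i in at) {
    traces[i:(i + w - 1), 1] <- traces[i:(i + w - 1), 1] +
      0.2 * sin(pi * (0:(w - 1)) / w)
  }
  rec <- mea_recording(traces, channel_id(1, 1:2), fs)
  res <- recording_metrics(rec)
  expect_equal(nrow(res$metrics), 2)
  expect_gte(res$metrics$peak_count[1], 38)
  expect_lte(res$metrics$peak_count[2], 2)
  expect_true(all(c("delta", "theta", "alpha", "beta", "gamma") %in%
                    names(res$metrics)))
  expect_equal(res$metrics$peak_count_per_s,
               res$metrics$peak_count / 30)
})
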