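noise_trace <- function(seed, dur_s = 120, fs = 300, sd = 0.02) {
  set.seed(seed)
  rnorm(dur_s * fs, 0, sd)
}

fake_frame <- function(summed, segment_s = 1) {
  nb <- length(summed)
  structure(list(times_s = (seq_len(nb) - 0.5) * segment_s,
                 freqs_hz = c(0, 1), magnitude = rbind(summed, summed),
                 summed_magnitude = summed, segment_s = segment_s,
                 sample_rate_hz = 300),
            class = "spectrogram_frame")
}

fake_baseline <- function(v_mean = 0, v_sd = 0.02, s_mean = 1, s_sd = 0.1) {
  structure(list(window = time_range(0, 60), voltage_mean_mv = v_mean,
                 voltage_sd_mv = v_sd, spectral_mean = s_mean,
                 spectral_sd = s_sd),
            class = "baseline_stats")
}

test_that("baseline selection avoids high-amplitude sections", {
  # exact score ties (constant trace): earliest candidate window wins
  bt <- suppressWarnings(select_baseline(numeric(120 * 300), 300))
  expect_equal(bt$window$start_s, 0)
  expect_equal(bt$window$end_s, 60)
  # stationary noise: stats reflect the noise floor
  b <- suppressWarnings(select_baseline(noise_trace(1, 120), 300))
  expect_lt(abs(b$voltage_sd_mv - 0.02), 0.002)
  expect_gt(b$spectral_sd, 0)

  # 20 s burst at 100-120 s: the chosen window must not touch it
  x <- noise_trace(2, 300)
  burst <- seq(100 * 300, 120 * 300)
  x[burst] <- x[burst] + 0.5 * sin(2 * pi * 8 * seq_along(burst) / 300)
  b2 <- select_baseline(x, 300)
  expect_true(b2$window$end_s <= 100 || b2$window$start_s >= 120)

  expect_error(select_baseline(rnorm(30 * 300), 300), "shorter")
})

test_that("spectral thresholding matches the elementwise definition", {
  base <- fake_baseline(s_mean = 1, s_sd = 0.1)
  p <- seizure_params()
  act0 <- detect_spectral_activity(fake_frame(rep(1, 50)), base, p)
  expect_false(any(act0$active))
  one_hot <- rep(1, 50)
  one_hot[17] <- 1 + 7 * 0.1
  act1 <- detect_spectral_activity(fake_frame(one_hot), base, p)
  expect_equal(which(act1$active), 17)
  set.seed(5)
  mags <- abs(rnorm(200, 1, 0.3))
  act <- detect_spectral_activity(fake_frame(mags), base, p)
  expect_equal(act$active, mags > 1 + 6 * 0.1)
  expect_error(detect_spectral_activity(fake_frame(rep(1, 10)),
                                        fake_baseline(s_sd = 0), p),
               "degenerate")
})

test_that("LFP activity stream marks injected events and rejects flat traces", {
  p <- seizure_params()
  base <- fake_baseline(v_mean = 0, v_sd = 0.02)
  expect_error(detect_lfp_activity(numeric(3000), 300,
                                   fake_baseline(v_sd = 0), p),
               "degenerate")
  # injected 1 mV, 0.05 s events on 0.02 mV noise: all marked
  x <- noise_trace(3, 60)
  at <- c(10, 25, 40, 52)
  w <- round(0.05 * 300)
  for (t0 in at) {
    i <- round(t0 * 300)
    x[i:(i + w - 1)] <- x[i:(i + w - 1)] + 1 * sin(pi * (0:(w - 1)) / w)
  }
  act <- detect_lfp_activity(x, 300, base, p)
  for (t0 in at) {
    expect_true(any(act$active[round(t0 * 300) + 0:w]),
                info = paste("event at", t0))
  }
  # pure noise: well under 0.1% of samples active at 6 SD with width gate
  frac <- mean(detect_lfp_activity(noise_trace(4, 120), 300, base,
                                   p)$active)
  expect_lt(frac, 0.001)
})

test_that("continuity filtering matches a naive moving-mean oracle", {
  p <- seizure_params(window_short = 6L, window_long = 20L)
  mk <- function(active, dt = 1 / 300) {
    mealfp:::activity_series((seq_along(active) - 1) * dt, active, "lfp", dt)
  }
  expect_equal(continuity_filter(mk(rep(FALSE, 200)), p), list())
  expect_error(continuity_filter(mk(rep(TRUE, 10)), p), "longer")

  # solid active block saturates the density
  blk <- c(rep(FALSE, 100), rep(TRUE, 60), rep(FALSE, 100))
  got <- continuity_filter(mk(blk), p)
  expect_equal(length(got), 1)
  expect_lt(abs(got[[1]]$start_s - 100 / 300), 6 / 300)
  expect_lt(abs(got[[1]]$end_s - 160 / 300), 6 / 300)

  set.seed(8)
  for (k in 1:25) {
    act <- runif(300) < 0.12
    got <- continuity_filter(mk(act), p)
    ref <- oracle_continuity_regions(act, 6, 20, p$density_cutoff_short,
                                     p$density_cutoff_long)
    expect_equal(length(got), length(ref), info = paste("case", k))
    for (i in seq_along(ref)) {
      expect_equal(got[[i]]$start_s, (ref[[i]][1] - 1) / 300)
      expect_equal(got[[i]]$end_s, ref[[i]][2] / 300)
    }
  }
})

test_that("short bursts never become envelopes (10 s minimum)", {
  set.seed(31)
  x <- noise_trace(31, 170)
  burst <- seq(120 * 300, 128 * 300)  # 8 s
  x[burst] <- x[burst] + 0.5 * sin(2 * pi * 8 * seq_along(burst) / 300)
  env <- suppressWarnings(detect_seizure_envelopes(x, 300))
  expect_equal(nrow(env), 0)
  expect_error(detect_seizure_envelopes(rnorm(60 * 300), 300), "too short")
})

test_that("a sustained burst yields one accurately timed envelope", {
  x <- noise_trace(32, 170)
  i0 <- 120 * 300
  trel <- (seq.int(i0, 150 * 300) - i0) / 300
  x[i0 + seq_along(trel) - 1] <- x[i0 + seq_along(trel) - 1] +
    0.5 * pmin(1, trel / 2) * sin(2 * pi * 8 * trel)
  env <- suppressWarnings(detect_seizure_envelopes(x, 300))
  expect_equal(nrow(env), 1)
  expect_lt(abs(env$start_s - 120), 2)
  expect_lt(abs(env$duration_s - 30), 5)
})

test_that("initiator ties follow the start-time tolerance", {
  env <- cbind(linear_to_channel(c(10, 20, 30)),
               data.frame(start_s = c(10.0, 10.4, 13.0),
                          end_s = c(40, 41, 42)))
  win <- time_range(0, 60)
  init <- find_initiators(env, win, tie_tolerance_s = 1)
  expect_equal(sort(init$linear_index), c(10, 20))
  init2 <- find_initiators(env, win, tie_tolerance_s = 0.25)
  expect_equal(init2$linear_index, 10)
  single <- find_initiators(env[1, ], win)
  expect_equal(single$linear_index, 10)
  # oracle comparison on random starts
  set.seed(12)
  for (k in 1:20) {
    n <- sample(2:40, 1)
    starts <- runif(n, 0, 30)
    e <- cbind(linear_to_channel(sample(4096, n)),
               data.frame(start_s = starts, end_s = starts + 15))
    got <- find_initiators(e, time_range(0, 60), tie_tolerance_s = 1)
    ref <- e$linear_index[starts <= min(starts) + 1]
    expect_equal(sort(got$linear_index), sort(ref))
  }
})

test_that("maximum spread distance is the exhaustive pairwise maximum", {
  one <- channel_id(1, 1)
  expect_equal(max_spread_distance(one, one, 60), 0)
  expect_equal(max_spread_distance(rbind(channel_id(1, 1), channel_id(1, 11)),
                                   channel_id(1, 1), 60), 600)
  set.seed(13)
  for (k in 1:10) {
    part <- linear_to_channel(sample(4096, 50))
    init <- part[sample(50, 3), ]
    got <- max_spread_distance(part, init, 60)
    ref <- 0
    for (i in seq_len(nrow(init))) {
      for (j in seq_len(nrow(part))) {
        ref <- max(ref, sqrt((init$row[i] - part$row[j])^2 +
                               (init$col[i] - part$col[j])^2) * 60)
      }
    }
    expect_equal(got, ref)
  }
  expect_error(max_spread_distance(one, channel_id(2, 2), 60), "subset")
})

test_that("durations and propagation speed follow the stated formulas", {
  env <- cbind(linear_to_channel(c(1, 2, 3)),
               data.frame(start_s = c(100, 100, 100),
                          end_s = c(110, 120, 130)))
  d <- sle_durations(env, time_range(90, 200))
  expect_equal(sort(d$per_channel$duration_s), c(10, 20, 30))
  expect_equal(d$mean_s, 20)
  expect_equal(d$max_s, 30)

  one_env <- cbind(linear_to_channel(7),
                   data.frame(start_s = 100, end_s = 130))
  expect_equal(sle_durations(one_env, time_range(0, 200))$mean_s, 30)

  # initiator at t=0 plus one channel 600 um away starting at t=2 s
  starts <- cbind(linear_to_channel(c(1, 11)),
                  data.frame(start_s = c(0, 2), end_s = c(20, 22)))
  init <- starts[1, ]
  sp <- propagation_speed(starts, init, 600)
  expect_true(sp$defined)
  expect_equal(sp$speed_um_s, 300)

  # all in the same tie window: undefined
  same <- cbind(linear_to_channel(c(1, 2)),
                data.frame(start_s = c(10, 10.1), end_s = c(30, 30)))
  sp2 <- propagation_speed(same, same, 600)
  expect_false(sp2$defined)
  expect_true(is.na(sp2$speed_um_s))
})

test_that("group metrics compose and are order-independent", {
  env <- cbind(linear_to_channel(c(5, 70, 135)),
               data.frame(start_s = c(100, 101, 102),
                          end_s = c(130, 129, 128)))
  env$duration_s <- env$end_s - env$start_s
  g <- channel_group("g", linear_to_channel(c(5, 70, 135, 200)))
  m <- sle_group_metrics(env, g, time_range(90, 150), 60)
  expect_true(m$has_sle)
  expect_equal(nrow(m$participating), 3)
  expect_equal(m$non_participating$linear_index, 200)
  expect_equal(m$initiators$linear_index, 5)
  expect_equal(m$mean_duration_s, mean(c(30, 28, 26)))
  perm <- env[c(3, 1, 2), ]
  m2 <- sle_group_metrics(perm, g, time_range(90, 150), 60)
  expect_equal(m2$max_distance_um, m$max_distance_um)
  expect_equal(m2$propagation_speed_um_s, m$propagation_speed_um_s)
  expect_equal(sort(m2$initiators$linear_index),
               sort(m$initiators$linear_index))

  none <- sle_group_metrics(env[0, ], g, time_range(0, 50), 60)
  expect_false(none$has_sle)
  expect_equal(nrow(none$participating), 0)
  expect_true(is.na(none$propagation_speed_um_s))
})

test_that("envelope tables export to CSV deterministically", {
  env <- cbind(linear_to_channel(c(9, 3)),
               data.frame(start_s = c(10, 12), end_s = c(25, 30),
                          duration_s = c(15, 18)))
  p1 <- withr::local_tempfile(fileext = ".csv")
  export_envelopes_csv(env, p1)
  got <- read.csv(p1)
  expect_equal(got$channel, c(3, 9))
  expect_equal(names(got),
               c("channel", "row", "col", "start_s", "end_s", "duration_s"))
})
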