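#' Synthetic recording scenario
#'
#' Configuration for the seedable generator of synthetic MEA recordings:
#' per-channel Gaussian background noise, interictal spikes (biphasic
#' half-sine transients at Poisson times), and a radially traveling
#' seizure-like event — an amplitude-ramped sustained oscillation with
#' Poisson spike riders whose onset at each channel lags the origin onset
#' by grid distance / wave speed. The defaults emulate a low-Mg2+
#' ictogenesis recording on a 400-channel (20 x 20) patch of the array:
#' 300 Hz working rate, 0.02 mV noise floor, a focal SLE starting at
#' 120 s, spreading at 1,000 um/s, and discharging at 8 Hz for 30 s at
#' 0.5 mV.
#'
#' @param grid_rows,grid_cols Grid extent used (1-based sub-grid of the
#'   64 x 64 array).
#' @param duration_s Recording length, s.
#' @param sample_rate_hz Sampling rate, Hz (default 300).
#' @param noise_sd_mv Background noise SD, mV (default 0.02).
#' @param spike_rate_hz Interictal spike rate per channel, Hz (0 disables).
#' @param spike_amplitude_mv,spike_width_s Interictal spike lobe amplitude
#'   (mV) and total biphasic width (s).
#' @param sle_origin Origin channel, `c(row, col)` (default grid centre);
#'   `NULL` together with `sle_onset_s = NA` disables the SLE.
#' @param sle_onset_s SLE onset time at the origin, s (`NA` disables).
#' @param sle_speed_um_s Radial propagation speed, um/s.
#' @param sle_duration_s Burst duration at each channel, s.
#' @param sle_osc_freq_hz Discharge oscillation frequency, Hz (default 8).
#' @param sle_amplitude_mv Burst oscillation amplitude, mV.
#' @param sle_ramp_s Linear amplitude ramp into the burst, s (default 2).
#' @param sle_spike_rate_hz Rate of spike riders during the burst, Hz.
#' @param pitch_um Electrode pitch, um (default 60).
#' @param seed Master seed; per-channel substreams are derived from it and
#'   the channel's linear index, so results do not depend on channel
#'   iteration order.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(grid_rows = 20L, grid_cols = 20L,
                            duration_s = 240, sample_rate_hz = 300,
                            noise_sd_mv = 0.02,
                            spike_rate_hz = 0.1,
                            spike_amplitude_mv = 0.15,
                            spike_width_s = 0.05,
                            sle_origin = NULL, sle_onset_s = 120,
                            sle_speed_um_s = 1000, sle_duration_s = 30,
                            sle_osc_freq_hz = 8, sle_amplitude_mv = 0.5,
                            sle_ramp_s = 2, sle_spike_rate_hz = 2,
                            pitch_um = 60, seed = 1L) {
  if (is.null(sle_origin)) {
    sle_origin <- c(ceiling(grid_rows / 2), ceiling(grid_cols / 2))
  }
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              duration_s = duration_s, sample_rate_hz = sample_rate_hz,
              noise_sd_mv = noise_sd_mv, spike_rate_hz = spike_rate_hz,
              spike_amplitude_mv = spike_amplitude_mv,
              spike_width_s = spike_width_s,
              sle_origin = as.integer(sle_origin),
              sle_onset_s = sle_onset_s,
              sle_speed_um_s = sle_speed_um_s,
              sle_duration_s = sle_duration_s,
              sle_osc_freq_hz = sle_osc_freq_hz,
              sle_amplitude_mv = sle_amplitude_mv,
              sle_ramp_s = sle_ramp_s,
              sle_spike_rate_hz = sle_spike_rate_hz,
              pitch_um = pitch_um, seed = as.integer(seed))
  if (cfg$grid_rows < 1L || cfg$grid_rows > 64L || cfg$grid_cols < 1L ||
      cfg$grid_cols > 64L) {
    stop("grid extent must lie within the 64 x 64 array", call. = FALSE)
  }
  if (cfg$duration_s <= 0 || cfg$sample_rate_hz <= 0 ||
      cfg$noise_sd_mv < 0 || cfg$spike_rate_hz < 0) {
    stop("durations and rates must be positive", call. = FALSE)
  }
  if (!is.na(cfg$sle_onset_s)) {
    if (cfg$sle_origin[1] < 1L || cfg$sle_origin[1] > cfg$grid_rows ||
        cfg$sle_origin[2] < 1L || cfg$sle_origin[2] > cfg$grid_cols) {
      stop("SLE origin outside the configured grid", call. = FALSE)
    }
    if (cfg$sle_speed_um_s <= 0 || cfg$sle_duration_s <= 0) {
      stop("SLE speed and duration must be positive", call. = FALSE)
    }
  }
  structure(cfg, class = "scenario_config")
}

# Deterministic per-channel substream seed; independent of iteration order
# and kept below 2^31.
channel_seed <- function(master, linear_index, stream = 0L) {
  (as.numeric(master) * 100003 + linear_index * 7919 +
     stream * 15485863) %% 2147483629 + 1
}

scenario_channels <- function(config) {
  grid <- expand.grid(col = seq_len(config$grid_cols),
                      row = seq_len(config$grid_rows))
  tab <- channel_id(grid$row, grid$col)
  tab[order(tab$linear_index), , drop = FALSE]
}

#' Generate seeded background noise
#'
#' Independent Gaussian noise per channel with SD `noise_sd_mv`; the same
#' seed reproduces the recording bit for bit.
#'
#' @param config A [scenario_config()].
#' @return A [mea_recording()].
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  tab <- scenario_channels(config)
  n <- round(config$duration_s * config$sample_rate_hz)
  traces <- matrix(0, n, nrow(tab))
  for (j in seq_len(nrow(tab))) {
    set.seed(channel_seed(config$seed, tab$linear_index[j], 0L))
    traces[, j] <- stats::rnorm(n, 0, config$noise_sd_mv)
  }
  mea_recording(traces, tab, config$sample_rate_hz, config$pitch_um)
}

# Biphasic half-sine spike waveform sampled at fs: positive then negative
# lobe, `width_s` total.
spike_waveform <- function(amplitude_mv, width_s, fs) {
  n <- max(2L, round(width_s * fs))
  amplitude_mv * sin(2 * pi * seq.int(0L, n - 1L) / n)
}

# Add spikes at `times` (s, waveform start) to a trace; returns trace.
add_spikes <- function(trace, times, wave, fs) {
  for (t0 in times) {
    i0 <- floor(t0 * fs) + 1L
    i1 <- min(length(trace), i0 + length(wave) - 1L)
    if (i0 <= length(trace)) {
      trace[i0:i1] <- trace[i0:i1] + wave[seq_len(i1 - i0 + 1L)]
    }
  }
  trace
}

#' Inject interictal spikes
#'
#' Adds biphasic half-sine transients at seeded Poisson times to every
#' channel. Spikes overlapping a previously placed spike on the same
#' channel are dropped so events stay isolated. The ground-truth log
#' records the positive-lobe apex time of every kept spike.
#'
#' @param rec A [mea_recording()] (typically from
#'   [generate_background()]).
#' @param config A [scenario_config()] with `spike_rate_hz > 0`.
#' @return List with `recording` and `truth` (list with per-channel
#'   `spike_times`).
#' @export
inject_interictal_spikes <- function(rec, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (round(config$spike_width_s * config$sample_rate_hz) < 2) {
    stop("spike width must span at least 2 samples", call. = FALSE)
  }
  if (config$spike_rate_hz * config$spike_width_s > 0.5) {
    stop("spike rate too high for the spike width", call. = FALSE)
  }
  dur <- recording_duration(rec)
  wave <- spike_waveform(config$spike_amplitude_mv, config$spike_width_s,
                         rec$sample_rate_hz)
  spike_times <- vector("list", n_channels(rec))
  names(spike_times) <- as.character(rec$channels$linear_index)
  if (config$spike_rate_hz > 0) {
    for (j in seq_len(n_channels(rec))) {
      set.seed(channel_seed(config$seed, rec$channels$linear_index[j], 1L))
      k <- stats::rpois(1, config$spike_rate_hz * dur)
      t0 <- sort(stats::runif(k, 0, dur - config$spike_width_s))
      if (length(t0) > 1L) {
        keep <- c(TRUE, diff(t0) >= config$spike_width_s)
        t0 <- t0[keep]
      }
      rec$traces[, j] <- add_spikes(rec$traces[, j], t0, wave,
                                    rec$sample_rate_hz)
      spike_times[[j]] <- t0 + config$spike_width_s / 4  # positive apex
    }
  }
  list(recording = rec, truth = list(spike_times = spike_times))
}

#' Inject a radially traveling seizure-like event
#'
#' Every channel at distance d um from the origin receives a burst
#' starting at `sle_onset_s + d / sle_speed_um_s`: a `sle_duration_s`
#' sinusoidal discharge at `sle_osc_freq_hz` with a linear amplitude ramp
#' over the first `sle_ramp_s`, plus Poisson spike riders, so both the
#' spectral and the LFP branch of the detector see sustained activity.
#' The ground truth holds each channel's exact onset/offset.
#'
#' @param rec A [mea_recording()].
#' @param config A [scenario_config()] with `sle_onset_s` set.
#' @return List with `recording` and `truth` (data frame `channels` with
#'   `onset_s`, `offset_s`, `distance_um`, plus `origin`, `speed_um_s`).
#' @export
inject_traveling_sle <- function(rec, config) {
  stopifnot(inherits(config, "scenario_config"), !is.na(config$sle_onset_s))
  origin <- channel_id(config$sle_origin[1], config$sle_origin[2])
  d_um <- channel_distance_um(rec$channels, origin, rec$pitch_um)
  onset <- config$sle_onset_s + d_um / config$sle_speed_um_s
  offset <- onset + config$sle_duration_s
  if (any(offset > recording_duration(rec))) {
    stop("traveling wave exits the recording window", call. = FALSE)
  }
  fs <- rec$sample_rate_hz
  rider_wave <- spike_waveform(config$sle_amplitude_mv, 0.05, fs)
  for (j in seq_len(n_channels(rec))) {
    i0 <- floor(onset[j] * fs) + 1L
    i1 <- min(nrow(rec$traces), ceiling(offset[j] * fs))
    trel <- (seq.int(i0, i1) - 1) / fs - onset[j]
    ramp <- pmin(1, trel / config$sle_ramp_s)
    burst <- config$sle_amplitude_mv * ramp *
      sin(2 * pi * config$sle_osc_freq_hz * trel)
    set.seed(channel_seed(config$seed, rec$channels$linear_index[j], 2L))
    k <- stats::rpois(1, config$sle_spike_rate_hz * config$sle_duration_s)
    rider_t <- sort(stats::runif(k, 0, config$sle_duration_s - 0.05))
    seg <- burst
    seg <- add_spikes(seg, rider_t, rider_wave, fs)
    # scale riders by the same ramp so onset stays graded
    seg <- burst + (seg - burst) * ramp
    rec$traces[i0:i1, j] <- rec$traces[i0:i1, j] + seg
  }
  truth_channels <- cbind(rec$channels,
                          data.frame(onset_s = onset, offset_s = offset,
                                     distance_um = d_um,
                                     lag_s = d_um / config$sle_speed_um_s))
  list(recording = rec,
       truth = list(channels = truth_channels, origin = origin,
                    speed_um_s = config$sle_speed_um_s,
                    onset_s = config$sle_onset_s,
                    duration_s = config$sle_duration_s))
}

#' Generate a full synthetic scenario
#'
#' Composition of [generate_background()], [inject_interictal_spikes()]
#' and [inject_traveling_sle()] according to the configuration; fully
#' deterministic under a fixed seed.
#'
#' @param config A [scenario_config()].
#' @return List of class `mea_scenario` with `recording` and `truth`
#'   (class `scenario_truth`): per-channel SLE onsets/offsets, origin,
#'   wave speed, and injected spike times.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  rec <- generate_background(config)
  truth <- list(config = config, spike_times = NULL, channels = NULL,
                origin = NULL, speed_um_s = NA_real_,
                onset_s = NA_real_, duration_s = NA_real_)
  if (config$spike_rate_hz > 0) {
    res <- inject_interictal_spikes(rec, config)
    rec <- res$recording
    truth$spike_times <- res$truth$spike_times
  }
  if (!is.na(config$sle_onset_s)) {
    res <- inject_traveling_sle(rec, config)
    rec <- res$recording
    truth$channels <- res$truth$channels
    truth$origin <- res$truth$origin
    truth$speed_um_s <- res$truth$speed_um_s
    truth$onset_s <- res$truth$onset_s
    truth$duration_s <- res$truth$duration_s
  }
  structure(list(recording = rec,
                 truth = structure(truth, class = "scenario_truth")),
            class = "mea_scenario")
}

#' Network metrics implied by the ground truth
#'
#' Applies the group network-metric definitions (initiator ties, maximum
#' spread, mean non-initiator onset lag) to the *true* per-channel onsets
#' of a scenario. This is the reference value a perfect detector would
#' recover; note the propagation-speed statistic equals the wave speed
#' only up to the geometry factor `max distance / mean distance` of the
#' non-initiator channels (see the methods vignette).
#'
#' @param truth A `scenario_truth` from [generate_scenario()].
#' @param tie_tolerance_s Co-initiator tolerance, s (match the detector's).
#' @return List with `initiators`, `max_distance_um`, `mean_duration_s`,
#'   `max_duration_s`, `speed_um_s`, `mean_lag_s`.
#' @export
truth_network_metrics <- function(truth, tie_tolerance_s = 0.25) {
  stopifnot(inherits(truth, "scenario_truth"), !is.null(truth$channels))
  ch <- truth$channels
  t_min <- min(ch$onset_s)
  init <- ch[ch$onset_s <= t_min + tie_tolerance_s, , drop = FALSE]
  dist <- max_spread_distance(ch, init, truth$config$pitch_um)
  non_init <- !(ch$linear_index %in% init$linear_index)
  mean_lag <- if (any(non_init)) mean(ch$onset_s[non_init] - t_min) else
    NA_real_
  list(initiators = init, max_distance_um = dist,
       mean_duration_s = mean(ch$offset_s - ch$onset_s),
       max_duration_s = max(ch$offset_s - ch$onset_s),
       speed_um_s = if (is.na(mean_lag) || mean_lag <= 0) NA_real_ else
         dist / mean_lag,
       mean_lag_s = mean_lag)
}

#' Write the ground truth as a JSON sidecar
#'
#' @param truth A `scenario_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "scenario_truth"))
  out <- list(
    config = unclass(truth$config),
    origin = truth$origin,
    speed_um_s = truth$speed_um_s,
    onset_s = truth$onset_s,
    duration_s = truth$duration_s,
    channels = truth$channels,
    spike_times = truth$spike_times)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
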