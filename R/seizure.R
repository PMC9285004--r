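#' Seizure detection parameters
#'
#' Parameters of the unsupervised seizure-like-event (SLE) detector. Per
#' channel, two activity streams are thresholded against a quiet baseline
#' window: the summed STFT magnitude per 1 s bin (spectral stream) and
#' threshold/duration LFP peaks on the raw voltage (LFP stream). Each
#' stream is smoothed by two centred sliding windows into intervals of
#' continuous activity, and overlaps of the two streams lasting at least
#' `min_envelope_s` become seizure envelopes.
#'
#' @param baseline_len_s Baseline window length, s (default 60).
#' @param baseline_search_s Portion of the recording searched for the
#'   baseline window, s (default 300 — the first 5 minutes).
#' @param spectral_k Threshold multiplier: spectral activity when the
#'   summed magnitude exceeds baseline mean + `spectral_k` SD (default 6).
#' @param voltage_k LFP peak threshold in baseline-voltage SDs (default 6).
#' @param lfp_event_duration_s Minimum LFP peak width, s (default 0.035).
#' @param window_short,window_long Sliding-window lengths, in datapoints of
#'   the LFP sample stream (defaults 30 and 500).
#' @param spectral_window_short,spectral_window_long Sliding-window lengths
#'   in spectral bins (defaults 5 and 30; the sample-stream defaults
#'   rescaled to the 1 s bin stream).
#' @param density_cutoff_short Fraction of active points within the short
#'   window required to call a time point active (default 0.1).
#' @param density_cutoff_long Long-window density above which the gap
#'   between two active regions is bridged (default 0.05).
#' @param min_envelope_s Minimum overlap of spectral and LFP activity to
#'   declare an envelope, s (default 10).
#' @param merge_gap_s Envelopes separated by less than this are merged
#'   (default 0, no merging).
#' @param segment_s STFT segment length, s (default 1, Hann, no overlap).
#' @param tie_tolerance_s Start-time tolerance within which channels count
#'   as co-initiators of an SLE, s (default 0.25; see the methods
#'   vignette for the choice).
#' @return An object of class `seizure_params`.
#' @export
seizure_params <- function(baseline_len_s = 60, baseline_search_s = 300,
                           spectral_k = 6, voltage_k = 6,
                           lfp_event_duration_s = 0.035,
                           window_short = 30L, window_long = 500L,
                           spectral_window_short = 5L,
                           spectral_window_long = 30L,
                           density_cutoff_short = 0.1,
                           density_cutoff_long = 0.05,
                           min_envelope_s = 10, merge_gap_s = 0,
                           segment_s = 1, tie_tolerance_s = 0.25) {
  p <- list(baseline_len_s = baseline_len_s,
            baseline_search_s = baseline_search_s,
            spectral_k = spectral_k, voltage_k = voltage_k,
            lfp_event_duration_s = lfp_event_duration_s,
            window_short = as.integer(window_short),
            window_long = as.integer(window_long),
            spectral_window_short = as.integer(spectral_window_short),
            spectral_window_long = as.integer(spectral_window_long),
            density_cutoff_short = density_cutoff_short,
            density_cutoff_long = density_cutoff_long,
            min_envelope_s = min_envelope_s, merge_gap_s = merge_gap_s,
            segment_s = segment_s, tie_tolerance_s = tie_tolerance_s)
  if (p$window_short >= p$window_long ||
      p$spectral_window_short >= p$spectral_window_long) {
    stop("short sliding window must be shorter than the long window",
         call. = FALSE)
  }
  if (p$min_envelope_s <= 0 || p$spectral_k <= 0 || p$voltage_k <= 0) {
    stop("min_envelope_s and threshold multipliers must be positive",
         call. = FALSE)
  }
  if (p$density_cutoff_short <= 0 || p$density_cutoff_short > 1 ||
      p$density_cutoff_long <= 0 || p$density_cutoff_long > 1) {
    stop("density cutoffs must lie in (0, 1]", call. = FALSE)
  }
  structure(p, class = "seizure_params")
}

#' Select a quiet baseline window
#'
#' Picks a `baseline_len_s` window with no LFP activity, seizure-like
#' activity or electrical noise spikes from the first `baseline_search_s`
#' of the trace (the full trace, with a warning, when shorter). Candidate
#' windows start on a 10 s grid; each is scored by the number of samples
#' deviating more than 6 robust (MAD-based) SDs from the search-region
#' median, plus the window variance normalised by the median candidate
#' variance. The earliest window with the minimal score wins, which makes
#' the choice deterministic.
#'
#' @param trace Voltage series, mV.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param params [seizure_params()].
#' @param frame Optional precomputed [stft_magnitude()] frame of the full
#'   trace (its aligned bins inside the chosen window are reused instead
#'   of recomputing the window's STFT).
#' @return An object of class `baseline_stats`: the chosen `window`
#'   ([time_range()]), `voltage_mean_mv`, `voltage_sd_mv`, and the mean
#'   and SD of the per-bin summed STFT magnitude over the window
#'   (`spectral_mean`, `spectral_sd`).
#' @export
select_baseline <- function(trace, sample_rate_hz,
                            params = seizure_params(), frame = NULL) {
  n <- length(trace)
  len <- round(params$baseline_len_s * sample_rate_hz)
  if (n < len) {
    stop("trace shorter than the baseline window", call. = FALSE)
  }
  search_n <- min(n, round(params$baseline_search_s * sample_rate_hz))
  if (n < round(params$baseline_search_s * sample_rate_hz)) {
    warning("trace shorter than baseline_search_s; searching what exists",
            call. = FALSE)
  }
  step <- max(1L, round(10 * sample_rate_hz))
  starts <- seq.int(1L, max(1L, search_n - len + 1L), by = step)

  seg <- trace[seq_len(search_n)]
  med <- stats::median(seg)
  sd_mad <- stats::mad(seg)
  dev <- abs(seg - med) > 6 * sd_mad
  cdev <- c(0, cumsum(dev))
  cx <- c(0, cumsum(seg))
  cx2 <- c(0, cumsum(seg^2))
  ends <- starts + len - 1L
  counts <- cdev[ends + 1L] - cdev[starts]
  sums <- cx[ends + 1L] - cx[starts]
  sq <- cx2[ends + 1L] - cx2[starts]
  vars <- pmax(0, (sq - sums^2 / len) / (len - 1))
  med_var <- stats::median(vars)
  score <- counts + if (med_var > 0) vars / med_var else 0
  best <- which.min(score)  # earliest minimum

  win <- trace[starts[best]:ends[best]]
  w0 <- (starts[best] - 1L) / sample_rate_hz
  w1 <- ends[best] / sample_rate_hz
  summed <- if (is.null(frame)) {
    stft_magnitude(win, sample_rate_hz, params$segment_s)$summed_magnitude
  } else {
    bin0 <- frame$times_s - frame$segment_s / 2
    frame$summed_magnitude[bin0 >= w0 - 1e-9 &
                             bin0 + frame$segment_s <= w1 + 1e-9]
  }
  structure(list(
    window = time_range(w0, w1),
    voltage_mean_mv = mean(win),
    voltage_sd_mv = stats::sd(win),
    spectral_mean = mean(summed),
    spectral_sd = stats::sd(summed)),
    class = "baseline_stats")
}

# Uniform binary activity stream with its sampling step.
activity_series <- function(times, active, stream, dt) {
  structure(list(times = times, active = active, stream = stream, dt = dt),
            class = "activity_series")
}

#' Threshold the spectral stream against baseline
#'
#' A spectral bin is active when its summed STFT magnitude exceeds the
#' baseline mean + `spectral_k` baseline SDs.
#'
#' @param frame A [stft_magnitude()] spectrogram frame.
#' @param baseline [select_baseline()] statistics for the same channel.
#' @param params [seizure_params()].
#' @return An `activity_series` over the spectral bins.
#' @export
detect_spectral_activity <- function(frame, baseline,
                                     params = seizure_params()) {
  stopifnot(inherits(frame, "spectrogram_frame"),
            inherits(baseline, "baseline_stats"))
  if (!is.finite(baseline$spectral_sd) || baseline$spectral_sd <= 0) {
    stop("degenerate baseline: zero spectral SD", call. = FALSE)
  }
  thr <- baseline$spectral_mean + params$spectral_k * baseline$spectral_sd
  activity_series(frame$times_s, frame$summed_magnitude > thr,
                  "spectral", frame$segment_s)
}

#' Threshold the LFP stream against baseline
#'
#' Detects LFP peaks with threshold `voltage_k` x baseline voltage SD and
#' minimum width `lfp_event_duration_s` (amplitudes measured from the
#' baseline window mean), then marks each peak's width interval as active
#' at sample resolution.
#'
#' @param trace Voltage series, mV.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param baseline [select_baseline()] statistics.
#' @param params [seizure_params()].
#' @return An `activity_series` over the samples.
#' @export
detect_lfp_activity <- function(trace, sample_rate_hz, baseline,
                                params = seizure_params()) {
  stopifnot(inherits(baseline, "baseline_stats"))
  if (!is.finite(baseline$voltage_sd_mv) || baseline$voltage_sd_mv <= 0) {
    stop("degenerate baseline: zero voltage SD", call. = FALSE)
  }
  dp <- detection_params(
    threshold_mv = params$voltage_k * baseline$voltage_sd_mv,
    min_duration_s = params$lfp_event_duration_s,
    polarity = "both", baseline_mv = baseline$voltage_mean_mv)
  peaks <- detect_lfp_peaks(trace, sample_rate_hz, dp)
  n <- length(trace)
  active <- logical(n)
  if (nrow(peaks)) {
    i0 <- pmax(1L, floor((peaks$time_s - peaks$width_s / 2) *
                           sample_rate_hz) + 1L)
    i1 <- pmin(n, ceiling((peaks$time_s + peaks$width_s / 2) *
                            sample_rate_hz) + 1L)
    cover <- cumsum(tabulate(i0, nbins = n) - tabulate(pmin(i1 + 1L, n + 1L),
                                                       nbins = n))
    active <- cover > 0L
    active[n] <- active[n] || any(i1 >= n)
  }
  activity_series((seq_along(trace) - 1) / sample_rate_hz, active,
                  "lfp", 1 / sample_rate_hz)
}

#' Turn a binary activity stream into continuous-activity intervals
#'
#' Two centred moving-mean densities are computed over the stream. A time
#' point belongs to a region when the short-window density reaches
#' `density_cutoff_short`; neighbouring regions are merged when the
#' long-window density stays at or above `density_cutoff_long` throughout
#' the gap. Returns maximal disjoint half-open intervals.
#'
#' @param series An `activity_series`.
#' @param params [seizure_params()]; window lengths are taken in the
#'   stream's own datapoints (`window_short`/`window_long` for the sample
#'   stream, `spectral_window_short`/`spectral_window_long` for the bin
#'   stream).
#' @return List of [time_range()] intervals.
#' @export
continuity_filter <- function(series, params = seizure_params()) {
  stopifnot(inherits(series, "activity_series"))
  spectral <- identical(series$stream, "spectral")
  w_short <- if (spectral) params$spectral_window_short else
    params$window_short
  w_long <- if (spectral) params$spectral_window_long else
    params$window_long
  n <- length(series$active)
  if (w_long > n) {
    stop("sliding window longer than the activity series", call. = FALSE)
  }
  d_short <- centered_density(series$active, w_short)
  in_region <- d_short >= params$density_cutoff_short
  if (!any(in_region)) return(list())
  d_long <- centered_density(series$active, w_long)
  bridge <- d_long >= params$density_cutoff_long

  r <- rle(in_region)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge across gaps bridged by the long-window density
  keep_start <- seg$start[1]
  out_start <- integer(0); out_end <- integer(0)
  for (k in seq_len(nrow(seg))) {
    if (k == nrow(seg)) {
      out_start <- c(out_start, keep_start)
      out_end <- c(out_end, seg$end[k])
    } else {
      gap <- (seg$end[k] + 1L):(seg$start[k + 1L] - 1L)
      if (all(bridge[gap])) {
        # bridged: continue the open interval
      } else {
        out_start <- c(out_start, keep_start)
        out_end <- c(out_end, seg$end[k])
        keep_start <- seg$start[k + 1L]
      }
    }
  }
  # half-open intervals on the stream's own grid; spectral times are bin
  # centers, so shift back to bin starts
  origin <- series$times[1] - if (spectral) series$dt / 2 else 0
  lapply(seq_along(out_start), function(k) {
    time_range(origin + (out_start[k] - 1L) * series$dt,
               origin + out_end[k] * series$dt)
  })
}

# Centred moving mean of a 0/1 vector; edge windows are truncated and
# normalised by their actual length.
centered_density <- function(active, w) {
  n <- length(active)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- c(0, cumsum(as.numeric(active)))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect seizure envelopes in one channel
#'
#' Full per-channel detection: baseline selection, spectral and LFP
#' activity streams, continuity filtering, and intersection. Overlapping
#' spectral/LFP regions of at least `min_envelope_s` become envelopes.
#' The reported start refines the overlap start to sample resolution: it
#' is the first time the moving-RMS amplitude envelope of the trace
#' crosses the voltage threshold (`voltage_k` baseline SDs), searched
#' from one STFT bin before the overlap start, so onset lags between
#' channels are resolved well below the 1 s spectral bin. Envelopes
#' closer than `merge_gap_s` are merged.
#'
#' @param trace Voltage series, mV (must be longer than
#'   `baseline_len_s + min_envelope_s`).
#' @param sample_rate_hz Sampling rate, Hz.
#' @param params [seizure_params()].
#' @param baseline Optional precomputed [select_baseline()] result.
#' @return Data frame with columns `start_s`, `end_s`, `duration_s`
#'   (zero rows when no envelope is found).
#' @export
detect_seizure_envelopes <- function(trace, sample_rate_hz,
                                     params = seizure_params(),
                                     baseline = NULL) {
  dur <- length(trace) / sample_rate_hz
  if (dur <= params$baseline_len_s + params$min_envelope_s) {
    stop("trace too short for baseline selection plus an envelope",
         call. = FALSE)
  }
  frame <- stft_magnitude(trace, sample_rate_hz, params$segment_s)
  if (is.null(baseline)) {
    baseline <- select_baseline(trace, sample_rate_hz, params, frame)
  }
  spect <- detect_spectral_activity(frame, baseline, params)
  lfp <- detect_lfp_activity(trace, sample_rate_hz, baseline, params)
  spect_int <- continuity_filter(spect, params)
  lfp_int <- continuity_filter(lfp, params)
  overlaps <- intersect_intervals(spect_int, lfp_int)
  overlaps <- Filter(function(r) (r$end_s - r$start_s) >= params$min_envelope_s,
                     overlaps)
  if (length(overlaps) == 0L) return(empty_envelopes())

  # Sample-resolution onset: the continuity filters give the overlap
  # region at window resolution; the reported start is the first crossing
  # of the moving-RMS amplitude envelope above the voltage threshold,
  # searched from one STFT bin before the overlap start. This keeps onset
  # lags between channels comparable well below the 1 s spectral bin.
  amp_env <- sqrt(2 * centered_density(
    (trace - baseline$voltage_mean_mv)^2, round(0.25 * sample_rate_hz)))
  thr_v <- params$voltage_k * baseline$voltage_sd_mv
  starts <- vapply(overlaps, function(r) {
    i_lo <- max(1L, floor((r$start_s - params$segment_s) *
                            sample_rate_hz) + 1L)
    i_hi <- min(length(trace),
                floor(min(r$end_s, r$start_s + 3 * params$segment_s) *
                        sample_rate_hz) + 1L)
    k <- which(amp_env[i_lo:i_hi] >= thr_v)
    if (length(k)) (i_lo + k[1] - 2) / sample_rate_hz else r$start_s
  }, numeric(1))
  ends <- vapply(overlaps, function(r) r$end_s, numeric(1))
  starts <- pmin(starts, ends - params$min_envelope_s)

  env <- data.frame(start_s = starts, end_s = ends)
  env <- env[order(env$start_s), , drop = FALSE]
  if (params$merge_gap_s > 0 && nrow(env) > 1L) {
    merged <- env[1, ]
    for (k in 2:nrow(env)) {
      last <- nrow(merged)
      if (env$start_s[k] - merged$end_s[last] < params$merge_gap_s) {
        merged$end_s[last] <- max(merged$end_s[last], env$end_s[k])
      } else {
        merged <- rbind(merged, env[k, ])
      }
    }
    env <- merged
  }
  env$duration_s <- env$end_s - env$start_s
  rownames(env) <- NULL
  env
}

empty_envelopes <- function() {
  data.frame(start_s = numeric(), end_s = numeric(),
             duration_s = numeric())
}

# Pairwise intersection of two sorted interval lists.
intersect_intervals <- function(a, b) {
  out <- list()
  for (ra in a) {
    for (rb in b) {
      s <- max(ra$start_s, rb$start_s)
      e <- min(ra$end_s, rb$end_s)
      if (e > s) out[[length(out) + 1L]] <- time_range(s, e)
    }
  }
  out
}

#' Detect seizure envelopes across a recording
#'
#' Runs [detect_seizure_envelopes()] on every channel (or a subset).
#' Channels with a degenerate baseline (zero variance) are skipped with a
#' warning rather than failing the whole recording.
#'
#' @param rec A [mea_recording()].
#' @param params [seizure_params()].
#' @param channels Optional channel table or linear indices to analyse.
#' @return Data frame with columns `row`, `col`, `linear_index`,
#'   `start_s`, `end_s`, `duration_s` — one row per envelope.
#' @export
detect_recording_envelopes <- function(rec, params = seizure_params(),
                                       channels = NULL) {
  validate_recording(rec)
  sub <- if (is.null(channels)) rec else subset_recording(rec, channels)
  out <- vector("list", n_channels(sub))
  for (j in seq_len(n_channels(sub))) {
    env <- tryCatch(
      detect_seizure_envelopes(sub$traces[, j], sub$sample_rate_hz, params),
      error = function(e) {
        if (grepl("degenerate baseline", conditionMessage(e))) {
          warning(sprintf("channel %d skipped: %s",
                          sub$channels$linear_index[j],
                          conditionMessage(e)), call. = FALSE)
          empty_envelopes()
        } else stop(e)
      })
    if (nrow(env)) {
      out[[j]] <- cbind(sub$channels[rep(j, nrow(env)), , drop = FALSE],
                        env)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- cbind(channel_id(integer(), integer()), empty_envelopes())
  }
  rownames(res) <- NULL
  res
}
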