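#' Per-channel LFP summary metrics
#'
#' Summarises detected peaks for one channel over an analysis interval:
#' peak count, count per second, mean peak amplitude and mean peak
#' duration (both undefined, `NA`, when no peaks were detected — not 0,
#' which would bias group means), plus EEG band powers of the trace
#' segment.
#'
#' @param peaks Peak table from [detect_lfp_peaks()] with times relative
#'   to the analysed range start.
#' @param trace The analysed voltage segment, mV.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param range The analysed [time_range()] (used for the per-second
#'   normalisation and recorded in exports).
#' @param bands Band table for [band_power()]; `NULL` skips band powers.
#' @return A list of class `channel_metrics`.
#' @export
channel_metrics <- function(peaks, trace, sample_rate_hz, range,
                            bands = default_bands()) {
  range <- as_time_range(range)
  dur <- range$end_s - range$start_s
  if (length(trace) > ceiling(dur * sample_rate_hz) + 1L) {
    stop("trace longer than the analysed time range", call. = FALSE)
  }
  if (nrow(peaks) > 0 && any(peaks$time_s < 0 | peaks$time_s > dur)) {
    stop("peaks fall outside the analysed time range", call. = FALSE)
  }
  n <- nrow(peaks)
  structure(list(
    peak_count = n,
    peak_count_per_s = n / dur,
    mean_amplitude_mv = if (n > 0) mean(peaks$amplitude_mv) else NA_real_,
    mean_duration_s = if (n > 0) mean(peaks$width_s) else NA_real_,
    band_powers = if (is.null(bands)) NULL else
      band_power(trace, sample_rate_hz, bands),
    range = range), class = "channel_metrics")
}

#' Detect peaks and compute metrics for every channel of a recording
#'
#' Runs [detect_lfp_peaks()] and [channel_metrics()] on each channel over
#' an analysis interval, optionally after zero-phase filtering.
#'
#' @param rec A [mea_recording()].
#' @param params [detection_params()].
#' @param range [time_range()] relative to the recording start; `NULL`
#'   analyses the whole recording.
#' @param bands Band table for [band_power()]; `NULL` skips band powers.
#' @param filter Optional [filter_spec()] applied before detection.
#' @return A list with `metrics` (data frame, one row per channel, in
#'   channel-table order: `row`, `col`, `linear_index`, `peak_count`,
#'   `peak_count_per_s`, `mean_amplitude_mv`, `mean_duration_s`, one
#'   column per band) and `peaks` (named list of peak tables, times in
#'   recording coordinates).
#' @export
recording_metrics <- function(rec, params = detection_params(),
                              range = NULL, bands = default_bands(),
                              filter = NULL) {
  validate_recording(rec)
  if (is.null(range)) range <- time_range(0, recording_duration(rec))
  range <- as_time_range(range)
  idx <- sample_index_range(range, rec$sample_rate_hz, nrow(rec$traces))
  rows <- vector("list", n_channels(rec))
  peaks_by_channel <- vector("list", n_channels(rec))
  names(peaks_by_channel) <- as.character(rec$channels$linear_index)
  for (j in seq_len(n_channels(rec))) {
    x <- rec$traces[idx, j]
    if (!is.null(filter)) x <- apply_filter(x, rec$sample_rate_hz, filter)
    pk <- detect_lfp_peaks(x, rec$sample_rate_hz, params)
    m <- channel_metrics(pk, x, rec$sample_rate_hz,
                         time_range(0, range$end_s - range$start_s), bands)
    pk$time_s <- pk$time_s + range$start_s
    peaks_by_channel[[j]] <- pk
    rows[[j]] <- c(list(row = rec$channels$row[j],
                        col = rec$channels$col[j],
                        linear_index = rec$channels$linear_index[j],
                        peak_count = m$peak_count,
                        peak_count_per_s = m$peak_count_per_s,
                        mean_amplitude_mv = m$mean_amplitude_mv,
                        mean_duration_s = m$mean_duration_s),
                   as.list(m$band_powers))
  }
  metrics <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  list(metrics = metrics, peaks = peaks_by_channel, range = range,
       params = params)
}

#' Channel-group summary measures
#'
#' Aggregates per-channel metrics over a channel group. A channel is
#' *active* when its peak count strictly exceeds `active_min_peaks`
#' ("more than 20 peaks" under the defaults). The top-N statistics are
#' computed over the `N` channels with the largest peak counts (ties at
#' the boundary broken toward the lower linear index); mean amplitude and
#' duration average the per-channel means, skipping channels without
#' peaks.
#'
#' @param metrics Per-channel metrics data frame from
#'   [recording_metrics()]`$metrics` (must contain the group's channels).
#' @param group A [channel_group()].
#' @param duration_s Analysed interval length, seconds.
#' @param N Number of most-active channels for the top-N statistics
#'   (default 20).
#' @param active_min_peaks Activity cut: a channel is active when
#'   `peak_count > active_min_peaks` (default 20, strict).
#' @return A list of class `group_summary` with `group`, `total_channels`,
#'   `active_channels`, `total_peak_count_per_s`, `mean_amplitude_mv`,
#'   `mean_duration_s` (all-channel means), and `topN_*` statistics.
#' @export
group_summary <- function(metrics, group, duration_s, N = 20L,
                          active_min_peaks = 20L) {
  stopifnot(inherits(group, "channel_group"))
  sel <- match(group$channels$linear_index, metrics$linear_index)
  if (anyNA(sel)) {
    stop("metrics are missing channels of group '", group$name, "'",
         call. = FALSE)
  }
  m <- metrics[sel, , drop = FALSE]
  n_top <- min(N, nrow(m))
  ord <- order(-m$peak_count, m$linear_index)
  top <- m[ord[seq_len(n_top)], , drop = FALSE]
  mean_defined <- function(x) if (all(is.na(x))) NA_real_ else
    mean(x, na.rm = TRUE)
  structure(list(
    group = group$name,
    total_channels = nrow(m),
    active_channels = sum(m$peak_count > active_min_peaks),
    total_peak_count_per_s = sum(m$peak_count) / duration_s,
    mean_amplitude_mv = mean_defined(m$mean_amplitude_mv),
    mean_duration_s = mean_defined(m$mean_duration_s),
    topN_peak_count_per_s = sum(top$peak_count) / duration_s,
    topN_mean_amplitude_mv = mean_defined(top$mean_amplitude_mv),
    topN_mean_duration_s = mean_defined(top$mean_duration_s),
    N = n_top), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary '%s': %d/%d active, %.3g peaks/s,",
              x$group, x$active_channels, x$total_channels,
              x$total_peak_count_per_s),
      sprintf("top-%d amp %.3g mV, dur %.3g s>\n", x$N,
              x$topN_mean_amplitude_mv, x$topN_mean_duration_s))
  invisible(x)
}

#' Build a raster from per-channel peak times
#'
#' Orders channels by linear index (grid position 1..4096) and bins event
#' times; binned counts conserve the total number of events.
#'
#' @param peaks_by_channel Named list (names = linear indices) of peak
#'   tables or numeric time vectors, times in seconds.
#' @param range [time_range()] covered by the raster.
#' @param bin_s Bin width, seconds (default 1).
#' @return A list of class `lfp_raster`: `events` (list of sorted time
#'   vectors per channel, ordered by linear index), `counts` (channels x
#'   bins matrix), `bin_edges_s`, `linear_index`.
#' @export
build_raster <- function(peaks_by_channel, range, bin_s = 1) {
  range <- as_time_range(range)
  lin <- as.integer(names(peaks_by_channel))
  if (anyNA(lin)) {
    stop("peaks_by_channel must be named by linear channel index",
         call. = FALSE)
  }
  ord <- order(lin)
  times <- lapply(peaks_by_channel[ord], function(p) {
    t <- if (is.data.frame(p)) p$time_s else as.numeric(p)
    sort(t)
  })
  bad <- vapply(times, function(t) {
    length(t) > 0 && (min(t) < range$start_s || max(t) >= range$end_s)
  }, logical(1))
  if (any(bad)) stop("peak times outside the raster range", call. = FALSE)
  edges <- seq(range$start_s, range$end_s, by = bin_s)
  if (edges[length(edges)] < range$end_s) {
    edges <- c(edges, range$end_s)
  }
  counts <- t(vapply(times, function(t) {
    if (length(t) == 0) return(integer(length(edges) - 1L))
    tabulate(findInterval(t, edges, rightmost.closed = FALSE,
                          left.open = FALSE),
             nbins = length(edges) - 1L)
  }, integer(length(edges) - 1L)))
  structure(list(events = times, counts = counts, bin_edges_s = edges,
                 linear_index = lin[ord], range = range),
            class = "lfp_raster")
}

#' Export per-channel metrics to CSV
#'
#' One row per channel with the documented export schema: LFP peak count,
#' mean peak amplitude (mV), mean peak duration (s), raw band power
#' (V^2/Hz) for delta/theta/alpha/beta/gamma, channel number, group
#' number, and the analysed time-range start/end. Channels with zero
#' peaks export empty amplitude/duration fields. Rows are ordered by
#' group, then linear index, so re-exports are byte-identical.
#'
#' @param metrics Per-channel metrics data frame
#'   ([recording_metrics()]`$metrics`); every exported channel must belong
#'   to exactly one group.
#' @param groups List of [channel_group()] objects (pairwise disjoint).
#' @param range Analysed [time_range()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_channel_metrics_csv <- function(metrics, groups, range, path) {
  range <- as_time_range(range)
  if (inherits(groups, "channel_group")) groups <- list(groups)
  assert_disjoint_groups(groups)
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    sel <- match(g$channels$linear_index, metrics$linear_index)
    if (anyNA(sel)) {
      stop("channel(s) of group '", g$name, "' missing from metrics",
           call. = FALSE)
    }
    m <- metrics[sel[order(g$channels$linear_index)], , drop = FALSE]
    data.frame(
      lfp_peak_count = m$peak_count,
      mean_peak_amplitude_mv = m$mean_amplitude_mv,
      mean_peak_duration_s = m$mean_duration_s,
      delta_power_v2hz = m$delta, theta_power_v2hz = m$theta,
      alpha_power_v2hz = m$alpha, beta_power_v2hz = m$beta,
      gamma_power_v2hz = m$gamma,
      channel = m$linear_index, group = gi,
      time_start_s = range$start_s, time_end_s = range$end_s)
  })
  in_groups <- unlist(lapply(groups, function(g) g$channels$linear_index))
  orphan <- setdiff(metrics$linear_index, in_groups)
  if (length(orphan)) {
    stop("channel(s) in no group: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, na = "", eol = "\r\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}
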