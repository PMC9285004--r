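#' LFP peak detection parameters
#'
#' Peaks are local voltage extrema that deviate from the channel baseline
#' by at least `threshold_mv` and whose full width at the baseline is at
#' least `min_duration_s`. Defaults (0.07 mV, 0.02 s) are the standard
#' raster-generation settings; no maximum amplitude or width limits are
#' applied.
#'
#' @param threshold_mv Minimum |apex - baseline| amplitude, mV (> 0).
#' @param min_duration_s Minimum full width at baseline, seconds (>= 0).
#' @param polarity Detect `"positive"` deflections, `"negative"`
#'   deflections, or `"both"` (default). With `"both"`, two opposite-
#'   polarity apexes closer than `min_duration_s` are treated as one
#'   biphasic event and the larger-amplitude apex is kept.
#' @param baseline_mv Baseline voltage level, mV; `NULL` (default) uses the
#'   median of the analysed trace segment, which is robust to sparse
#'   activity riding on the noise floor.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold_mv = 0.07, min_duration_s = 0.02,
                             polarity = c("both", "positive", "negative"),
                             baseline_mv = NULL) {
  polarity <- match.arg(polarity)
  if (!is.numeric(threshold_mv) || threshold_mv <= 0) {
    stop("threshold_mv must be positive", call. = FALSE)
  }
  if (!is.numeric(min_duration_s) || min_duration_s < 0) {
    stop("min_duration_s must be non-negative", call. = FALSE)
  }
  structure(list(threshold_mv = threshold_mv,
                 min_duration_s = min_duration_s,
                 polarity = polarity, baseline_mv = baseline_mv),
            class = "detection_params")
}

#' Detect LFP peaks in a voltage trace
#'
#' Finds strict local maxima (and/or minima) whose amplitude from baseline
#' reaches `threshold_mv` and whose full width at the baseline level —
#' the time between the two baseline crossings bracketing the apex,
#' linearly interpolated — reaches `min_duration_s`. Apex times are in
#' seconds from the start of `trace`.
#'
#' @param trace Voltage series, mV (length >= 3).
#' @param sample_rate_hz Sampling rate, Hz (> 0).
#' @param params A [detection_params()] object.
#' @return Data frame with one row per peak, sorted by time: `time_s`,
#'   `amplitude_mv`, `width_s`, `polarity` (+1/-1), `index` (sample index
#'   of the apex).
#' @examples
#' t <- seq(0, 1, by = 1 / 300)
#' x <- 0.1 * exp(-((t - 0.5) / 0.01)^2)
#' detect_lfp_peaks(x, 300, detection_params())
#' @export
detect_lfp_peaks <- function(trace, sample_rate_hz, params = detection_params()) {
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive", call. = FALSE)
  }
  if (length(trace) < 3L) {
    stop("trace must contain at least 3 samples", call. = FALSE)
  }
  baseline <- if (is.null(params$baseline_mv)) stats::median(trace) else
    params$baseline_mv

  pos <- if (params$polarity %in% c("both", "positive")) {
    one_sided_peaks(trace, sample_rate_hz, baseline, params$threshold_mv)
  }
  neg <- if (params$polarity %in% c("both", "negative")) {
    flipped <- one_sided_peaks(2 * baseline - trace, sample_rate_hz,
                               baseline, params$threshold_mv)
    if (nrow(flipped)) flipped$polarity <- -1L
    flipped
  }
  peaks <- rbind(pos, neg)
  if (is.null(peaks) || nrow(peaks) == 0L) return(empty_peaks())

  peaks <- peaks[peaks$width_s >= params$min_duration_s, , drop = FALSE]
  if (params$polarity == "both" && nrow(peaks) > 1L) {
    peaks <- merge_biphasic(peaks, params$min_duration_s)
  }
  peaks <- peaks[order(peaks$time_s, -peaks$polarity), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

empty_peaks <- function() {
  data.frame(time_s = numeric(), amplitude_mv = numeric(),
             width_s = numeric(), polarity = integer(), index = integer())
}

# Strict local maxima at least `threshold` above `baseline`, with full
# width at the baseline level: the interval between the last upward and
# first downward baseline crossings around the apex (interpolated);
# clipped to the trace ends when the excursion never returns to baseline.
one_sided_peaks <- function(x, fs, baseline, threshold) {
  n <- length(x)
  dx <- diff(x)
  apex <- which(dx[seq_len(n - 2L)] > 0 & dx[2:(n - 1L)] < 0) + 1L
  amp <- x[apex] - baseline
  sel <- amp >= threshold & amp > 0
  apex <- apex[sel]
  if (length(apex) == 0L) return(empty_peaks())

  le <- x <= baseline
  idx <- seq_len(n)
  v <- integer(n); v[le] <- idx[le]
  prev_le <- cummax(v)                       # last i <= apex with x <= b
  ler <- rev(le)
  vr <- integer(n); vr[ler] <- idx[ler]
  next_le <- rev(n + 1L - cummax(vr))        # first i >= apex with x <= b
  next_le[next_le > n] <- NA_integer_        # no return to baseline

  l <- prev_le[apex]
  r <- next_le[apex]

  t_left <- numeric(length(apex))
  has_l <- l > 0L
  li <- l[has_l]
  t_left[has_l] <- (li - 1 + (baseline - x[li]) / (x[li + 1L] - x[li])) / fs
  t_right <- rep((n - 1) / fs, length(apex))
  has_r <- !is.na(r)
  ri <- r[has_r]
  t_right[has_r] <- (ri - 2 + (x[ri - 1L] - baseline) /
                       (x[ri - 1L] - x[ri])) / fs

  data.frame(time_s = (apex - 1) / fs,
             amplitude_mv = x[apex] - baseline,
             width_s = t_right - t_left,
             polarity = 1L,
             index = apex)
}

# Biphasic merge: among threshold-passing apexes, accept in order of
# decreasing amplitude; drop a candidate when an accepted apex of opposite
# polarity lies within min_duration_s. Ties broken by earlier time, then
# positive polarity, so results are order-independent. Implemented as a
# neighbor-kill sweep: accepting an apex suppresses conflicting, not yet
# accepted opposite-polarity apexes in its window.
merge_biphasic <- function(peaks, min_duration_s) {
  if (min_duration_s <= 0) return(peaks)
  ot <- order(peaks$time_s, -peaks$polarity)
  p <- peaks[ot, , drop = FALSE]
  m <- nrow(p)
  lo <- findInterval(p$time_s - min_duration_s, p$time_s,
                     left.open = TRUE) + 1L
  hi <- findInterval(p$time_s + min_duration_s, p$time_s,
                     left.open = FALSE)
  hi <- pmin(hi, m)
  # indices whose |dt| < min_duration: refine closed/open bounds below
  status <- integer(m)  # 0 unknown, 1 accepted, -1 suppressed
  for (i in order(-p$amplitude_mv, p$time_s, -p$polarity)) {
    if (status[i] != 0L) next
    status[i] <- 1L
    rng <- lo[i]:hi[i]
    clash <- rng[p$polarity[rng] != p$polarity[i] & status[rng] == 0L &
                   abs(p$time_s[rng] - p$time_s[i]) < min_duration_s]
    status[clash] <- -1L
  }
  p[status == 1L, , drop = FALSE]
}
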