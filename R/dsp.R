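#' Digital filter specification
#'
#' Zero-phase Butterworth filtering for viewing and band-limited analysis,
#' e.g. a 40–150 Hz band-pass to isolate low/high-gamma activity. The
#' filter is applied forward and backward ([signal::filtfilt()]), so event
#' timing is preserved — important because detected peak times feed the
#' seizure onset metrics.
#'
#' @param kind One of `"low-pass"`, `"high-pass"`, `"band-pass"`.
#' @param cutoff_hz One cutoff (low/high-pass) or two increasing cutoffs
#'   (band-pass), Hz.
#' @param order Butterworth order (default 4).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("low-pass", "high-pass", "band-pass"),
                        cutoff_hz, order = 4L) {
  kind <- match.arg(kind)
  cutoff_hz <- as.numeric(cutoff_hz)
  n_needed <- if (kind == "band-pass") 2L else 1L
  if (length(cutoff_hz) != n_needed || any(cutoff_hz <= 0)) {
    stop(kind, " filter needs ", n_needed, " positive cutoff(s)",
         call. = FALSE)
  }
  if (kind == "band-pass" && cutoff_hz[1] >= cutoff_hz[2]) {
    stop("band-pass cutoffs must be increasing", call. = FALSE)
  }
  structure(list(kind = kind, cutoff_hz = cutoff_hz,
                 order = as.integer(order)),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @param trace Voltage series, mV.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param spec A `filter_spec`.
#' @return `apply_filter()` returns the filtered trace (same length).
#'   A band-pass upper edge at or above Nyquist is clipped to 0.99 x
#'   Nyquist with a warning; any other cutoff at or above Nyquist is an
#'   error.
#' @examples
#' x <- sin(2 * pi * 80 * seq(0, 1, by = 1 / 300))
#' y <- apply_filter(x, 300, filter_spec("band-pass", c(40, 149)))
#' @export
apply_filter <- function(trace, sample_rate_hz, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- sample_rate_hz / 2
  cutoff <- spec$cutoff_hz
  if (spec$kind == "band-pass" && cutoff[2] >= nyq) {
    cutoff[2] <- 0.99 * nyq
    warning(sprintf(
      "band-pass upper edge >= Nyquist (%g Hz); clipped to %g Hz",
      nyq, cutoff[2]), call. = FALSE)
    if (cutoff[1] >= cutoff[2]) {
      stop("band-pass lower edge at or above (clipped) upper edge",
           call. = FALSE)
    }
  }
  if (any(cutoff >= nyq)) {
    stop("filter cutoff at or above Nyquist frequency", call. = FALSE)
  }
  type <- switch(spec$kind, "low-pass" = "low", "high-pass" = "high",
                 "band-pass" = "pass")
  bt <- signal::butter(spec$order, cutoff / nyq, type = type)
  # reflection padding keeps filtfilt start-up transients out of the trace
  pad <- min(length(trace) - 1L,
             as.integer(ceiling(3 * sample_rate_hz / min(cutoff))))
  n <- length(trace)
  xp <- c(2 * trace[1] - trace[(pad + 1L):2L], trace,
          2 * trace[n] - trace[(n - 1L):(n - pad)])
  yp <- signal::filtfilt(bt, xp)
  yp[(pad + 1L):(pad + n)]
}

#' One-sided FFT amplitude spectrum
#'
#' Amplitude spectrum normalised so a pure sine of amplitude A mV produces
#' a spectral peak of A mV (one-sided scaling: `2 |X_k| / N`, except the
#' DC and Nyquist bins which are `|X_k| / N`).
#'
#' @param trace Voltage series, mV (length >= 2).
#' @param sample_rate_hz Sampling rate, Hz.
#' @return A data frame with columns `freq_hz`, `amplitude_mv`.
#' @examples
#' sp <- amplitude_spectrum(sin(2 * pi * 25 * (0:899) / 300), 300)
#' sp$freq_hz[which.max(sp$amplitude_mv)]
#' @export
amplitude_spectrum <- function(trace, sample_rate_hz) {
  n <- length(trace)
  if (n < 2L) stop("trace must contain at least 2 samples", call. = FALSE)
  x <- stats::fft(trace)
  n_keep <- floor(n / 2) + 1L
  amp <- Mod(x[seq_len(n_keep)]) / n
  scale2 <- rep(2, n_keep)
  scale2[1] <- 1
  if (n %% 2L == 0L) scale2[n_keep] <- 1
  data.frame(freq_hz = (seq_len(n_keep) - 1L) * sample_rate_hz / n,
             amplitude_mv = amp * scale2)
}

#' Short-time Fourier transform magnitudes
#'
#' Hann-windowed STFT over consecutive segments (1 s, no overlap by
#' default); this is the spectral-activity signal used by the seizure
#' detector. For each time bin, `summed_magnitude` is the sum of the
#' spectral magnitudes over all frequency components below half the
#' sampling frequency. A trailing partial segment is discarded.
#'
#' @param trace Voltage series, mV.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param segment_s Segment length, seconds (default 1).
#' @param overlap_fraction Fractional overlap between segments in `[0, 1)`
#'   (default 0).
#' @return An object of class `spectrogram_frame`: list with `times_s`
#'   (segment centers), `freqs_hz`, `magnitude` (freq x time matrix) and
#'   `summed_magnitude`.
#' @export
stft_magnitude <- function(trace, sample_rate_hz, segment_s = 1,
                           overlap_fraction = 0) {
  seg_len <- round(segment_s * sample_rate_hz)
  if (seg_len < 2L) stop("segment too short for the sampling rate",
                         call. = FALSE)
  if (seg_len > length(trace)) {
    stop("segment longer than trace", call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)", call. = FALSE)
  }
  hop <- max(1L, round(seg_len * (1 - overlap_fraction)))
  starts <- seq.int(1L, length(trace) - seg_len + 1L, by = hop)
  win <- hann_window(seg_len)
  seg <- matrix(trace[outer(seq_len(seg_len) - 1L, starts, "+")],
                nrow = seg_len)
  seg <- seg * win
  spec <- stats::mvfft(seg)
  n_keep <- floor(seg_len / 2) + 1L
  mag <- Mod(spec[seq_len(n_keep), , drop = FALSE])
  freqs <- (seq_len(n_keep) - 1L) * sample_rate_hz / seg_len
  below_nyq <- freqs < sample_rate_hz / 2
  structure(list(
    times_s = (starts - 1L + seg_len / 2) / sample_rate_hz,
    freqs_hz = freqs,
    magnitude = mag,
    summed_magnitude = colSums(mag[below_nyq, , drop = FALSE]),
    segment_s = seg_len / sample_rate_hz,
    sample_rate_hz = sample_rate_hz),
    class = "spectrogram_frame")
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq.int(0L, n - 1L) / n)
}

#' Conventional EEG frequency bands
#'
#' Default band edges: delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30,
#' gamma 30–100 Hz. Bands are clipped to the trace Nyquist by
#' [band_power()].
#'
#' @param gamma_hi_hz Upper gamma edge, Hz.
#' @return Data frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
default_bands <- function(gamma_hi_hz = 100) {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo_hz = c(0.5, 4, 8, 13, 30),
    hi_hz = c(4, 8, 13, 30, gamma_hi_hz))
}

#' Band-averaged power spectral density
#'
#' Welch power spectral density (1 s Hann segments, 50% overlap, one-sided
#' density normalisation) averaged over each requested band. Traces are in
#' mV; powers are reported in V^2/Hz to match the per-channel CSV export
#' convention.
#'
#' @param trace Voltage series, mV.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param bands Band table as from [default_bands()]. Bands whose lower
#'   edge reaches Nyquist are an error; upper edges are clipped to Nyquist.
#' @param clip_to_nyquist If `FALSE`, a band edge at or above Nyquist is an
#'   error instead of being clipped.
#' @return Named numeric vector of mean PSD per band, V^2/Hz.
#' @export
band_power <- function(trace, sample_rate_hz, bands = default_bands(),
                       clip_to_nyquist = TRUE) {
  nyq <- sample_rate_hz / 2
  if (any(bands$lo_hz >= bands$hi_hz)) {
    stop("band edges must satisfy lo < hi", call. = FALSE)
  }
  if (any(bands$lo_hz >= nyq)) {
    stop("band lies entirely above the Nyquist frequency", call. = FALSE)
  }
  hi <- bands$hi_hz
  if (any(hi > nyq)) {
    if (!clip_to_nyquist) stop("band edge above Nyquist", call. = FALSE)
    hi <- pmin(hi, nyq)
  }
  psd <- welch_psd(trace / 1000, sample_rate_hz)  # mV -> V
  out <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- psd$freq_hz >= bands$lo_hz[i] & psd$freq_hz < hi[i]
    if (!any(sel)) return(0)
    mean(psd$density[sel])
  }, numeric(1))
  names(out) <- bands$name
  out
}

# Welch PSD: Hann segments with 50% overlap, one-sided density
# normalisation (sum(psd) * df ~ signal power). Falls back to a single
# full-length segment for traces shorter than segment_s.
welch_psd <- function(x, sample_rate_hz, segment_s = 1) {
  seg_len <- min(length(x), round(segment_s * sample_rate_hz))
  hop <- max(1L, floor(seg_len / 2))
  starts <- seq.int(1L, length(x) - seg_len + 1L, by = hop)
  win <- hann_window(seg_len)
  u <- sum(win^2)
  seg <- matrix(x[outer(seq_len(seg_len) - 1L, starts, "+")],
                nrow = seg_len)
  seg <- seg * win
  spec <- stats::mvfft(seg)
  n_keep <- floor(seg_len / 2) + 1L
  pxx <- rowMeans(Mod(spec[seq_len(n_keep), , drop = FALSE])^2) /
    (sample_rate_hz * u)
  pxx[-1] <- pxx[-1] * 2
  if (seg_len %% 2L == 0L) pxx[n_keep] <- pxx[n_keep] / 2
  list(freq_hz = (seq_len(n_keep) - 1L) * sample_rate_hz / seg_len,
       density = pxx)
}
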