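#' Downsample a recording with anti-alias filtering
#'
#' Reduces the sampling rate by an integer factor `q = floor(source /
#' target)`: each channel is low-pass filtered with a zero-phase FIR
#' anti-alias filter (Hamming-windowed linear-phase design, cutoff at 0.4 x
#' the achieved output rate, applied forward and backward) and then
#' decimated by keeping every q-th sample. Because only integer factors are
#' used, the achieved rate `source / q` can differ from the request for
#' non-integer ratios; it is reported in the returned recording and by
#' [cmd_downsample()].
#'
#' This is the working-file preparation step of the analysis pipeline:
#' array recordings acquired at 10 kHz are reduced to a 300 Hz LFP-band
#' working file before peak detection and seizure analysis.
#'
#' @param rec A [mea_recording()].
#' @param target_rate_hz Requested output rate, Hz (must not exceed the
#'   source rate).
#' @return A `mea_recording` at the achieved rate with `floor(n / q)`
#'   samples per channel.
#' @examples
#' rec <- mea_recording(matrix(rnorm(3000), ncol = 1), channel_id(1, 1), 3000)
#' low <- downsample_recording(rec, 300)
#' low$sample_rate_hz
#' @export
downsample_recording <- function(rec, target_rate_hz) {
  validate_recording(rec)
  if (target_rate_hz > rec$sample_rate_hz) {
    stop("target rate exceeds source rate", call. = FALSE)
  }
  q <- floor(rec$sample_rate_hz / target_rate_hz)
  if (q == 1) {
    achieved <- rec$sample_rate_hz
    out <- rec$traces
  } else {
    achieved <- rec$sample_rate_hz / q
    cutoff_hz <- 0.4 * achieved
    n_out <- floor(nrow(rec$traces) / q)
    keep <- seq.int(1L, by = q, length.out = n_out)
    out <- apply(rec$traces, 2L, function(x) {
      fir_lowpass_zerophase(x, rec$sample_rate_hz, cutoff_hz)[keep]
    })
    if (!is.matrix(out)) out <- matrix(out, ncol = ncol(rec$traces))
  }
  mea_recording(out, rec$channels, achieved, rec$pitch_um, rec$start_time_s)
}

# Zero-phase FIR low-pass: Hamming-window design via signal::fir1, applied
# forward and backward on a reflection-padded copy so filter edge
# transients do not leak into the output.
fir_lowpass_zerophase <- function(x, sample_rate_hz, cutoff_hz,
                                  n_taps = NULL) {
  w <- cutoff_hz / (sample_rate_hz / 2)
  if (w >= 1) return(x)
  if (is.null(n_taps)) {
    # transition width of a Hamming FIR ~ 6.6 / n of Nyquist units;
    # size so the stop band starts well before the new Nyquist
    n_taps <- max(30L, as.integer(ceiling(20 / w)))
    if (n_taps %% 2L == 1L) n_taps <- n_taps + 1L
  }
  b <- signal::fir1(n_taps, w, type = "low")
  pad <- min(length(x) - 1L, 3L * n_taps)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x,
          2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)])
  yp <- signal::filtfilt(b, xp)
  yp[(pad + 1L):(pad + length(x))]
}
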