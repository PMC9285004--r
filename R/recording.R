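#' Multichannel voltage recording
#'
#' Container for a grid-addressed multichannel extracellular recording.
#' Traces are stored as a samples x channels matrix in millivolts; channel
#' identity (grid row/col and linear index) lives in an ordered channel
#' table aligned with the matrix columns.
#'
#' @param traces Numeric matrix, `n_samples x n_channels`, in mV.
#' @param channels Channel table from [channel_id()]; one row per trace
#'   column, no duplicate `linear_index`.
#' @param sample_rate_hz Sampling rate, Hz (> 0).
#' @param pitch_um Electrode pitch, micrometers (> 0; default 60).
#' @param start_time_s Time of the first sample relative to the original
#'   recording start, seconds (0 for full recordings).
#' @return An object of class `mea_recording`.
#' @seealso [read_recording()], [write_recording()], [downsample_recording()]
#' @examples
#' rec <- mea_recording(matrix(rnorm(600), 300, 2), channel_id(1, 1:2), 300)
#' recording_duration(rec)
#' @export
mea_recording <- function(traces, channels, sample_rate_hz, pitch_um = 60,
                          start_time_s = 0) {
  if (is.vector(traces)) traces <- matrix(traces, ncol = 1L)
  storage.mode(traces) <- "double"
  rec <- structure(
    list(traces = traces, channels = channels,
         sample_rate_hz = as.numeric(sample_rate_hz),
         pitch_um = as.numeric(pitch_um),
         start_time_s = as.numeric(start_time_s)),
    class = "mea_recording")
  validate_recording(rec)
  rec
}

#' @rdname mea_recording
#' @param rec A `mea_recording`.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "mea_recording"))
  if (!is.matrix(rec$traces) || nrow(rec$traces) < 1L) {
    stop("traces must be a matrix with at least one sample", call. = FALSE)
  }
  if (nrow(rec$channels) != ncol(rec$traces)) {
    stop("channel table must have one row per trace column", call. = FALSE)
  }
  if (anyDuplicated(rec$channels$linear_index)) {
    stop("duplicate linear_index in channel table", call. = FALSE)
  }
  with(rec$channels, {
    if (any(linear_index != (row - 1L) * 64L + col)) {
      stop("linear_index inconsistent with (row, col) on the 64x64 grid",
           call. = FALSE)
    }
  })
  if (!is.finite(rec$sample_rate_hz) || rec$sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive", call. = FALSE)
  }
  if (!is.finite(rec$pitch_um) || rec$pitch_um <= 0) {
    stop("pitch_um must be positive", call. = FALSE)
  }
  invisible(rec)
}

#' @rdname mea_recording
#' @export
recording_duration <- function(rec) nrow(rec$traces) / rec$sample_rate_hz

#' @rdname mea_recording
#' @export
n_channels <- function(rec) ncol(rec$traces)

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording: %d channels x %d samples @ %g Hz (%.1f s), pitch %g um>\n",
    ncol(x$traces), nrow(x$traces), x$sample_rate_hz,
    recording_duration(x), x$pitch_um))
  invisible(x)
}

#' Extract a channel's trace
#'
#' @param rec A `mea_recording`.
#' @param linear_index Linear channel number.
#' @return Numeric vector of voltage samples, mV.
#' @export
channel_trace <- function(rec, linear_index) {
  j <- match(linear_index, rec$channels$linear_index)
  if (is.na(j)) {
    stop("channel ", linear_index, " not present in recording", call. = FALSE)
  }
  rec$traces[, j]
}

#' Subset a recording in memory
#'
#' @param rec A `mea_recording`.
#' @param channels Optional channel table or linear indices to keep.
#' @param time_range Optional [time_range()] relative to recording start.
#' @return A `mea_recording` restricted to the requested channels/samples;
#'   `start_time_s` is advanced to the range start.
#' @export
subset_recording <- function(rec, channels = NULL, time_range = NULL) {
  traces <- rec$traces
  tab <- rec$channels
  start_time <- rec$start_time_s
  if (!is.null(channels)) {
    want <- if (is.data.frame(channels)) channels$linear_index else
      as.integer(channels)
    j <- match(want, tab$linear_index)
    if (anyNA(j)) {
      stop("channel(s) not present in recording: ",
           paste(want[is.na(j)], collapse = ", "), call. = FALSE)
    }
    traces <- traces[, j, drop = FALSE]
    tab <- tab[j, , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (!is.null(time_range)) {
    time_range <- as_time_range(time_range)
    idx <- sample_index_range(time_range, rec$sample_rate_hz,
                              nrow(rec$traces))
    traces <- traces[idx, , drop = FALSE]
    start_time <- rec$start_time_s + time_range$start_s
  }
  mea_recording(traces, tab, rec$sample_rate_hz, rec$pitch_um, start_time)
}

#' Half-open analysis time interval
#'
#' Intervals are half-open, `[start_s, end_s)`, in seconds from recording
#' start, so adjacent intervals tile a recording without double-counting
#' samples.
#'
#' @param start_s Interval start, seconds (>= 0).
#' @param end_s Interval end, seconds (> `start_s`).
#' @return An object of class `time_range`.
#' @export
time_range <- function(start_s, end_s) {
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  if (!is.finite(start_s) || !is.finite(end_s) || start_s < 0 ||
      end_s <= start_s) {
    stop("time_range requires 0 <= start_s < end_s", call. = FALSE)
  }
  structure(list(start_s = start_s, end_s = end_s), class = "time_range")
}

#' @rdname time_range
#' @param x Object to coerce: a `time_range` or a length-2 numeric.
#' @export
as_time_range <- function(x) {
  if (inherits(x, "time_range")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(time_range(x[1], x[2]))
  stop("cannot interpret object as a time range", call. = FALSE)
}

#' @export
print.time_range <- function(x, ...) {
  cat(sprintf("<time_range [%g, %g) s>\n", x$start_s, x$end_s))
  invisible(x)
}

# Sample indices covered by [start, end) at the given rate; 1-based,
# validated against the trace length.
sample_index_range <- function(range, sample_rate_hz, n_samples) {
  i0 <- floor(range$start_s * sample_rate_hz) + 1
  i1 <- ceiling(range$end_s * sample_rate_hz)
  if (i0 > n_samples || range$start_s * sample_rate_hz > n_samples) {
    stop("time range starts beyond the recording", call. = FALSE)
  }
  i1 <- min(i1, n_samples)
  seq.int(i0, i1)
}
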