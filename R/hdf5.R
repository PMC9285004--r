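#' Write a recording to the open HDF5 layout
#'
#' Persists a [mea_recording()] to an HDF5 file using a documented open
#' layout (the vendor export format is proprietary; adapters can convert
#' into this layout):
#'
#' * `/recording/traces` — float32, dimensions `(n_channels, n_samples)`;
#'   each channel's samples are contiguous so channel subsets can be read
#'   selectively,
#' * `/recording/sample_rate_hz`, `/recording/pitch_um`,
#'   `/recording/start_time_s` — float64 scalars,
#' * `/recording/channels/{row,col,linear_index}` — int32 channel table.
#'
#' Traces are stored as 32-bit floats in mV, so a round trip is lossless to
#' about 1e-7 relative precision.
#'
#' @param rec A valid [mea_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("directory does not exist: ", dir, call. = FALSE)
  }
  .Call(C_h5_write, path.expand(path), rec$traces,
        as.integer(rec$channels$row), as.integer(rec$channels$col),
        as.integer(rec$channels$linear_index),
        rec$sample_rate_hz, rec$pitch_um, rec$start_time_s)
  invisible(path)
}

#' Read a recording (optionally a channel/time subset) from HDF5
#'
#' Reads a file written by [write_recording()]. When `channels` or
#' `time_range` are given, only the requested hyperslabs of
#' `/recording/traces` are read from disk — unrequested channels' traces
#' are never loaded, which is what makes extraction of a few hundred
#' slice-overlying channels from a large array recording practical.
#'
#' @param path HDF5 file path.
#' @param channels Optional channel table ([channel_id()]) or integer
#'   linear indices to load. Requesting a channel absent from the file is
#'   an error.
#' @param time_range Optional [time_range()] in seconds relative to the
#'   file's trace start. The returned `start_time_s` is advanced
#'   accordingly.
#' @return A [mea_recording()].
#' @export
read_recording <- function(path, channels = NULL, time_range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- .Call(C_h5_read_meta, path.expand(path))
  tab <- data.frame(row = meta$row, col = meta$col,
                    linear_index = meta$linear_index)
  n_samples <- as.integer(meta$n_samples)

  if (is.null(channels)) {
    sel <- seq_len(nrow(tab))
  } else {
    want <- if (is.data.frame(channels)) channels$linear_index else
      as.integer(channels)
    sel <- match(want, tab$linear_index)
    if (anyNA(sel)) {
      stop("channel(s) not present in file: ",
           paste(want[is.na(sel)], collapse = ", "), call. = FALSE)
    }
  }

  start_time <- meta$start_time_s
  if (is.null(time_range)) {
    s0 <- 0L
    ns <- n_samples
  } else {
    time_range <- as_time_range(time_range)
    idx <- sample_index_range(time_range, meta$sample_rate_hz, n_samples)
    s0 <- idx[1] - 1L
    ns <- length(idx)
    start_time <- meta$start_time_s + time_range$start_s
  }

  traces <- .Call(C_h5_read_traces, path.expand(path),
                  as.integer(sel - 1L), as.numeric(s0), as.numeric(ns))
  out_tab <- tab[sel, , drop = FALSE]
  rownames(out_tab) <- NULL
  mea_recording(traces, out_tab, meta$sample_rate_hz, meta$pitch_um,
                start_time)
}
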