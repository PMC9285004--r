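#' Read an analysis configuration file
#'
#' YAML configuration replacing the interactive settings: detection and
#' seizure parameters, band edges, channel groups, time range, and an
#' optional filter. Unknown keys are rejected so typos fail loudly. All
#' numeric defaults equal the standard analysis settings (0.07 mV /
#' 0.02 s peak detection; 6 SD spectral and voltage thresholds, 0.035 s
#' LFP event duration, 30/500-point sliding windows, 10 s minimum
#' envelope; 60 um pitch).
#'
#' Example file:
#' ```yaml
#' detection:
#'   threshold_mv: 0.07
#'   min_duration_s: 0.02
#' seizure:
#'   spectral_k: 6
#'   voltage_k: 6
#' groups:
#'   Group1: [1, 2, 3, 65]
#'   Group2: [130, 131]
#' time_range: [0, 120]
#' ```
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return A list of class `analysis_config` with elements `detection`
#'   ([detection_params()]), `seizure` ([seizure_params()]), `bands`,
#'   `groups` (list of [channel_group()]), `time_range` (or `NULL`),
#'   `filter` (or `NULL`), `raster_bin_s`.
#' @export
read_analysis_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("detection", "seizure", "bands", "groups", "time_range",
             "filter", "raster_bin_s")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    x
  }
  det <- check_keys(raw$detection %||% list(),
                    c("threshold_mv", "min_duration_s", "polarity"),
                    "detection")
  sez <- check_keys(raw$seizure %||% list(),
                    setdiff(names(formals(seizure_params)), "..."),
                    "seizure")
  bands <- if (is.null(raw$bands)) default_bands() else {
    b <- raw$bands
    data.frame(name = vapply(b, `[[`, "", "name"),
               lo_hz = vapply(b, function(x) as.numeric(x$lo_hz), 0),
               hi_hz = vapply(b, function(x) as.numeric(x$hi_hz), 0))
  }
  groups <- NULL
  if (!is.null(raw$groups)) {
    groups <- lapply(names(raw$groups), function(nm) {
      channel_group(nm, as.integer(raw$groups[[nm]]))
    })
    assert_disjoint_groups(groups)
  }
  filt <- NULL
  if (!is.null(raw$filter)) {
    f <- check_keys(raw$filter, c("kind", "cutoff_hz", "order"), "filter")
    filt <- filter_spec(f$kind, as.numeric(unlist(f$cutoff_hz)),
                        f$order %||% 4L)
  }
  structure(list(
    detection = do.call(detection_params, det),
    seizure = do.call(seizure_params, sez),
    bands = bands,
    groups = groups,
    time_range = if (!is.null(raw$time_range))
      as_time_range(as.numeric(unlist(raw$time_range))),
    filter = filt,
    raster_bin_s = raw$raster_bin_s %||% 1),
    class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
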