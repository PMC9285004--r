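#' Seizure initiation channels
#'
#' Within an analysis window, the initiation site is the channel whose
#' envelope starts first; channels whose starts are indistinguishable from
#' the earliest (within `tie_tolerance_s`) are co-initiators. Envelope
#' starts are clipped to the window.
#'
#' @param envelopes Envelope table from [detect_recording_envelopes()]
#'   (columns `row`, `col`, `linear_index`, `start_s`, `end_s`).
#' @param window [time_range()] of the selected raster section.
#' @param tie_tolerance_s Start-time tolerance for co-initiators, s.
#' @return Data frame of initiator channels with their clipped `start_s`;
#'   zero rows when no envelope intersects the window.
#' @export
find_initiators <- function(envelopes, window, tie_tolerance_s = 0.25) {
  starts <- earliest_starts(envelopes, window)
  if (nrow(starts) == 0L) return(starts)
  t_min <- min(starts$start_s)
  out <- starts[starts$start_s <= t_min + tie_tolerance_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-channel earliest envelope start within the window (clipped).
earliest_starts <- function(envelopes, window) {
  window <- as_time_range(window)
  sel <- envelopes$start_s < window$end_s & envelopes$end_s > window$start_s
  e <- envelopes[sel, , drop = FALSE]
  if (nrow(e) == 0L) {
    return(cbind(channel_id(integer(), integer()),
                 data.frame(start_s = numeric(), end_s = numeric())))
  }
  e$start_s <- pmax(e$start_s, window$start_s)
  e$end_s <- pmin(e$end_s, window$end_s)
  e <- e[order(e$linear_index, e$start_s), , drop = FALSE]
  first <- !duplicated(e$linear_index)
  out <- e[first, c("row", "col", "linear_index", "start_s", "end_s"),
           drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximum distance of seizure spread
#'
#' Largest Euclidean grid distance from any initiator to any participating
#' channel, scaled by the electrode pitch:
#' `sqrt((x2 - x1)^2 + (y2 - y1)^2) * pitch_um`. With several
#' co-initiators the maximum over all initiator/participant pairs is
#' taken.
#'
#' @param participating Channel table of channels with an SLE.
#' @param initiators Channel table of initiation channels (subset of
#'   `participating`).
#' @param pitch_um Electrode pitch, micrometers.
#' @return Maximum spread distance, micrometers.
#' @export
max_spread_distance <- function(participating, initiators, pitch_um = 60) {
  if (nrow(participating) == 0L || nrow(initiators) == 0L) {
    stop("participating and initiator sets must be non-empty",
         call. = FALSE)
  }
  if (!all(initiators$linear_index %in% participating$linear_index)) {
    stop("initiators must be a subset of participating channels",
         call. = FALSE)
  }
  d2 <- outer(initiators$row, participating$row, "-")^2 +
    outer(initiators$col, participating$col, "-")^2
  sqrt(max(d2)) * pitch_um
}

#' Per-channel seizure durations in a window
#'
#' Duration is envelope end minus envelope start, clipped to the analysis
#' window; per channel the earliest intersecting envelope is used. Mean
#' and maximum are reported over the participating channels.
#'
#' @inheritParams find_initiators
#' @return List with `per_channel` (data frame incl. `duration_s`),
#'   `mean_s`, `max_s`.
#' @export
sle_durations <- function(envelopes, window) {
  starts <- earliest_starts(envelopes, window)
  if (nrow(starts) == 0L) {
    return(list(per_channel = cbind(starts, duration_s = numeric(0)),
                mean_s = NA_real_, max_s = NA_real_))
  }
  starts$duration_s <- starts$end_s - starts$start_s
  list(per_channel = starts, mean_s = mean(starts$duration_s),
       max_s = max(starts$duration_s))
}

#' Seizure propagation speed
#'
#' Maximum spread distance divided by the mean onset lag of the
#' non-initiator participating channels relative to the earliest onset.
#' Initiators are excluded from the denominator so near-zero lags do not
#' deflate the mean; the result is flagged undefined when there are no
#' non-initiator participants or the mean lag is zero.
#'
#' @param starts Per-channel earliest starts (from [find_initiators()]'s
#'   underlying table; see [sle_group_metrics()]).
#' @param initiators Initiator table from [find_initiators()].
#' @param max_distance_um Maximum spread distance, micrometers.
#' @return List with `speed_um_s` (`NA` when undefined), `defined`,
#'   `mean_lag_s`.
#' @export
propagation_speed <- function(starts, initiators, max_distance_um) {
  t_init <- min(starts$start_s)
  non_init <- !(starts$linear_index %in% initiators$linear_index)
  if (!any(non_init)) {
    return(list(speed_um_s = NA_real_, defined = FALSE,
                mean_lag_s = NA_real_,
                reason = "no non-initiator participating channels"))
  }
  mean_lag <- mean(starts$start_s[non_init] - t_init)
  if (mean_lag <= 0) {
    return(list(speed_um_s = NA_real_, defined = FALSE,
                mean_lag_s = mean_lag, reason = "zero mean onset lag"))
  }
  list(speed_um_s = max_distance_um / mean_lag, defined = TRUE,
       mean_lag_s = mean_lag)
}

#' Seizure network metrics for a channel group
#'
#' Composes initiation, spread distance, duration, and propagation speed
#' for the channels of a group whose envelopes intersect the selected
#' window. Group channels without an envelope are reported as
#' non-participating. With no envelope at all, a valid "no SLE" result is
#' returned (empty participation, `NA` metrics).
#'
#' @param envelopes Envelope table from [detect_recording_envelopes()].
#' @param group A [channel_group()].
#' @param window [time_range()] of the selected raster section.
#' @param pitch_um Electrode pitch, micrometers.
#' @param tie_tolerance_s Co-initiator start tolerance, s.
#' @return A list of class `sle_group_metrics`.
#' @export
sle_group_metrics <- function(envelopes, group, window, pitch_um = 60,
                              tie_tolerance_s = 0.25) {
  stopifnot(inherits(group, "channel_group"))
  window <- as_time_range(window)
  env <- envelopes[envelopes$linear_index %in% group$channels$linear_index, ,
                   drop = FALSE]
  starts <- earliest_starts(env, window)
  non_participating <- group$channels[
    !(group$channels$linear_index %in% starts$linear_index), , drop = FALSE]
  if (nrow(starts) == 0L) {
    return(structure(list(
      group = group$name, window = window, has_sle = FALSE,
      initiators = starts, participating = starts,
      non_participating = non_participating,
      max_distance_um = NA_real_, mean_duration_s = NA_real_,
      max_duration_s = NA_real_, propagation_speed_um_s = NA_real_,
      speed_defined = FALSE, mean_lag_s = NA_real_),
      class = "sle_group_metrics"))
  }
  initiators <- find_initiators(env, window, tie_tolerance_s)
  dist <- max_spread_distance(starts, initiators, pitch_um)
  durs <- sle_durations(env, window)
  speed <- propagation_speed(starts, initiators, dist)
  structure(list(
    group = group$name, window = window, has_sle = TRUE,
    initiators = initiators, participating = starts,
    non_participating = non_participating,
    max_distance_um = dist,
    mean_duration_s = durs$mean_s, max_duration_s = durs$max_s,
    propagation_speed_um_s = speed$speed_um_s,
    speed_defined = speed$defined, mean_lag_s = speed$mean_lag_s),
    class = "sle_group_metrics")
}

#' @export
print.sle_group_metrics <- function(x, ...) {
  cat(sprintf("<sle_group_metrics '%s' [%g, %g) s>\n", x$group,
              x$window$start_s, x$window$end_s))
  if (!x$has_sle) {
    cat("  no seizure-like event in window\n")
    return(invisible(x))
  }
  cat(sprintf("  participating %d, initiators %d (first start %.2f s)\n",
              nrow(x$participating), nrow(x$initiators),
              min(x$participating$start_s)))
  cat(sprintf("  max spread %.0f um, duration mean %.1f s / max %.1f s\n",
              x$max_distance_um, x$mean_duration_s, x$max_duration_s))
  if (x$speed_defined) {
    cat(sprintf("  propagation speed %.0f um/s (mean lag %.2f s)\n",
                x$propagation_speed_um_s, x$mean_lag_s))
  } else {
    cat("  propagation speed undefined\n")
  }
  invisible(x)
}

#' Export an envelope table to CSV
#'
#' @param envelopes Envelope table from [detect_recording_envelopes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_envelopes_csv <- function(envelopes, path) {
  cols <- c("linear_index", "row", "col", "start_s", "end_s", "duration_s")
  out <- envelopes[order(envelopes$linear_index, envelopes$start_s),
                   cols, drop = FALSE]
  names(out)[1] <- "channel"
  utils::write.csv(out, path, row.names = FALSE, na = "", eol = "\r\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}
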