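#' Raster plot of LFP activity
#'
#' Channels (ordered by linear index, i.e. grid position 1..4096) against
#' time, one tick per detected LFP peak.
#'
#' @param raster An `lfp_raster` from [build_raster()].
#' @return A ggplot object.
#' @export
plot_raster <- function(raster) {
  stopifnot(inherits(raster, "lfp_raster"))
  n_ev <- vapply(raster$events, length, integer(1))
  df <- data.frame(
    time_s = unlist(raster$events, use.names = FALSE),
    channel = rep(raster$linear_index, n_ev))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$channel)) +
    ggplot2::geom_point(shape = "|", size = 1.5) +
    ggplot2::coord_cartesian(xlim = c(raster$range$start_s,
                                      raster$range$end_s)) +
    ggplot2::labs(x = "time (s)", y = "channel (linear index)") +
    ggplot2::theme_minimal()
}

#' Seizure map of a channel group
#'
#' Grid map of the analysed window: participating channels red,
#' non-participating blue, unselected channels gray, initiation site(s)
#' green.
#'
#' @param metrics An `sle_group_metrics` from [sle_group_metrics()].
#' @param all_channels Optional channel table of every recorded channel
#'   (drawn gray when outside the group).
#' @return A ggplot object.
#' @export
plot_seizure_map <- function(metrics, all_channels = NULL) {
  stopifnot(inherits(metrics, "sle_group_metrics"))
  layer <- function(tab, status) {
    if (is.null(tab) || nrow(tab) == 0L) return(NULL)
    data.frame(row = tab$row, col = tab$col, status = status)
  }
  df <- rbind(
    if (!is.null(all_channels)) layer(all_channels, "unselected"),
    layer(metrics$non_participating, "no SLE"),
    layer(metrics$participating, "SLE"),
    layer(metrics$initiators, "initiation"))
  df$status <- factor(df$status,
                      levels = c("unselected", "no SLE", "SLE", "initiation"))
  # one point per electrode; higher status (initiation > SLE > ...) wins
  df <- df[order(df$status), ]
  df <- df[!duplicated(df[c("row", "col")], fromLast = TRUE), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(
      "unselected" = "gray70", "no SLE" = "blue", "SLE" = "red",
      "initiation" = "green3"), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "grid column", y = "grid row", colour = NULL) +
    ggplot2::theme_minimal()
}

# Save a ggplot as PNG without depending on an X display.
save_plot_png <- function(p, path, width = 8, height = 5) {
  grDevices::png(path, width = width * 100, height = height * 100,
                 res = 100, type = "cairo")
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
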