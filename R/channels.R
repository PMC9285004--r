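#' Electrode grid addressing
#'
#' Electrodes sit on a 64 x 64 grid (4,096 sites). A channel is addressed
#' either by its 1-based `(row, col)` grid position or by its linear index
#' `(row - 1) * 64 + col`, the 1..4096 channel number used in raster plots.
#'
#' @param row,col Integer vectors of 1-based grid coordinates.
#' @param grid_dim Grid extent (rows = cols); 64 for the full array.
#' @return `channel_id()` returns a data frame with columns `row`, `col`,
#'   `linear_index` — the channel table used throughout the package.
#' @examples
#' channel_id(1, 1:3)
#' linear_to_channel(c(1, 65, 4096))
#' @export
channel_id <- function(row, col, grid_dim = 64L) {
  n <- max(length(row), length(col))
  row <- as.integer(rep_len(row, n))
  col <- as.integer(rep_len(col, n))
  if (anyNA(row) || anyNA(col)) {
    stop("channel row/col must be integers", call. = FALSE)
  }
  if (any(row < 1L | row > grid_dim) || any(col < 1L | col > grid_dim)) {
    stop(sprintf("channel coordinates must lie in 1..%d", grid_dim),
         call. = FALSE)
  }
  data.frame(row = row, col = col,
             linear_index = (row - 1L) * as.integer(grid_dim) + col)
}

#' @rdname channel_id
#' @param linear_index Integer vector of linear channel numbers (1..4096).
#' @export
linear_to_channel <- function(linear_index, grid_dim = 64L) {
  linear_index <- as.integer(linear_index)
  if (any(linear_index < 1L | linear_index > grid_dim * grid_dim)) {
    stop(sprintf("linear_index must lie in 1..%d", grid_dim * grid_dim),
         call. = FALSE)
  }
  row <- (linear_index - 1L) %/% as.integer(grid_dim) + 1L
  col <- (linear_index - 1L) %% as.integer(grid_dim) + 1L
  data.frame(row = row, col = col, linear_index = linear_index)
}

#' Named group of channels
#'
#' Channel groups delimit regions of interest on the array (for example the
#' hippocampus vs. either half of the neocortex) for regional summary
#' measures and seizure metrics.
#'
#' @param name Group label, e.g. `"Group1"`.
#' @param channels Channel table as returned by [channel_id()], or an integer
#'   vector of linear indices.
#' @return An object of class `channel_group`.
#' @examples
#' g <- channel_group("hippocampus", channel_id(1:3, 2))
#' @export
channel_group <- function(name, channels) {
  if (is.numeric(channels)) channels <- linear_to_channel(channels)
  stopifnot(is.data.frame(channels),
            all(c("row", "col", "linear_index") %in% names(channels)))
  if (nrow(channels) == 0L) {
    stop("channel group must contain at least one channel", call. = FALSE)
  }
  if (anyDuplicated(channels$linear_index)) {
    stop("channel group contains duplicate channels", call. = FALSE)
  }
  structure(list(name = as.character(name),
                 channels = channels[order(channels$linear_index), ,
                                     drop = FALSE]),
            class = "channel_group")
}

#' @export
print.channel_group <- function(x, ...) {
  cat(sprintf("<channel_group '%s': %d channels>\n", x$name,
              nrow(x$channels)))
  invisible(x)
}

#' Check that groups are pairwise disjoint
#'
#' Groups analysed together must not share channels, otherwise per-channel
#' metrics would be double-counted in the group summaries.
#'
#' @param groups List of [channel_group()] objects.
#' @return Invisibly `TRUE`; signals an error on overlap.
#' @export
assert_disjoint_groups <- function(groups) {
  idx <- unlist(lapply(groups, function(g) g$channels$linear_index))
  if (anyDuplicated(idx)) {
    stop("channel groups overlap: channel(s) ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "),
         " appear in more than one group", call. = FALSE)
  }
  invisible(TRUE)
}

#' Grid distance between channels in micrometers
#'
#' Euclidean distance between grid positions (rows/cols at unit spacing)
#' scaled by the electrode pitch.
#'
#' @param a,b Channel tables (data frames with `row`, `col`); recycled.
#' @param pitch_um Electrode pitch, micrometers (60 for the reference array).
#' @return Numeric vector of distances in micrometers.
#' @export
channel_distance_um <- function(a, b, pitch_um = 60) {
  sqrt((a$row - b$row)^2 + (a$col - b$col)^2) * pitch_um
}
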