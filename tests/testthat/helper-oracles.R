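# Independent brute-force oracles. These re-derive the documented rules
# with naive loops and must stay independent of the package internals.

# Exhaustive local-extrema peak oracle: strict extrema, amplitude from
# baseline, full width between baseline crossings (interpolated), then
# greedy opposite-polarity merge by descending amplitude.
oracle_detect_peaks <- function(trace, fs, threshold_mv = 0.07,
                                min_duration_s = 0.02, polarity = "both",
                                baseline = NULL) {
  n <- length(trace)
  b <- if (is.null(baseline)) median(trace) else baseline
  cand <- list()
  scan_side <- function(sign) {
    x <- if (sign > 0) trace else 2 * b - trace
    for (i in 2:(n - 1)) {
      if (x[i] > x[i - 1] && x[i] > x[i + 1] && (x[i] - b) >= threshold_mv) {
        # walk left to the last sample at or below baseline
        l <- i
        while (l >= 1 && x[l] > b) l <- l - 1
        t_left <- if (l < 1) 0 else
          (l - 1 + (b - x[l]) / (x[l + 1] - x[l])) / fs
        r <- i
        while (r <= n && x[r] > b) r <- r + 1
        t_right <- if (r > n) (n - 1) / fs else
          (r - 2 + (x[r - 1] - b) / (x[r - 1] - x[r])) / fs
        if ((t_right - t_left) >= min_duration_s) {
          cand[[length(cand) + 1L]] <<- data.frame(
            time_s = (i - 1) / fs, amplitude_mv = x[i] - b,
            width_s = t_right - t_left, polarity = as.integer(sign))
        }
      }
    }
  }
  if (polarity %in% c("both", "positive")) scan_side(1)
  if (polarity %in% c("both", "negative")) scan_side(-1)
  if (length(cand) == 0L) {
    return(data.frame(time_s = numeric(), amplitude_mv = numeric(),
                      width_s = numeric(), polarity = integer()))
  }
  p <- do.call(rbind, cand)
  if (polarity == "both" && nrow(p) > 1L && min_duration_s > 0) {
    ord <- order(-p$amplitude_mv, p$time_s, -p$polarity)
    acc <- integer(0)
    for (i in ord) {
      clash <- FALSE
      for (j in acc) {
        if (p$polarity[j] != p$polarity[i] &&
            abs(p$time_s[j] - p$time_s[i]) < min_duration_s) {
          clash <- TRUE
          break
        }
      }
      if (!clash) acc <- c(acc, i)
    }
    p <- p[sort(acc), , drop = FALSE]
  }
  p <- p[order(p$time_s, -p$polarity), , drop = FALSE]
  rownames(p) <- NULL
  p
}

# Naive O(N^2) one-sided DFT amplitude spectrum.
oracle_amplitude_spectrum <- function(x, fs) {
  n <- length(x)
  n_keep <- floor(n / 2) + 1
  amp <- numeric(n_keep)
  for (k in seq_len(n_keep)) {
    w <- exp(-2i * pi * (k - 1) * (seq_len(n) - 1) / n)
    amp[k] <- Mod(sum(x * w)) / n
  }
  scale2 <- rep(2, n_keep)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[n_keep] <- 1
  amp * scale2
}

# Naive centred moving mean with truncated edge windows.
oracle_moving_density <- function(active, w) {
  n <- length(active)
  half_l <- (w - 1) %/% 2
  half_r <- w - 1 - half_l
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half_l)
    hi <- min(n, i + half_r)
    out[i] <- mean(active[lo:hi])
  }
  out
}

# Naive continuity regions: short-window density threshold + long-window
# gap bridging, on index space.
oracle_continuity_regions <- function(active, w_short, w_long,
                                      cut_short, cut_long) {
  ds <- oracle_moving_density(active, w_short)
  dl <- oracle_moving_density(active, w_long)
  inr <- ds >= cut_short
  # merge gaps fully covered by the long density
  i <- 1
  n <- length(active)
  segs <- list()
  while (i <= n) {
    if (inr[i]) {
      j <- i
      while (j < n && inr[j + 1]) j <- j + 1
      segs[[length(segs) + 1L]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(segs) < 2) return(segs)
  merged <- list(segs[[1]])
  for (k in 2:length(segs)) {
    last <- merged[[length(merged)]]
    gap <- (last[2] + 1):(segs[[k]][1] - 1)
    if (all(dl[gap] >= cut_long)) {
      merged[[length(merged)]] <- c(last[1], segs[[k]][2])
    } else {
      merged[[length(merged) + 1L]] <- segs[[k]]
    }
  }
  merged
}

# Random spiky test trace: Gaussian noise plus half-sine transients of
# random amplitude, width and sign.
random_spiky_trace <- function(seed, fs = 300, min_len = 300L,
                               max_len = 1500L, noise_sd = 0.02) {
  set.seed(seed)
  n <- sample(min_len:max_len, 1)
  x <- rnorm(n, 0, noise_sd)
  for (k in seq_len(rpois(1, 4))) {
    w <- round(runif(1, 0.01, 0.08) * fs)
    if (w < 2) next
    a <- runif(1, 0.05, 0.3) * sample(c(-1, 1), 1)
    i0 <- sample(n - w, 1)
    x[i0:(i0 + w - 1)] <- x[i0:(i0 + w - 1)] + a * sin(pi * (0:(w - 1)) / w)
  }
  x
}
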