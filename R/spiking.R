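# Multi-unit activity: spike detection on the 500-5000 Hz band, firing rate,
# 50 ms binning summed across electrodes, and plug-in information measures.

#' MUA detection configuration
#'
#' @param band Detection band in Hz (default 500-5000; clipped to `0.45 * fs`
#'   with a warning when the recording is sampled too slowly).
#' @param k_sd Threshold in SDs of the filtered trace (default 5).
#' @param prominence_ratio Required topographic prominence as a fraction of
#'   the peak magnitude (default 0.5).
#' @param refractory_s Minimum spacing between detected spikes (default 1 ms).
#' @param robust_sd Use a median/0.6745-based SD estimate instead of the
#'   sample SD.
#' @return A `mua_config` list.
#' @export
mua_config <- function(band = c(500, 5000), k_sd = 5, prominence_ratio = 0.5,
                       refractory_s = 0.001, robust_sd = FALSE) {
  if (k_sd <= 0 || prominence_ratio <= 0 || prominence_ratio > 1) {
    abort("k_sd must be positive and prominence_ratio in (0, 1]",
          class = "neodev_param_error")
  }
  structure(list(band = band, k_sd = k_sd,
                 prominence_ratio = prominence_ratio,
                 refractory_s = refractory_s, robust_sd = robust_sd),
            class = "mua_config")
}

# Topographic prominence of peaks at indices `idx` of series `y` (peaks
# positive). For each peak: walk to the nearest higher sample on each side
# (or the edge), take the minimum in between; prominence = peak - max of the
# two side minima.
peak_prominence <- function(y, idx) {
  n <- length(y)
  vapply(idx, function(i) {
    v <- y[i]
    jl <- i - 1L
    while (jl >= 1L && y[jl] <= v) jl <- jl - 1L
    saddle_l <- if (jl + 1L <= i - 1L) min(y[(jl + 1L):(i - 1L)]) else v
    jr <- i + 1L
    while (jr <= n && y[jr] <= v) jr <- jr + 1L
    saddle_r <- if (i + 1L <= jr - 1L) min(y[(i + 1L):(jr - 1L)]) else v
    v - max(saddle_l, saddle_r)
  }, numeric(1))
}

#' Detect multi-unit spikes
#'
#' Spikes are local minima of the band-pass-filtered trace whose magnitude
#' exceeds `k_sd` standard deviations of the filtered trace and whose
#' topographic prominence (computed on the negated trace) exceeds
#' `prominence_ratio` times the peak magnitude. Only negative deflections are
#' detected. Both criteria are relative, so detections are invariant to
#' amplitude scaling.
#'
#' @param rec A [recording()].
#' @param cfg A [mua_config()].
#' @param channel_id Channels to process (default: all).
#' @return Spike tibble `time_s`, `channel_id`, `amplitude` with attribute
#'   `duration_s`.
#' @export
detect_mua <- function(rec, cfg = mua_config(), channel_id = NULL) {
  stopifnot(inherits(rec, "neodev_recording"))
  band <- cfg$band
  if (rec$fs < 2 * band[2]) {
    band[2] <- 0.45 * rec$fs
    warn(sprintf("sampling rate %g Hz too low for %g Hz band edge; clipped to %g Hz",
                 rec$fs, cfg$band[2], band[2]))
  }
  filtered <- bandpass(rec, band[1], band[2])
  ids <- channel_id %||% rec$channels$channel_id
  out <- purrr::map_dfr(ids, function(id) {
    x <- channel_trace(filtered, id)
    s <- if (cfg$robust_sd) stats::median(abs(x)) / 0.6745 else stats::sd(x)
    if (s == 0) abort(sprintf("zero-variance filtered trace on '%s'", id),
                      class = "neodev_param_error")
    y <- -x  # peaks of negative deflections
    n <- length(y)
    cand <- which(y > cfg$k_sd * s)
    cand <- cand[cand > 1 & cand < n]
    cand <- cand[y[cand] > y[cand - 1] & y[cand] >= y[cand + 1]]
    if (length(cand) == 0) {
      return(tibble::tibble(time_s = numeric(), channel_id = character(),
                            amplitude = numeric()))
    }
    prom <- peak_prominence(y, cand)
    keep <- prom > cfg$prominence_ratio * y[cand]
    cand <- cand[keep]
    if (length(cand) > 1) {
      # refractory: greedy by magnitude
      o <- order(y[cand], decreasing = TRUE)
      sel <- logical(length(cand))
      taken <- numeric(0)
      gap <- cfg$refractory_s * rec$fs
      for (k in o) {
        if (all(abs(cand[k] - taken) >= gap)) {
          sel[k] <- TRUE
          taken <- c(taken, cand[k])
        }
      }
      cand <- sort(cand[sel])
    }
    tibble::tibble(time_s = (cand - 1) / rec$fs, channel_id = id,
                   amplitude = x[cand])
  })
  attr(out, "duration_s") <- duration(rec)
  out
}

#' Firing rate over a window
#'
#' Spike count in the half-open window `[t0, t1)` divided by its length.
#'
#' @param spikes Spike tibble (`time_s` column).
#' @param t0,t1 Window bounds in seconds, `t1 > t0`.
#' @return Rate in Hz.
#' @export
firing_rate <- function(spikes, t0, t1) {
  if (!(t1 > t0)) abort("t1 must exceed t0", class = "neodev_param_error")
  sum(spikes$time_s >= t0 & spikes$time_s < t1) / (t1 - t0)
}

#' Bin spikes at fixed resolution, summed across a region's electrodes
#'
#' @param spikes Spike tibble with `time_s`, `channel_id` and a `duration_s`
#'   attribute (or pass `duration_s`).
#' @param channels Channel table (`channel_id`, `region`) mapping electrodes
#'   to regions.
#' @param region Region label to sum over.
#' @param bin_s Bin width in seconds (default 0.05).
#' @param duration_s Recording duration; default from the spikes attribute.
#' @return Integer vector of counts, length `floor(duration_s / bin_s)`, with
#'   attributes `region`, `bin_s`, `n_electrodes`.
#' @export
bin_spikes <- function(spikes, channels, region, bin_s = 0.05,
                       duration_s = NULL) {
  dur <- duration_s %||% attr(spikes, "duration_s")
  if (is.null(dur)) abort("duration_s required", class = "neodev_param_error")
  if (!region %in% channels$region) {
    abort(sprintf("unknown region '%s'", region),
          class = "neodev_param_error")
  }
  ids <- channels$channel_id[channels$region == region]
  n_bins <- floor(dur / bin_s)
  t <- spikes$time_s[spikes$channel_id %in% ids]
  t <- t[t >= 0 & t < n_bins * bin_s]
  counts <- tabulate(floor(t / bin_s) + 1L, nbins = n_bins)
  structure(counts, region = region, bin_s = bin_s,
            n_electrodes = length(ids))
}

#' Plug-in Shannon entropy of a count vector
#'
#' Entropy of the empirical distribution of the vector's values (maximum
#' likelihood / plug-in estimator).
#'
#' @param counts Non-empty vector (e.g. binned spike counts).
#' @param base Logarithm base (2 = bits, default).
#' @return Entropy (>= 0, <= log of the number of distinct values).
#' @export
entropy <- function(counts, base = 2) {
  if (length(counts) == 0) abort("empty vector", class = "neodev_param_error")
  p <- as.numeric(table(counts)) / length(counts)
  -sum(p * log(p, base = base))
}

#' Plug-in mutual information between two count vectors
#'
#' MI from the joint empirical distribution of paired values,
#' `MI = H(x) + H(y) - H(x, y)`; symmetric, non-negative, and equal to `H(x)`
#' when `y = x`.
#'
#' @param x_counts,y_counts Equal-length vectors (same binning of the same
#'   recording).
#' @param base Logarithm base (2 = bits, default).
#' @return Mutual information in `base`-log units.
#' @export
mutual_information <- function(x_counts, y_counts, base = 2) {
  if (length(x_counts) != length(y_counts)) {
    abort("vectors must have equal length", class = "neodev_param_error")
  }
  joint <- paste(x_counts, y_counts, sep = "\r")
  entropy(x_counts, base) + entropy(y_counts, base) - entropy(joint, base)
}
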