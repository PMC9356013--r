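# Detection of discontinuous oscillatory "active periods" in neonatal LFP:
# band-pass 4-20 Hz, downsample to 100 Hz, (optionally z-score), RMS boxcar
# envelope (500 ms), hysteresis thresholding (upper seeds, extension while
# above the lower threshold), merging of gaps shorter than 1 s, and discarding
# of periods shorter than 300 ms -- in that order.

#' Detection configuration for active periods
#'
#' @param mode `"relative"` (thresholds in units of the standardized signal's
#'   SD; invariant to per-animal gain) or `"absolute"` (thresholds in uV).
#' @param upper_threshold Seed threshold: envelope samples above it start a
#'   period (default 4 SD relative / 100 uV absolute).
#' @param lower_threshold Extension threshold (default 2 SD / 50 uV).
#' @param boxcar_s Envelope boxcar length in seconds (default 0.5).
#' @param merge_gap_s Periods closer than this are merged (default 1).
#' @param min_duration_s Periods shorter than this are discarded (default 0.3).
#' @param detect_band Band (Hz) the signal is filtered to before detection.
#' @param detect_fs Rate (Hz) the signal is downsampled to before detection.
#' @param amplitude_band Band (Hz) of the raw-scale trace on which the maximum
#'   amplitude of each period is measured.
#' @param envelope_method `"square_boxcar_sqrt"` (RMS envelope, default) or
#'   `"rectify_boxcar"` (rectified moving average).
#' @return A `detection_config` list.
#' @export
detection_config <- function(mode = c("relative", "absolute"),
                             upper_threshold = NULL, lower_threshold = NULL,
                             boxcar_s = 0.5, merge_gap_s = 1,
                             min_duration_s = 0.3,
                             detect_band = c(4, 20), detect_fs = 100,
                             amplitude_band = c(4, 100),
                             envelope_method = c("square_boxcar_sqrt",
                                                 "rectify_boxcar")) {
  mode <- match.arg(mode)
  envelope_method <- match.arg(envelope_method)
  upper <- upper_threshold %||% if (mode == "relative") 4 else 100
  lower <- lower_threshold %||% if (mode == "relative") 2 else 50
  if (!(lower < upper)) {
    abort("lower_threshold must be below upper_threshold",
          class = "neodev_param_error")
  }
  if (boxcar_s <= 0 || merge_gap_s <= 0 || min_duration_s <= 0) {
    abort("boxcar_s, merge_gap_s, min_duration_s must be positive",
          class = "neodev_param_error")
  }
  structure(list(mode = mode, upper_threshold = upper, lower_threshold = lower,
                 boxcar_s = boxcar_s, merge_gap_s = merge_gap_s,
                 min_duration_s = min_duration_s, detect_band = detect_band,
                 detect_fs = detect_fs, amplitude_band = amplitude_band,
                 envelope_method = envelope_method),
            class = "detection_config")
}

#' Boxcar envelope of an oscillatory signal
#'
#' The default squares the signal, applies a centered moving average of
#' `boxcar_s` seconds, and takes the square root (an RMS envelope); a
#' rectify-then-average variant is available. Output length equals input
#' length and the envelope of a constant-amplitude oscillation is
#' approximately constant away from the edges.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate (Hz).
#' @param boxcar_s Boxcar length in seconds (>= 2 samples).
#' @param method `"square_boxcar_sqrt"` (default) or `"rectify_boxcar"`.
#' @return Non-negative envelope vector, same length as `x`.
#' @export
envelope <- function(x, fs, boxcar_s = 0.5,
                     method = c("square_boxcar_sqrt", "rectify_boxcar")) {
  method <- match.arg(method)
  k <- as.integer(round(boxcar_s * fs))
  if (k < 2) abort("boxcar must span at least 2 samples",
                   class = "neodev_param_error")
  if (k > length(x)) abort("boxcar longer than signal",
                           class = "neodev_param_error")
  if (method == "square_boxcar_sqrt") {
    sqrt(pmax(moving_average(x^2, k), 0))
  } else {
    moving_average(abs(x), k)
  }
}

# Merge intervals (rows of start_s/end_s, sorted) whose gaps are < gap_s.
# Idempotent: merging twice changes nothing.
merge_gaps <- function(starts, ends, gap_s) {
  if (length(starts) == 0) return(list(starts = starts, ends = ends))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me < gap_s) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  list(starts = c(out_s, ms), ends = c(out_e, me))
}

#' Detect oscillatory active periods
#'
#' Applies the full detection chain to a raw recording (band-pass to
#' `detect_band`, downsample to `detect_fs`, z-score in relative mode, RMS
#' boxcar envelope) and thresholds the envelope with hysteresis: maximal runs
#' of samples strictly above the lower threshold are kept when they contain at
#' least one sample strictly above the upper threshold. Runs separated by less
#' than `merge_gap_s` are merged, then runs shorter than `min_duration_s` are
#' discarded. The maximum amplitude of each period is measured on the
#' raw-scale trace filtered to `amplitude_band`.
#'
#' If the recording is already at `detect_fs` and filtered, the preprocessing
#' steps are skipped where they would be no-ops; the returned table's
#' `preprocessing` attribute records the path taken.
#'
#' @param rec A [recording()] in uV (absolute mode requires uV units).
#' @param cfg A [detection_config()].
#' @param channel_id Channel to analyze (default: all channels).
#' @return Tibble of active periods: `channel_id`, `start_s`, `end_s`,
#'   `max_amplitude_uV`, `label`.
#' @export
detect_active_periods <- function(rec, cfg = detection_config(),
                                  channel_id = NULL) {
  stopifnot(inherits(rec, "neodev_recording"))
  if (cfg$mode == "absolute" && !identical(rec$units, "uV")) {
    abort("absolute-threshold detection requires a recording in uV",
          class = "neodev_unit_error")
  }
  if (!is.null(channel_id)) {
    sel <- match(channel_id, rec$channels$channel_id)
    if (anyNA(sel)) {
      abort(sprintf("channel '%s' not found",
                    channel_id[which(is.na(sel))[1]]),
            class = "neodev_validation_error")
    }
    rec$samples <- rec$samples[sel, , drop = FALSE]
    rec$channels <- rec$channels[sel, ]
  }
  preprocessing <- character()
  work <- rec
  if (work$fs > cfg$detect_fs) {
    work <- bandpass(work, cfg$detect_band[1],
                     min(cfg$detect_band[2], 0.45 * work$fs))
    work <- downsample(work, cfg$detect_fs)
    preprocessing <- c("bandpass", "downsample")
  } else {
    work <- bandpass(work, cfg$detect_band[1],
                     min(cfg$detect_band[2], 0.45 * work$fs))
    preprocessing <- "bandpass"
  }
  # amplitude measured on raw-scale trace in the (clipped) amplitude band
  amp_hi <- min(cfg$amplitude_band[2], 0.45 * rec$fs)
  amp_rec <- bandpass(rec, cfg$amplitude_band[1], amp_hi)

  ids <- channel_id %||% rec$channels$channel_id
  out <- purrr::map_dfr(ids, function(id) {
    x <- channel_trace(work, id)
    if (cfg$mode == "relative") {
      s <- sqrt(mean((x - mean(x))^2))
      if (s == 0) {
        abort(sprintf("zero-variance channel '%s' in relative mode", id),
              class = "neodev_param_error")
      }
      x <- (x - mean(x)) / s
      preprocessing <- c(preprocessing, "zscore")
    }
    env <- envelope(x, cfg$detect_fs, cfg$boxcar_s, cfg$envelope_method)
    above_low <- env > cfg$lower_threshold
    r <- rle(above_low)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    keep <- r$values
    starts_i <- starts_i[keep]; ends_i <- ends_i[keep]
    if (length(starts_i) > 0) {
      has_seed <- vapply(seq_along(starts_i), function(j) {
        any(env[starts_i[j]:ends_i[j]] > cfg$upper_threshold)
      }, logical(1))
      starts_i <- starts_i[has_seed]; ends_i <- ends_i[has_seed]
    }
    # half-open seconds on the detect_fs grid (0-based sample indices)
    starts <- (starts_i - 1) / cfg$detect_fs
    ends <- ends_i / cfg$detect_fs
    m <- merge_gaps(starts, ends, cfg$merge_gap_s)
    keep2 <- (m$ends - m$starts) >= cfg$min_duration_s
    starts <- m$starts[keep2]; ends <- m$ends[keep2]
    if (length(starts) == 0) {
      return(tibble::tibble(channel_id = character(), start_s = numeric(),
                            end_s = numeric(), max_amplitude_uV = numeric(),
                            label = character()))
    }
    xa <- channel_trace(amp_rec, id)
    amp <- vapply(seq_along(starts), function(j) {
      i0 <- max(1L, floor(starts[j] * rec$fs) + 1L)
      i1 <- min(length(xa), ceiling(ends[j] * rec$fs))
      max(abs(xa[i0:i1]))
    }, numeric(1))
    tibble::tibble(channel_id = id, start_s = starts, end_s = ends,
                   max_amplitude_uV = amp, label = "active_period")
  })
  attr(out, "preprocessing") <- unique(preprocessing)
  out
}

#' Summary features of detected active periods
#'
#' @param periods Tibble from [detect_active_periods()] (one channel).
#' @param recording_duration_s Total recording length in seconds.
#' @return One-row tibble: `max_amplitude_uV` (mean of period maxima),
#'   `mean_duration_s`, `periods_per_min`, `fraction_active`. With no periods
#'   the rate and fraction are 0 and the amplitude/duration are `NA` (missing,
#'   not zero).
#' @export
period_features <- function(periods, recording_duration_s) {
  if (!is_scalar_number(recording_duration_s) || recording_duration_s <= 0) {
    abort("recording_duration_s must be positive",
          class = "neodev_param_error")
  }
  if (nrow(periods) > 0 &&
      max(periods$end_s) > recording_duration_s + 1e-9) {
    abort("period extends beyond recording duration",
          class = "neodev_validation_error")
  }
  if (nrow(periods) == 0) {
    return(tibble::tibble(max_amplitude_uV = NA_real_,
                          mean_duration_s = NA_real_,
                          periods_per_min = 0, fraction_active = 0))
  }
  durs <- periods$end_s - periods$start_s
  tibble::tibble(
    max_amplitude_uV = mean(periods$max_amplitude_uV),
    mean_duration_s = mean(durs),
    periods_per_min = nrow(periods) / (recording_duration_s / 60),
    fraction_active = sum(durs) / recording_duration_s
  )
}
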