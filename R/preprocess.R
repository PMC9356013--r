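# Filtering, resampling, and standardization applied ahead of burst detection
# and spectral analysis. Filters are zero-phase forward-backward Butterworth
# (default order 3, i.e. effective 6th order) with reflect padding, the
# standard choice for LFP work where phase distortion would corrupt
# phase-amplitude coupling estimates.

#' Band-pass (or low-pass) filter a recording
#'
#' Zero-phase forward-backward Butterworth filtering with reflect padding at
#' the edges. With `low_hz = 0` the filter degenerates to a low-pass.
#'
#' @param rec A [recording()].
#' @param low_hz,high_hz Band edges in Hz; `0 <= low_hz < high_hz < fs/2`.
#' @param order Butterworth order for each pass (default 3; the
#'   forward-backward application doubles the effective order).
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single-pass.
#' @return A filtered recording with identical shape, fs, and metadata.
#' @export
bandpass <- function(rec, low_hz, high_hz, order = 3, zero_phase = TRUE) {
  stopifnot(inherits(rec, "neodev_recording"))
  fs <- rec$fs
  if (!is_scalar_number(high_hz) || high_hz >= fs / 2) {
    abort(sprintf("high_hz (%g) must be below Nyquist (%g)", high_hz, fs / 2),
          class = "neodev_param_error")
  }
  if (!is_scalar_number(low_hz) || low_hz < 0 || low_hz >= high_hz) {
    abort("need 0 <= low_hz < high_hz", class = "neodev_param_error")
  }
  n <- ncol(rec$samples)
  # settling length proxy: 3 periods of the lowest passed frequency
  pad <- as.integer(min(n - 1, ceiling(3 * fs / max(low_hz, 1))))
  if (n <= pad + 1) {
    abort("recording too short for the requested band (filter settling)",
          class = "neodev_param_error")
  }
  filt <- if (low_hz > 0) {
    signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  } else {
    signal::butter(order, high_hz / (fs / 2), type = "low")
  }
  apply_one <- function(x) {
    if (low_hz > 0) x <- x - mean(x)  # band excludes DC; remove it exactly
    xp <- c(2 * x[1] - rev(x[seq_len(pad) + 1L]), x,
            2 * x[n] - rev(x[n - seq_len(pad)]))
    y <- if (zero_phase) {
      signal::filtfilt(filt, xp)
    } else {
      as.numeric(signal::filter(filt, xp))
    }
    y[(pad + 1):(pad + n)]
  }
  out <- rec
  out$samples <- t(apply(rec$samples, 1, apply_one))
  if (nrow(rec$samples) == 1) out$samples <- matrix(out$samples, nrow = 1)
  out
}

#' Downsample a recording with anti-alias filtering
#'
#' Applies a zero-phase frequency-domain low-pass (flat to `0.4 * target_fs`,
#' zero from `0.5 * target_fs`) before resampling, so in-band content below
#' 40% of the target rate is preserved. Integer decimation is used when
#' `fs / target_fs` is integral, linear interpolation on the new time grid
#' otherwise.
#'
#' @param rec A [recording()].
#' @param target_fs New sampling rate in Hz, strictly below `rec$fs`.
#' @return The resampled recording.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "neodev_recording"))
  if (!is_scalar_number(target_fs) || target_fs >= rec$fs) {
    abort("target_fs must be below the current sampling rate",
          class = "neodev_param_error")
  }
  fs <- rec$fs
  n <- ncol(rec$samples)
  ratio <- fs / target_fs
  filtered <- t(apply(rec$samples, 1, fft_lowpass, fs = fs,
                      pass_hz = 0.4 * target_fs, stop_hz = 0.5 * target_fs))
  if (nrow(rec$samples) == 1) filtered <- matrix(filtered, nrow = 1)
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, n, by = as.integer(round(ratio)))
    out_samples <- filtered[, idx, drop = FALSE]
  } else {
    t_old <- (seq_len(n) - 1) / fs
    t_new <- seq(0, (n - 1) / fs, by = 1 / target_fs)
    out_samples <- t(apply(filtered, 1, function(x) {
      approx(t_old, x, xout = t_new)$y
    }))
    if (nrow(rec$samples) == 1) out_samples <- matrix(out_samples, nrow = 1)
  }
  out <- rec
  out$samples <- out_samples
  out$fs <- target_fs
  out
}

#' Z-score a recording per channel
#'
#' Standardizes each channel over the entire recording using the population
#' standard deviation, matching the convention that relative detection
#' thresholds ("4 standard deviations") refer to recording-level SD.
#'
#' @param rec A [recording()].
#' @return A standardized recording with `units = "z"`.
#' @export
zscore <- function(rec) {
  stopifnot(inherits(rec, "neodev_recording"))
  out <- rec
  for (i in seq_len(nrow(rec$samples))) {
    x <- rec$samples[i, ]
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) {
      abort(sprintf("zero-variance channel '%s' cannot be z-scored",
                    rec$channels$channel_id[i]),
            class = "neodev_param_error")
    }
    out$samples[i, ] <- (x - mean(x)) / s
  }
  out$units <- "z"
  out
}
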