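# Spectral measures over active periods: Welch PSD with non-overlapping
# windows, band powers, imaginary coherence, and phase-amplitude coupling.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)

# One-sided Welch auto/cross spectra from non-overlapping Hann-tapered
# segments. Returns freqs plus the averaged cross-periodogram matrix columns.
welch_segments <- function(segments, fs, taper = TRUE) {
  nper <- length(segments[[1]])
  w <- if (taper) hann_window(nper) else rep(1, nper)
  scale <- 1 / (fs * sum(w^2))
  nf <- nper %/% 2 + 1
  ffts <- lapply(segments, function(s) fft(s * w)[seq_len(nf)])
  list(freqs = seq(0, nf - 1) * fs / nper, ffts = ffts, scale = scale,
       nper = nper, nf = nf)
}

one_sided <- function(p, nper, nf) {
  # double all bins except DC and (for even nper) Nyquist
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nf] <- 1
  p * dbl
}

#' Welch power spectral density
#'
#' PSD from non-overlapping Hann-tapered windows, normalized so that the
#' integral of the one-sided PSD over frequency equals the signal's mean
#' square (Parseval).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length in seconds (default 1, i.e. 1 Hz resolution).
#' @return A `neodev_psd`: tibble of `freq_hz`, `power` (uV^2/Hz) with
#'   attributes `n_windows`, `window_s`, `fs`.
#' @export
welch_psd <- function(x, fs, window_s = 1) {
  nper <- as.integer(round(window_s * fs))
  if (length(x) < nper) {
    abort("signal shorter than one Welch window", class = "neodev_param_error")
  }
  nwin <- length(x) %/% nper
  segs <- lapply(seq_len(nwin), function(i) x[((i - 1) * nper + 1):(i * nper)])
  ws <- welch_segments(segs, fs)
  p <- Reduce(`+`, lapply(ws$ffts, function(f) Mod(f)^2)) / nwin * ws$scale
  pow <- one_sided(p, ws$nper, ws$nf)
  out <- tibble::tibble(freq_hz = ws$freqs, power = pow)
  structure(out, n_windows = nwin, window_s = window_s, fs = fs,
            class = c("neodev_psd", class(out)))
}

# Collect full non-overlapping windows lying inside periods; returns the list
# of segments plus how many periods were skipped for being too short.
period_segments <- function(x, fs, periods, window_s) {
  nper <- as.integer(round(window_s * fs))
  segs <- list()
  skipped <- 0L
  for (i in seq_len(nrow(periods))) {
    i0 <- floor(periods$start_s[i] * fs) + 1L
    i1 <- min(length(x), ceiling(periods$end_s[i] * fs))
    len <- i1 - i0 + 1L
    if (len < nper) { skipped <- skipped + 1L; next }
    nwin <- len %/% nper
    for (k in seq_len(nwin)) {
      segs[[length(segs) + 1L]] <- x[(i0 + (k - 1L) * nper):(i0 + k * nper - 1L)]
    }
  }
  list(segments = segs, skipped = skipped, nper = nper)
}

#' Welch PSD restricted to active periods
#'
#' Draws non-overlapping Welch windows only from within the given periods
#' (periods shorter than one window are skipped and counted) and returns the
#' window-weighted average spectrum.
#'
#' @param rec A [recording()].
#' @param periods Interval tibble (e.g. from [detect_active_periods()]).
#' @param window_s Welch window length in seconds.
#' @param channel_id Channel to analyze (default: first channel).
#' @return A `neodev_psd` with attribute `n_skipped_periods`.
#' @export
psd_over_periods <- function(rec, periods, window_s = 1, channel_id = NULL) {
  stopifnot(inherits(rec, "neodev_recording"))
  id <- channel_id %||% rec$channels$channel_id[[1]]
  x <- channel_trace(rec, id)
  ps <- period_segments(x, rec$fs, periods, window_s)
  if (length(ps$segments) == 0) {
    abort(sprintf("no period long enough for a %g s window (%d skipped)",
                  window_s, ps$skipped),
          class = "neodev_param_error")
  }
  ws <- welch_segments(ps$segments, rec$fs)
  p <- Reduce(`+`, lapply(ws$ffts, function(f) Mod(f)^2)) /
    length(ps$segments) * ws$scale
  pow <- one_sided(p, ws$nper, ws$nf)
  out <- tibble::tibble(freq_hz = ws$freqs, power = pow)
  structure(out, n_windows = length(ps$segments), window_s = window_s,
            fs = rec$fs, n_skipped_periods = ps$skipped,
            class = c("neodev_psd", class(out)))
}

#' Frequency band scheme
#'
#' Default bands follow the neonatal convention: theta 4-12 Hz, beta 12-30 Hz,
#' gamma 30-40 Hz. Bands must be ascending and non-overlapping except at
#' shared edges.
#'
#' @param theta,beta,gamma Numeric length-2 band edges in Hz, or additional
#'   named bands via `...`.
#' @param ... Further named bands.
#' @return Named list of band edges.
#' @export
band_scheme <- function(theta = c(4, 12), beta = c(12, 30), gamma = c(30, 40),
                        ...) {
  bands <- c(list(theta = theta, beta = beta, gamma = gamma), list(...))
  edges <- do.call(rbind, bands)
  o <- order(edges[, 1])
  edges <- edges[o, , drop = FALSE]
  if (any(edges[, 1] >= edges[, 2]) ||
      any(utils::head(edges[, 2], -1) > utils::tail(edges[, 1], -1) + 1e-12)) {
    abort("bands must be ascending and non-overlapping",
          class = "neodev_param_error")
  }
  bands
}

#' Integrated band power from a PSD
#'
#' Trapezoidal integral of the PSD over `[lo, hi]`, with exact interpolation
#' at the band edges so that powers are additive over adjacent bands.
#'
#' @param psd A `neodev_psd` (or tibble with `freq_hz`, `power`).
#' @param band Numeric length-2 band edges in Hz, inside the PSD support.
#' @return Band power (uV^2).
#' @export
band_power <- function(psd, band) {
  f <- psd$freq_hz; p <- psd$power
  lo <- band[1]; hi <- band[2]
  if (lo < min(f) - 1e-9 || hi > max(f) + 1e-9 || lo >= hi) {
    abort("band outside PSD support", class = "neodev_param_error")
  }
  inner <- f > lo & f < hi
  fx <- c(lo, f[inner], hi)
  px <- c(approx(f, p, lo)$y, p[inner], approx(f, p, hi)$y)
  trapz(fx, px)
}

#' Imaginary coherence spectrum
#'
#' Computes `|Im(Pxy / sqrt(Pxx * Pyy))|` from Welch cross- and auto-spectra
#' with non-overlapping windows. The imaginary part discards zero-lag
#' (volume-conduction-like) coupling, so identical or instantaneously mixed
#' signals score zero.
#'
#' @param x,y Equal-length signals.
#' @param fs Sampling rate (Hz).
#' @param window_s Welch window length in seconds.
#' @return Tibble `freq_hz`, `icoh` with attribute `n_windows`.
#' @export
imaginary_coherence <- function(x, y, fs, window_s = 1) {
  if (length(x) != length(y)) {
    abort("signals must have equal length", class = "neodev_param_error")
  }
  nper <- as.integer(round(window_s * fs))
  nwin <- length(x) %/% nper
  if (nwin < 1) abort("signal shorter than one window",
                      class = "neodev_param_error")
  if (nwin < 8) warn("fewer than 8 Welch windows; coherence will be noisy")
  seg <- function(s, i) s[((i - 1) * nper + 1):(i * nper)]
  w <- hann_window(nper)
  nf <- nper %/% 2 + 1
  pxx <- pyy <- numeric(nf)
  pxy <- complex(nf)
  for (i in seq_len(nwin)) {
    X <- fft(seg(x, i) * w)[seq_len(nf)]
    Y <- fft(seg(y, i) * w)[seq_len(nf)]
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  denom <- sqrt(pxx * pyy)
  ic <- abs(Im(pxy / ifelse(denom == 0, 1, denom)))
  out <- tibble::tibble(freq_hz = seq(0, nf - 1) * fs / nper, icoh = ic)
  structure(out, n_windows = nwin,
            class = c("neodev_icoh", class(out)))
}

#' Imaginary coherence restricted to active periods
#'
#' Windows are drawn only from within `periods` on both channels jointly.
#'
#' @param rec A two-region [recording()].
#' @param periods Interval tibble; windows are cut from these intervals.
#' @param window_s Welch window length (s).
#' @param channels Character vector of two channel ids (default: first PL and
#'   first HP channel).
#' @return As [imaginary_coherence()].
#' @export
icoh_over_periods <- function(rec, periods, window_s = 1, channels = NULL) {
  chans <- channels %||% c(region_channel(rec, "PL"), region_channel(rec, "HP"))
  x <- channel_trace(rec, chans[1])
  y <- channel_trace(rec, chans[2])
  psx <- period_segments(x, rec$fs, periods, window_s)
  psy <- period_segments(y, rec$fs, periods, window_s)
  if (length(psx$segments) == 0) {
    abort("no period long enough for a window", class = "neodev_param_error")
  }
  w <- hann_window(psx$nper)
  nf <- psx$nper %/% 2 + 1
  pxx <- pyy <- numeric(nf)
  pxy <- complex(nf)
  for (i in seq_along(psx$segments)) {
    X <- fft(psx$segments[[i]] * w)[seq_len(nf)]
    Y <- fft(psy$segments[[i]] * w)[seq_len(nf)]
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  denom <- sqrt(pxx * pyy)
  ic <- abs(Im(pxy / ifelse(denom == 0, 1, denom)))
  out <- tibble::tibble(freq_hz = seq(0, nf - 1) * rec$fs / psx$nper,
                        icoh = ic)
  structure(out, n_windows = length(psx$segments),
            class = c("neodev_icoh", class(out)))
}

# Band-pass one signal vector (helper for PAC; zero-phase Butterworth).
bp_vec <- function(x, fs, lo, hi, order = 3) {
  r <- recording(matrix(x, 1), fs, units = "uV")
  as.numeric(bandpass(r, lo, hi, order = order)$samples)
}

#' Phase-amplitude coupling comodulogram
#'
#' For every (phase frequency, amplitude frequency) pair: band-pass each
#' signal, take the instantaneous phase of `phase_signal` and the amplitude
#' envelope of `amp_signal` from the analytic signal, bin amplitude by phase
#' into `n_bins` bins, and compute the Kullback-Leibler-based modulation index
#' `MI = (log N + sum(p log p)) / log N` (0 = no coupling, 1 = all amplitude
#' in one phase bin). A mean-vector-length estimator is available via
#' `method = "mvl"`.
#'
#' @param phase_signal,amp_signal Equal-length signals at rate `fs` (e.g. HP
#'   for phase, PL for amplitude in cross-regional coupling).
#' @param fs Sampling rate (Hz).
#' @param phase_freqs Tibble/data frame with `center_hz`, `halfwidth_hz` for
#'   the phase axis; default 2-14 Hz step 1 Hz, +/-1 Hz bands.
#' @param amp_freqs Same for the amplitude axis; default 13-47 Hz step 2 Hz
#'   (clipped below Nyquist) with adaptive bandwidth. An `NA` halfwidth means
#'   adaptive: the amplitude band spans `center +/- (phase frequency + 2)` Hz,
#'   wide enough to pass the modulation sidebands at `carrier +/- phase
#'   frequency` - a narrower band would filter out the very envelope
#'   modulation being measured.
#' @param n_bins Number of phase bins (default 18).
#' @param periods Optional interval tibble; analysis restricted to samples
#'   inside these intervals.
#' @param method `"tort"` (KL modulation index, default) or `"mvl"`.
#' @return A `neodev_comodulogram`: tibble `phase_hz`, `amp_hz`, `coupling`
#'   with attributes `n_bins`, `method`.
#' @export
pac_comodulogram <- function(phase_signal, amp_signal, fs,
                             phase_freqs = NULL, amp_freqs = NULL,
                             n_bins = 18, periods = NULL,
                             method = c("tort", "mvl")) {
  method <- match.arg(method)
  if (length(phase_signal) != length(amp_signal)) {
    abort("signals must have equal length", class = "neodev_param_error")
  }
  phase_freqs <- phase_freqs %||%
    tibble::tibble(center_hz = 2:14, halfwidth_hz = 1)
  if (is.null(amp_freqs)) {
    amp_freqs <- tibble::tibble(center_hz = seq(13, 47, by = 2),
                                halfwidth_hz = NA_real_)
    amp_freqs <- amp_freqs[amp_freqs$center_hz + 5 < fs / 2, ]
  }
  fixed_hw <- !is.na(amp_freqs$halfwidth_hz)
  if (any(amp_freqs$center_hz[fixed_hw] + amp_freqs$halfwidth_hz[fixed_hw] >=
            fs / 2)) {
    abort("amplitude band exceeds Nyquist", class = "neodev_param_error")
  }
  if (max(phase_freqs$center_hz + phase_freqs$halfwidth_hz) >
      min(amp_freqs$center_hz - pmax(amp_freqs$halfwidth_hz, 0),
          na.rm = TRUE)) {
    warn("phase and amplitude bands overlap for some grid cells")
  }
  mask <- rep(TRUE, length(phase_signal))
  if (!is.null(periods) && nrow(periods) > 0) {
    mask <- rep(FALSE, length(phase_signal))
    for (i in seq_len(nrow(periods))) {
      i0 <- max(1L, floor(periods$start_s[i] * fs) + 1L)
      i1 <- min(length(mask), ceiling(periods$end_s[i] * fs))
      mask[i0:i1] <- TRUE
    }
  }
  phases <- lapply(seq_len(nrow(phase_freqs)), function(i) {
    b <- bp_vec(phase_signal, fs, phase_freqs$center_hz[i] - phase_freqs$halfwidth_hz[i],
                phase_freqs$center_hz[i] + phase_freqs$halfwidth_hz[i])
    Arg(analytic_signal(b))[mask]
  })
  amp_cache <- new.env(parent = emptyenv())
  amp_env <- function(center, hw) {
    lo <- center - hw
    hi <- min(center + hw, fs / 2 - 0.5)
    key <- sprintf("%.3f_%.3f", lo, hi)
    if (is.null(amp_cache[[key]])) {
      amp_cache[[key]] <-
        Mod(analytic_signal(bp_vec(amp_signal, fs, lo, hi)))[mask]
    }
    amp_cache[[key]]
  }
  grid <- tidyr::expand_grid(pi_ = seq_len(nrow(phase_freqs)),
                             ai_ = seq_len(nrow(amp_freqs)))
  grid$coupling <- purrr::map2_dbl(grid$pi_, grid$ai_, function(i, j) {
    hw <- amp_freqs$halfwidth_hz[j]
    if (is.na(hw)) hw <- phase_freqs$center_hz[i] + 4
    if (amp_freqs$center_hz[j] - hw <= 0) return(NA_real_)
    modulation_index(phases[[i]], amp_env(amp_freqs$center_hz[j], hw),
                     n_bins, method)
  })
  out <- tibble::tibble(phase_hz = phase_freqs$center_hz[grid$pi_],
                        amp_hz = amp_freqs$center_hz[grid$ai_],
                        coupling = grid$coupling)
  structure(out, n_bins = n_bins, method = method,
            class = c("neodev_comodulogram", class(out)))
}

# KL modulation index (or mean vector length) of one phase/amplitude pair.
modulation_index <- function(phase, amp, n_bins = 18,
                             method = c("tort", "mvl")) {
  method <- match.arg(method)
  if (method == "mvl") {
    return(Mod(mean(amp * exp(1i * phase))) / mean(amp))
  }
  bin <- pmin(floor((phase + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  m <- vapply(seq_len(n_bins), function(b) {
    a <- amp[bin == b]
    if (length(a) == 0) 0 else mean(a)
  }, numeric(1))
  if (sum(m) == 0) return(0)
  p <- m / sum(m)
  nz <- p > 0
  (log(n_bins) + sum(p[nz] * log(p[nz]))) / log(n_bins)
}

#' Average coupling over a comodulogram region
#'
#' Mean of comodulogram cells whose amplitude-frequency center lies in
#' `amp_range` and phase-frequency center in `phase_range`; the default
#' reproduces the 20-30 Hz amplitude summary over the theta phase range.
#'
#' @param com A `neodev_comodulogram`.
#' @param amp_range,phase_range Numeric length-2 inclusive ranges (Hz).
#' @return Scalar mean coupling.
#' @export
pac_band_average <- function(com, amp_range = c(20, 30),
                             phase_range = c(4, 12)) {
  sel <- com$amp_hz >= amp_range[1] & com$amp_hz <= amp_range[2] &
    com$phase_hz >= phase_range[1] & com$phase_hz <= phase_range[2]
  if (!any(sel) || all(is.na(com$coupling[sel]))) {
    abort("no comodulogram cells in the requested ranges",
          class = "neodev_param_error")
  }
  mean(com$coupling[sel], na.rm = TRUE)
}
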