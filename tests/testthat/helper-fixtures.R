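# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# Two-region recording containing pure noise plus optional sinusoidal bursts
# at given intervals (list of c(start, end)), on both channels.
burst_recording <- function(duration_s = 60, fs = 100, noise_sd = 0.5,
                            bursts = list(), amplitude = 150, freq = 10,
                            seed = 1) {
  withr::with_seed(seed, {
    n <- duration_s * fs
    t <- (seq_len(n) - 1) / fs
    x <- rnorm(n, sd = noise_sd)
    for (iv in bursts) {
      sel <- t >= iv[1] & t < iv[2]
      x[sel] <- x[sel] + amplitude * sin(2 * pi * freq * t[sel])
    }
    recording(rbind(x, x), fs,
              channels = tibble::tibble(channel_id = c("pl1", "hp1"),
                                        region = c("PL", "HP")))
  })
}

# MUA fixture: in-band biphasic templates at a realistic multi-unit rate in
# Gaussian noise, scaled so the injected negative peaks sit at ~10x the SD of
# the band-pass filtered trace. Returns the trace and the true peak times.
mua_fixture <- function(seed, fs = 25000, duration_s = 10, n_spikes = 400,
                        noise_sd = 0.034) {
  withr::with_seed(seed, {
    n <- fs * duration_s
    x <- rnorm(n, sd = noise_sd)
    sp_t <- seq(-0.003, 0.003, by = 1 / fs)
    raw <- -exp(-(sp_t / 2e-4)^2) + 0.12 * exp(-((sp_t - 1e-3) / 8e-4)^2)
    filt <- signal::butter(3, c(500, 5000) / (fs / 2), "pass")
    tpl <- signal::filtfilt(filt, c(rep(0, 300), raw, rep(0, 300)))
    tpl <- tpl / max(abs(tpl))
    times <- sort(sample(seq(0.2, duration_s - 0.2, by = 0.02), n_spikes))
    for (tt in times) {
      i0 <- round(tt * fs)
      x[i0:(i0 + length(tpl) - 1)] <- x[i0:(i0 + length(tpl) - 1)] + tpl
    }
    list(x = x, fs = fs,
         peak_t = times + (which.min(tpl) - 1) / fs)
  })
}

# Interval matching by intersection-over-union >= min_overlap; returns recall,
# precision, and boundary errors of matched pairs.
interval_match_stats <- function(det, truth, min_overlap = 0.5) {
  iou <- function(a1, a2, b1, b2) {
    i <- pmax(0, pmin(a2, b2) - pmax(a1, b1))
    i / (pmax(a2, b2) - pmin(a1, b1))
  }
  m <- vapply(seq_len(nrow(truth)), function(i) {
    o <- iou(truth$start_s[i], truth$end_s[i], det$start_s, det$end_s)
    j <- which.max(o)
    if (length(o) > 0 && o[j] >= min_overlap) j else NA_integer_
  }, integer(1))
  matched <- !is.na(m)
  be <- c(abs(det$start_s[m[matched]] - truth$start_s[matched]),
          abs(det$end_s[m[matched]] - truth$end_s[matched]))
  list(recall = mean(matched),
       precision = if (nrow(det) == 0) NA_real_ else
         length(unique(m[matched])) / nrow(det),
       boundary_errors = be)
}

# Single-cell KL modulation index between the HP phase rhythm and the PL
# carrier envelope of a generated recording (package default bands).
pac_cell_mi <- function(rec, phase_hz = 6, amp_hz = 25) {
  com <- suppressWarnings(pac_comodulogram(
    rec$samples[2, ], rec$samples[1, ], rec$fs,
    phase_freqs = tibble::tibble(center_hz = phase_hz, halfwidth_hz = 1),
    amp_freqs = tibble::tibble(center_hz = amp_hz, halfwidth_hz = NA_real_)))
  com$coupling[[1]]
}
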