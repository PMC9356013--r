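# Internal numerical helpers shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom stats fft rnorm runif rpois rbinom rlnorm rexp quantile pnorm
#'   pchisq sd approx
NULL

# Centered moving average with reflected edges, O(n) via cumulative sums.
moving_average <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 1)
  if (k > n) abort("window longer than signal", class = "neodev_param_error")
  if (k == 1) return(x)
  half_l <- (k - 1L) %/% 2L
  half_r <- k - 1L - half_l
  xp <- c(rev(x[seq_len(half_l) + 1L]), x, rev(x[n - seq_len(half_r)]))
  cs <- cumsum(c(0, xp))
  (cs[(k + 1):(length(xp) + 1)] - cs[seq_len(length(xp) - k + 1)]) / k
}

# Analytic signal via FFT (Marple): zero negative frequencies, double positive.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Zero-phase frequency-domain low-pass with raised-cosine transition between
# pass_hz and stop_hz. Used as the anti-alias step before decimation: flat to
# pass_hz, zero beyond stop_hz, no phase distortion.
fft_lowpass <- function(x, fs, pass_hz, stop_hz) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(fs)))
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  m <- length(xp)
  f <- abs(seq(0, m - 1) / m * fs)
  f <- pmin(f, fs - f)
  gain <- rep(1, m)
  trans <- f > pass_hz & f < stop_hz
  gain[trans] <- 0.5 * (1 + cos(pi * (f[trans] - pass_hz) / (stop_hz - pass_hz)))
  gain[f >= stop_hz] <- 0
  out <- Re(fft(fft(xp) * gain, inverse = TRUE) / m)
  out[(pad + 1):(pad + n)]
}

# Run `code` under a temporary RNG state seeded with `seed` (NULL = leave RNG
# alone). All generators route randomness through this.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

# Deterministic per-unit seed derivation that stays inside 32-bit range.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 7919) %% 2147483647)
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @importFrom utils head tail
NULL

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
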