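test_that("injected multi-unit spikes are recovered with millisecond timing", {
  fx <- mua_fixture(seed = 21)
  sp <- detect_mua(recording(matrix(fx$x, 1), fx$fs))
  matched <- vapply(fx$peak_t, function(tt) any(abs(sp$time_s - tt) <= 1e-3),
                    logical(1))
  expect_gte(mean(matched), 0.95)
  # brute-force minima scan oracle: every detection is a filtered-trace
  # local minimum below -5 SD
  filt <- signal::butter(3, c(500, 5000) / (fx$fs / 2), "pass")
  xf <- signal::filtfilt(filt, fx$x)
  idx <- round(sp$time_s * fx$fs) + 1
  expect_true(all(xf[idx] < -5 * sd(xf)))
  expect_true(all(xf[idx] <= xf[idx - 1] & xf[idx] <= xf[idx + 1]))
})

test_that("positive-only deflections yield no detections", {
  fx <- mua_fixture(seed = 22)
  spi <- detect_mua(recording(matrix(-fx$x, 1), fx$fs))
  expect_equal(nrow(spi), 0)
})

test_that("detection is invariant to amplitude scaling", {
  fx <- mua_fixture(seed = 23, duration_s = 5, n_spikes = 200)
  sp1 <- detect_mua(recording(matrix(fx$x, 1), fx$fs))
  sp2 <- detect_mua(recording(matrix(fx$x * 273.15, 1), fx$fs))
  expect_equal(sp1$time_s, sp2$time_s)
})

test_that("sub-threshold deflections are not detected", {
  fs <- 25000
  filt <- signal::butter(3, c(500, 5000) / (fs / 2), "pass")
  withr::with_seed(24, {
    x <- rnorm(5 * fs)
    sp_t <- seq(-0.003, 0.003, by = 1 / fs)
    raw <- -exp(-(sp_t / 2e-4)^2) + 0.12 * exp(-((sp_t - 1e-3) / 8e-4)^2)
    tpl <- signal::filtfilt(filt, c(rep(0, 300), raw, rep(0, 300)))
    tpl <- tpl / max(abs(tpl)) * 2.5 * sd(signal::filtfilt(filt, x))
    for (tt in seq(0.5, 4.5, length.out = 10)) {
      i0 <- round(tt * fs)
      x[i0:(i0 + length(tpl) - 1)] <- x[i0:(i0 + length(tpl) - 1)] + tpl
    }
  })
  sdf <- sd(signal::filtfilt(filt, x))
  expect_lt(max(abs(tpl)) / sdf, 5)  # deflections sit near -2.5 SD
  expect_equal(nrow(detect_mua(recording(matrix(x, 1), fs))), 0)
})

test_that("band edge is clipped with a warning at low sampling rates", {
  rec <- withr::with_seed(2, recording(matrix(rnorm(20000), 1), fs = 8000))
  expect_warning(detect_mua(rec), regexp = "clipped")
  flat <- recording(matrix(0, 1, 20000), fs = 25000)
  expect_error(suppressWarnings(detect_mua(flat)),
               class = "neodev_param_error")
})

test_that("firing rate uses half-open windows", {
  sp <- tibble::tibble(time_s = c(0, 10, 59.999, 60),
                       channel_id = "pl_mua")
  expect_equal(firing_rate(sp, 0, 60), 3 / 60)
  expect_equal(firing_rate(sp[0, ], 0, 60), 0)
  expect_equal(firing_rate(tibble::tibble(time_s = seq_len(120) / 2 - 0.25,
                                          channel_id = "x"), 0, 60), 2)
  expect_error(firing_rate(sp, 60, 60), class = "neodev_param_error")
})

test_that("spike binning sums a region's electrodes and conserves counts", {
  channels <- tibble::tibble(channel_id = c("p1", "p2", "h1"),
                             region = c("PL", "PL", "HP"))
  sp <- tibble::tibble(time_s = c(0.07, 0.16, 0.17),
                       channel_id = c("p1", "p1", "p2"))
  counts <- bin_spikes(sp, channels, "PL", 0.05, duration_s = 1)
  expect_equal(length(counts), 20)
  expect_equal(counts[2], 1)
  expect_equal(counts[4], 2)
  expect_equal(sum(counts), 3)

  rnd <- withr::with_seed(8, tibble::tibble(
    time_s = runif(500, 0, 10),
    channel_id = sample(c("p1", "p2"), 500, TRUE)))
  expect_equal(sum(bin_spikes(rnd, channels, "PL", 0.05, duration_s = 10)),
               500)
  expect_error(bin_spikes(sp, channels, "CTX", duration_s = 1),
               class = "neodev_param_error")
})

test_that("entropy matches analytic values", {
  expect_equal(entropy(rep(7, 100)), 0)
  expect_equal(entropy(rep(c(0, 1), 50)), 1)
  expect_equal(entropy(c(0, 0, 1, 2)), 1.5)
  expect_error(entropy(integer(0)), class = "neodev_param_error")
})

test_that("mutual information has its identity, independence, and symmetry properties", {
  x <- withr::with_seed(9, rpois(2000, 2))
  expect_equal(mutual_information(x, x), entropy(x))

  # exact-count independent fair coins: joint uniform over {0,1}^2
  xs <- c(0, 0, 1, 1); ys <- c(0, 1, 0, 1)
  expect_equal(mutual_information(xs, ys), 0)

  y <- withr::with_seed(10, rpois(2000, 2))
  expect_lt(abs(mutual_information(x, y) - mutual_information(y, x)), 1e-12)
  expect_lte(mutual_information(x, y), min(entropy(x), entropy(y)) + 1e-12)
  expect_error(mutual_information(x, y[-1]), class = "neodev_param_error")
})

test_that("coarser binning does not increase mutual information beyond noise", {
  gen <- gen_coupled_spike_trains(8, 0.6, 600, seed = 11)
  fine_pl <- gen$counts_pl
  fine_hp <- gen$counts_hp
  merge2 <- function(v) v[seq(1, length(v) - 1, 2)] + v[seq(2, length(v), 2)]
  mi_fine <- mutual_information(fine_pl, fine_hp)
  mi_coarse <- mutual_information(merge2(fine_pl), merge2(fine_hp))
  # data processing: a slight plug-in bias change is tolerated
  expect_lt(mi_coarse, mi_fine + 0.05)
})
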