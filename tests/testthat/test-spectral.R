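test_that("Welch PSD satisfies Parseval for sinusoids and noise", {
  fs <- 100
  expect_true(all(welch_psd(rep(0, 1000), fs)$power == 0))

  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  p <- welch_psd(2 * sin(2 * pi * 10 * t), fs, window_s = 2)
  integral <- neodev:::trapz(p$freq_hz, p$power)
  expect_equal(integral, 2, tolerance = 0.05)  # A^2/2
  expect_equal(p$freq_hz[which.max(p$power)], 10)
  expect_identical(attr(p, "n_windows"), 30L %/% 1L * 1L)

  pw <- welch_psd(withr::with_seed(1, rnorm(6000, sd = 2)), fs, 1)
  expect_gte(attr(pw, "n_windows"), 30)
  expect_gt(neodev:::trapz(pw$freq_hz, pw$power), 3.6)
  expect_lt(neodev:::trapz(pw$freq_hz, pw$power), 4.4)

  expect_error(welch_psd(rnorm(50), fs, 1), class = "neodev_param_error")
})

test_that("PSD over periods equals the PSD of the excised segment", {
  fs <- 100
  rec <- burst_recording(duration_s = 60, bursts = list(c(20, 30)),
                         amplitude = 50, noise_sd = 1, seed = 10)
  periods <- tibble::tibble(channel_id = "pl1", start_s = 20, end_s = 30,
                            label = "p")
  p1 <- psd_over_periods(rec, periods, 1, "pl1")
  excised <- rec$samples[1, (20 * fs + 1):(30 * fs)]
  p2 <- welch_psd(excised, fs, 1)
  expect_equal(p1$freq_hz[which.max(p1$power)], 10)
  expect_equal(p1$power, p2$power, tolerance = 0.05)

  # two identical periods average to the same PSD as one
  p3 <- psd_over_periods(rec, periods[c(1, 1), ], 1, "pl1")
  expect_equal(p3$power, p1$power, tolerance = 1e-12)

  short <- tibble::tibble(channel_id = "pl1", start_s = 5, end_s = 5.5,
                          label = "p")
  expect_error(psd_over_periods(rec, short, 1, "pl1"),
               class = "neodev_param_error")
})

test_that("band powers integrate correctly and add over adjacent bands", {
  psd <- structure(tibble::tibble(freq_hz = 0:50,
                                  power = as.numeric(0:50 >= 4 & 0:50 < 12)),
                   class = c("neodev_psd", "tbl_df", "tbl", "data.frame"))
  # flat 1 uV^2/Hz over theta: trapezoid loses half a bin at each edge
  expect_equal(band_power(psd, c(4, 12)), 7.5)

  sim <- welch_psd(withr::with_seed(2, rnorm(12000)), 100, 1)
  bands <- band_scheme()
  total <- band_power(sim, c(4, 40))
  parts <- sum(vapply(bands, function(b) band_power(sim, b), numeric(1)))
  expect_equal(parts, total, tolerance = 1e-9)

  t <- seq(0, 60 - 0.01, by = 0.01)
  p25 <- welch_psd(sin(2 * pi * 25 * t), 100, 1)
  expect_gt(band_power(p25, c(12, 30)) / neodev:::trapz(p25$freq_hz, p25$power),
            0.95)

  expect_error(band_power(sim, c(40, 60)), class = "neodev_param_error")
  expect_error(band_scheme(theta = c(4, 13)), class = "neodev_param_error")
})

test_that("imaginary coherence is exactly zero for identical signals", {
  x <- withr::with_seed(3, rnorm(3000))
  ic <- imaginary_coherence(x, x, 100, 1)
  expect_lte(max(ic$icoh), 1e-12)
  expect_true(all(ic$icoh >= 0 & ic$icoh <= 1))
})

test_that("imaginary coherence detects quadrature coupling and rejects noise", {
  fs <- 100
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  withr::with_seed(4, {
    x <- sin(2 * pi * 10 * t) + 0.1 * rnorm(length(t))
    y <- cos(2 * pi * 10 * t) + 0.1 * rnorm(length(t))
  })
  ic <- imaginary_coherence(x, y, fs, 1)
  expect_gte(ic$icoh[ic$freq_hz == 10], 0.9)

  null <- withr::with_seed(5, imaginary_coherence(rnorm(10000), rnorm(10000),
                                                  fs, 1))
  expect_lte(mean(null$icoh), 0.15)
  expect_identical(attr(null, "n_windows"), 100L)

  expect_error(imaginary_coherence(rnorm(100), rnorm(99), fs),
               class = "neodev_param_error")
})

test_that("imaginary coherence ignores zero-lag mixing", {
  withr::with_seed(6, {
    x <- rnorm(20000)
    n <- rnorm(20000)
  })
  for (a in c(0.01, 0.1, 1)) {
    ic <- imaginary_coherence(x, x + a * n, 100, 1)
    expect_lte(mean(ic$icoh), 0.15)
  }
})

test_that("comodulogram peaks at the injected phase/amplitude cell", {
  sim <- gen_lfp(lfp_sim_spec(duration_s = 60, bursts = NULL,
                              pac = list(phase_hz = 6, amp_hz = 25,
                                         depth = 0.9), seed = 11))
  com <- suppressWarnings(pac_comodulogram(sim$recording$samples[2, ],
                                           sim$recording$samples[1, ], 100))
  peak <- com[which.max(com$coupling), ]
  expect_equal(peak$phase_hz, 6)
  expect_equal(peak$amp_hz, 25)
  expect_true(all(com$coupling >= 0 & com$coupling <= 1, na.rm = TRUE))
})

test_that("modulation index is invariant to amplitude scaling of either signal", {
  sim <- gen_lfp(lfp_sim_spec(duration_s = 30, bursts = NULL,
                              pac = list(phase_hz = 6, amp_hz = 25,
                                         depth = 0.7), seed = 12))
  rec2 <- sim$recording
  rec2$samples[1, ] <- 5 * rec2$samples[1, ]
  rec2$samples[2, ] <- 0.3 * rec2$samples[2, ]
  expect_equal(pac_cell_mi(rec2), pac_cell_mi(sim$recording),
               tolerance = 1e-9)
})

test_that("pac_band_average selects the right cells", {
  com <- structure(tidyr::expand_grid(phase_hz = 4:12,
                                      amp_hz = seq(14, 40, 2)),
                   class = c("neodev_comodulogram", "tbl_df", "tbl",
                             "data.frame"))
  com$coupling <- 1
  expect_equal(pac_band_average(com), 1)

  com$coupling <- withr::with_seed(7, runif(nrow(com)))
  sel <- com$amp_hz >= 20 & com$amp_hz <= 30 & com$phase_hz >= 4 &
    com$phase_hz <= 12
  expect_equal(pac_band_average(com), mean(com$coupling[sel]))
  one <- com$coupling[com$amp_hz == 20 & com$phase_hz == 5]
  expect_equal(pac_band_average(com, c(20, 20), c(5, 5)), one)
  expect_error(pac_band_average(com, c(100, 110)),
               class = "neodev_param_error")
})
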