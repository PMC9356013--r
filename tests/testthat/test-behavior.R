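make_track <- function(head, cog, fps = 10) {
  tibble::tibble(t_s = (seq_along(head) - 1) / fps, head_zone = head,
                 cog_zone = cog)
}

test_that("interaction bouts follow the head-in, climbing-excluded rule", {
  head <- rep(NA_character_, 100); head[11:20] <- "obj"
  s <- extract_interactions(make_track(head, rep(NA_character_, 100)), "obj")
  expect_equal(s$n_bouts, 1)
  expect_equal(s$total_time_s, 1)
  expect_equal(s$mean_bout_s, 1)

  both <- rep("obj", 50)
  s2 <- extract_interactions(make_track(both, both), "obj")
  expect_equal(s2$n_bouts, 0)
  expect_equal(s2$total_time_s, 0)

  alt <- rep(c("obj", NA), 5)
  s3 <- extract_interactions(make_track(alt, rep(NA_character_, 10)), "obj")
  expect_equal(s3$n_bouts, 5)  # run-length oracle

  # interaction time never increases when the climbing exclusion is on
  withr::with_seed(12, {
    for (i in 1:5) {
      h <- sample(c("obj", NA), 60, TRUE)
      cg <- sample(c("obj", NA), 60, TRUE)
      on <- extract_interactions(make_track(h, cg), "obj")
      off <- extract_interactions(make_track(h, cg), "obj",
                                  climbing_exclusion = FALSE)
      expect_lte(on$total_time_s, off$total_time_s)
    }
  })
  expect_error(extract_interactions(make_track(rep("x", 5),
                                               rep(NA_character_, 5)),
                                    "obj", zones = c("obj", "arena")),
               class = "neodev_param_error")
})

test_that("discrimination ratio is the normalized difference, antisymmetric, NA at 0/0", {
  expect_equal(discrimination_ratio(30, 10), 0.5)
  expect_equal(discrimination_ratio(10, 10), 0)
  expect_equal(discrimination_ratio(7, 0), 1)
  expect_true(is.na(discrimination_ratio(0, 0)))
  withr::with_seed(13, {
    a <- runif(20); b <- runif(20)
    expect_equal(discrimination_ratio(a, b), -discrimination_ratio(b, a))
  })
  expect_error(discrimination_ratio(-1, 2), class = "neodev_param_error")
})

test_that("alternation metrics enumerate triplets correctly", {
  m <- alternation_metrics(c("A", "B", "C", "A", "B", "C"))
  expect_equal(m$spontaneous_pct, 100)
  m2 <- alternation_metrics(c("A", "B", "A", "B"))
  expect_equal(m2$spontaneous_pct, 0)
  expect_equal(m2$alternate_arm_return_pct, 100)
  m3 <- alternation_metrics(c("A", "A", "A"))
  expect_equal(m3$same_arm_return_pct, 100)
  expect_error(alternation_metrics(c("A", "B")), class = "neodev_param_error")
  expect_error(alternation_metrics(c("A", "B", "D")),
               class = "neodev_param_error")
})

test_that("alternation categories are disjoint on random sequences", {
  withr::with_seed(14, {
    for (i in 1:20) {
      seqn <- sample(c("A", "B", "C"), 25, TRUE)
      m <- alternation_metrics(seqn)
      # spontaneous, alternate-arm-return, same-arm-return, and the
      # remaining first=second!=third case partition all triplets
      expect_lte(m$spontaneous_pct + m$alternate_arm_return_pct +
                   m$same_arm_return_pct, 100 + 1e-9)
    }
  })
})

test_that("marble index averages observers per timepoint", {
  counts <- tibble::tibble(timepoint_min = rep(c(5, 10), each = 3),
                           observer = rep(1:3, 2),
                           n_buried = c(10, 12, 11, 0, 0, 0))
  idx <- marble_index(counts)
  expect_equal(idx$marble_index, c(11, 0))
  rnd <- withr::with_seed(15, tibble::tibble(
    timepoint_min = rep(c(5, 10, 15, 20, 30), each = 3),
    observer = rep(1:3, 5), n_buried = sample(0:20, 15, TRUE)))
  idx2 <- marble_index(rnd)
  oracle <- tapply(rnd$n_buried, rnd$timepoint_min, sum) / 3
  expect_equal(idx2$marble_index,
               as.numeric(oracle[as.character(idx2$timepoint_min)]))
  expect_error(marble_index(tibble::tibble(timepoint_min = 5, observer = 1,
                                           n_buried = 21)),
               class = "neodev_param_error")
})

test_that("open-field metrics compute occupancy, distance, velocity", {
  reg <- tibble::tibble(zone = c("c1", "b1"), role = c("center", "border"))
  still <- tibble::tibble(t_s = seq(0, 9.9, 0.1), x_cm = 0, y_cm = 0,
                          cog_zone = "c1")
  m <- openfield_metrics(still, reg)
  expect_equal(m$distance_cm, 0)
  expect_equal(m$velocity_cm_s, 0)
  expect_equal(m$time_center_s, 10)

  straight <- tibble::tibble(t_s = seq(0, 9.9, 0.1),
                             x_cm = seq(0, 34, length.out = 100), y_cm = 0,
                             cog_zone = "b1")
  m2 <- openfield_metrics(straight, reg)
  expect_equal(m2$distance_cm, 34)
  expect_equal(m2$velocity_cm_s, 3.4)

  square <- tibble::tibble(
    t_s = seq(0, 3.9, 0.1),
    x_cm = c(seq(0, 9, 1), rep(10, 10), seq(9, 0, -1), rep(0, 10)),
    y_cm = c(rep(0, 10), seq(1, 10, 1), rep(10, 10), seq(9, 0, -1)),
    cog_zone = "c1")
  m3 <- openfield_metrics(square, reg)
  poly <- sum(sqrt(diff(square$x_cm)^2 + diff(square$y_cm)^2))
  expect_equal(m3$distance_cm, poly)
  expect_warning(openfield_metrics(straight, reg, arena_radius_cm = 17),
                 regexp = "clamped")
})

test_that("scan-sampling proportion is the on-nest percentage", {
  expect_equal(scan_sampling_proportion(c(rep(TRUE, 15), rep(FALSE, 5))), 75)
  expect_equal(scan_sampling_proportion(rep(FALSE, 20)), 0)
  d1 <- rep(c(TRUE, FALSE), c(12, 8))
  d2 <- rep(c(TRUE, FALSE), c(5, 15))
  d3 <- rep(c(TRUE, FALSE), c(20, 0))
  combined <- scan_sampling_proportion(c(d1, d2, d3))
  daily <- c(scan_sampling_proportion(d1), scan_sampling_proportion(d2),
             scan_sampling_proportion(d3))
  expect_equal(combined, mean(daily))
  expect_error(scan_sampling_proportion(logical(0)),
               class = "neodev_param_error")
})
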