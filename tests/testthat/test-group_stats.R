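test_that("percentile outlier rule drops strict exceedances of P10/P90", {
  e <- exclude_outliers(1:10)
  expect_equal(sort(e$excluded), c(1, 10))  # P10 = 1.9, P90 = 9.1 (type 7)
  expect_setequal(c(e$kept, e$excluded), 1:10)

  same <- exclude_outliers(rep(3.3, 8))
  expect_equal(length(same$excluded), 0)

  withr::with_seed(16, {
    v <- rnorm(25)
    a <- exclude_outliers(v)
    b <- exclude_outliers(-v)
    expect_equal(length(a$excluded), length(b$excluded))
    expect_equal(sort(-a$kept), sort(b$kept))
  })
  expect_warning(exclude_outliers(c(1, 2)), regexp = "skipped")
})

test_that("Mann-Whitney U is exact for small tie-free samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 labelings as extreme

  # U_x + U_y = nx * ny and p symmetric in the arguments
  withr::with_seed(17, {
    x <- rnorm(6); y <- rnorm(8)
    rx <- mann_whitney_u(x, y); ry <- mann_whitney_u(y, x)
    expect_equal(rx$statistic + ry$statistic, 48)
    expect_equal(rx$p_value, ry$p_value)
  })

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 0.05)
  expect_error(mann_whitney_u(numeric(0), 1), class = "neodev_param_error")
})

test_that("exact Mann-Whitney matches wilcox.test for all sizes with nx+ny <= 10", {
  withr::with_seed(18, {
    for (nx in 1:5) {
      for (ny in seq_len(10 - nx)) {
        v <- sample(1000, nx + ny)  # tie-free
        x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
        mine <- mann_whitney_u(x, y)
        ref <- wilcox.test(x, y, exact = TRUE)
        expect_equal(mine$statistic, unname(ref$statistic))
        expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
      }
    }
  })
})

test_that("tied or large samples use the corrected normal approximation", {
  withr::with_seed(19, {
    x <- round(rnorm(20), 1); y <- round(rnorm(25), 1)  # ties likely
    mine <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_match(mine$method, "normal")
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  })
})

test_that("rank tests are invariant under strictly monotone transforms", {
  withr::with_seed(20, {
    x <- rlnorm(9); y <- rlnorm(11)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 mann_whitney_u(log(x), log(y))$p_value)
    g <- list(a = rnorm(7), b = rnorm(7), c = rnorm(7))
    ge <- lapply(g, exp)
    expect_equal(kruskal_dunn(g)$statistic, kruskal_dunn(ge)$statistic)
  })
})

test_that("Kruskal-Wallis H matches the hand-ranked fixture and base R", {
  k <- kruskal_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(k$statistic, 7.2)  # mean ranks 2, 5, 8
  expect_equal(unname(k$statistic),
               unname(kruskal.test(list(c(1, 2, 3), c(4, 5, 6),
                                        c(7, 8, 9)))$statistic))
  expect_equal(nrow(k$pairwise), 3)
  expect_true(all(k$pairwise$p_adjusted >= k$pairwise$p_unadjusted))

  ident <- kruskal_dunn(list(a = rep(2, 4), b = rep(2, 4), c = rep(2, 4)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  withr::with_seed(21, {
    g <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6))
    expect_equal(kruskal_dunn(g)$statistic,
                 kruskal_dunn(g[c(3, 1, 2)])$statistic)
    # tie-corrected H matches base R with ties present
    gt <- lapply(g, round, digits = 0)
    expect_equal(unname(kruskal_dunn(gt)$statistic),
                 unname(kruskal.test(gt)$statistic))
  })
})

test_that("Friedman chi-square is n(k-1) at perfect concordance and matches base R", {
  m <- matrix(rep(c(1, 2, 3), each = 10), nrow = 10)
  f <- friedman_dunn(m)
  expect_equal(f$statistic, 20)
  expect_equal(unname(f$statistic), unname(friedman.test(m)$statistic))
  expect_lt(f$p_value, 0.001)

  withr::with_seed(22, {
    r <- matrix(rnorm(36), 12)
    expect_equal(unname(friedman_dunn(r)$statistic),
                 unname(friedman.test(r)$statistic))
  })
  expect_error(friedman_dunn(matrix(c(1, NA, 2, 3), 2)),
               class = "neodev_param_error")
})

test_that("two-treatment Friedman agrees with the sign test ordering", {
  withr::with_seed(23, {
    m <- matrix(rnorm(30), 15, 2)
    f <- friedman_dunn(m)
    b <- sum(m[, 1] > m[, 2])
    sign_p <- binom.test(b, 15)$p.value
    # both are functions of the same count; identical accept/reject ordering
    expect_equal(f$statistic, (2 * b - 15)^2 / 15)
    expect_equal(f$p_value < 0.05, sign_p < 0.05)
  })
})

test_that("tidy and glance expose test results in broom form", {
  k <- kruskal_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  td <- tidy(k)
  expect_equal(td$term[1], "omnibus")
  expect_equal(nrow(td), 4)
  gl <- glance(k)
  expect_equal(gl$n, 9)
  expect_equal(gl$k_groups, 3)
})
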