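# Nonparametric group-comparison battery: percentile outlier exclusion,
# Mann-Whitney U (exact by full enumeration for small tie-free samples, normal
# approximation with tie and continuity corrections otherwise), Kruskal-Wallis
# with Dunn's post hoc, and Friedman with Dunn's post hoc. All tests are
# rank-based and therefore invariant under strictly monotone transformations.

new_test_result <- function(method, statistic_name, statistic, p_value,
                            group_sizes, pairwise = NULL, exclusions = NULL) {
  structure(list(method = method, statistic_name = statistic_name,
                 statistic = statistic, p_value = p_value,
                 group_sizes = group_sizes, pairwise = pairwise,
                 exclusions = exclusions),
            class = "neodev_test")
}

#' @export
print.neodev_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic_name, x$statistic, x$p_value,
              paste(x$group_sizes, collapse = "/")))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Percentile outlier exclusion
#'
#' Drops values strictly above the 90th and strictly below the 10th percentile
#' (linear-interpolation percentiles, `stats::quantile()` type 7). With
#' `n <= 2` the input is returned unchanged with a warning.
#'
#' @param values Numeric vector, `n >= 1`.
#' @param probs Lower/upper percentile bounds (default `c(0.1, 0.9)`).
#' @param type Percentile method passed to [stats::quantile()] (default 7,
#'   linear interpolation).
#' @return List with `kept` and `excluded`; their union is the input.
#' @export
exclude_outliers <- function(values, probs = c(0.1, 0.9), type = 7) {
  if (length(values) == 0) abort("empty input", class = "neodev_param_error")
  if (length(values) <= 2) {
    warn("n <= 2: outlier exclusion skipped")
    return(list(kept = values, excluded = values[0]))
  }
  q <- quantile(values, probs = probs, type = type, names = FALSE)
  drop <- values < q[1] | values > q[2]
  list(kept = values[!drop], excluded = values[drop])
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (tie-free data only). Returns p = min(1, 2 * min tail).
mw_exact_p <- function(u, nx, ny) {
  n <- nx + ny
  combos <- utils::combn(n, nx)
  ranksum <- colSums(combos)
  us <- ranksum - nx * (nx + 1) / 2
  lo <- mean(us <= u)
  hi <- mean(us >= u)
  min(1, 2 * min(lo, hi))
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from midrank-tied ranks. The p-value is exact (full
#' enumeration of the `choose(nx + ny, nx)` rank assignments) when
#' `nx + ny <= 16` and the data are tie-free; otherwise a normal approximation
#' with tie and continuity corrections is used. `U_x + U_y = nx * ny` always.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Largest combined n for which the exact enumeration is
#'   attempted (default 16).
#' @return A `neodev_test` with the U statistic (for `x`) and two-sided p.
#' @export
mann_whitney_u <- function(x, y, exact_max = 16) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) abort("empty group", class = "neodev_param_error")
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(all_v))
  n <- nx + ny
  if (!ties && n <= exact_max) {
    p <- mw_exact_p(u, nx, ny)
    method <- "Mann-Whitney U (exact)"
  } else {
    tie_tab <- table(all_v)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    mu <- nx * ny / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U (normal approximation)"
  }
  new_test_result(method, "U", u, p, c(nx, ny))
}

# Dunn pairwise comparisons after Kruskal-Wallis. `r` are the pooled ranks,
# `g` the group factor. Bonferroni (multiply by number of pairs, cap at 1) by
# default; Holm available.
dunn_pairwise <- function(r, g, adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  n <- length(r)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    na <- sum(g == a); nb <- sum(g == b)
    z <- (mean(r[g == a]) - mean(r[g == b])) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / na + 1 / nb))
    tibble::tibble(comparison = paste(a, "vs", b), z = z,
                   p_unadjusted = 2 * pnorm(-abs(z)))
  })
  m <- nrow(res)
  res$p_adjusted <- if (adjust == "bonferroni") {
    pmin(1, res$p_unadjusted * m)
  } else {
    stats::p.adjust(res$p_unadjusted, "holm")
  }
  res
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected H with a chi-square omnibus p on `k - 1` df, followed by Dunn
#' pairwise z tests with Bonferroni adjustment (multiply by the number of
#' pairs, cap at 1). With two groups the omnibus test degrades gracefully to a
#' rank test on one df.
#'
#' @param groups Named list of numeric vectors, or a data frame with `value`
#'   and `group` columns.
#' @param adjust `"bonferroni"` (default) or `"holm"`.
#' @return A `neodev_test` with the H statistic, omnibus p, and the pairwise
#'   table in `$pairwise`.
#' @export
kruskal_dunn <- function(groups, adjust = "bonferroni") {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (any(lengths(groups) == 0)) abort("empty group",
                                       class = "neodev_param_error")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)),
              levels = names(groups) %||% seq_along(groups))
  n <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  tie_tab <- table(v)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  h <- if (corr > 0) h / corr else 0
  k <- nlevels(g)
  p <- pchisq(h, df = k - 1, lower.tail = FALSE)
  new_test_result("Kruskal-Wallis + Dunn", "H", h, p, ni,
                  pairwise = dunn_pairwise(r, g, adjust))
}

#' Friedman test with Dunn's post hoc comparisons
#'
#' Within-block midranks, tie-corrected Friedman chi-square on `k - 1` df,
#' and Dunn pairwise z tests on the treatment mean ranks with Bonferroni
#' adjustment.
#'
#' @param block_matrix Numeric matrix, blocks x treatments (no missing cells;
#'   unbalanced designs are unsupported).
#' @param adjust `"bonferroni"` or `"holm"`.
#' @return A `neodev_test` with the chi-square statistic and pairwise table.
#' @export
friedman_dunn <- function(block_matrix, adjust = "bonferroni") {
  m <- as.matrix(block_matrix)
  if (anyNA(m)) abort("missing cells: unbalanced designs unsupported",
                      class = "neodev_param_error")
  nb <- nrow(m); k <- ncol(m)
  if (nb < 2 || k < 2) abort("need >= 2 blocks and >= 2 treatments",
                             class = "neodev_param_error")
  ranks <- t(apply(m, 1, rank))
  rj <- colSums(ranks)
  stat <- 12 / (nb * k * (k + 1)) * sum(rj^2) - 3 * nb * (k + 1)
  # tie correction within blocks
  tie_sum <- sum(apply(m, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  corr <- 1 - tie_sum / (nb * k * (k^2 - 1))
  stat <- if (corr > 0) stat / corr else 0
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  rbar <- rj / nb
  cols <- colnames(m) %||% paste0("T", seq_len(k))
  pairs <- utils::combn(seq_len(k), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    z <- (rbar[a] - rbar[b]) / sqrt(k * (k + 1) / (6 * nb))
    tibble::tibble(comparison = paste(cols[a], "vs", cols[b]), z = z,
                   p_unadjusted = 2 * pnorm(-abs(z)))
  })
  mpairs <- nrow(pw)
  pw$p_adjusted <- if (adjust == "bonferroni") {
    pmin(1, pw$p_unadjusted * mpairs)
  } else {
    stats::p.adjust(pw$p_unadjusted, "holm")
  }
  new_test_result("Friedman + Dunn", "chi-squared", stat, p, rep(nb, k),
                  pairwise = pw)
}
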