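test_that("KNNr statistic is maximal for separated clusters and matches exact enumeration", {
  # chained spacings keep each cluster's neighbour graph connected, so
  # exactly the 2 cluster-aligned labelings reach the maximal statistic
  x <- c(0, 1, 2.1, 3.3, 4.6)
  pts <- cbind(c(x, x + 100), 0)
  labs <- rep(c("a", "b"), each = 5)
  res <- knnr_test(pts, labs, k = 1, n_perm = 4999, seed = 11)
  expect_equal(res$statistic, 10)
  expect_lte(res$p_value, 0.01)
  expect_equal(knnr_exact_p(pts, labs, k = 1), 2 / choose(10, 5))
  expect_lt(abs(res$p_value - 2 / choose(10, 5)), 0.005)

  # tiny instance: permutation p agrees with full enumeration
  set.seed(5)
  small <- cbind(rnorm(8), rnorm(8))
  slabs <- rep(c("a", "b"), each = 4)
  exact <- knnr_exact_p(small, slabs, k = 1)
  perm <- knnr_test(small, slabs, k = 1, n_perm = 4999, seed = 2)$p_value
  expect_lt(abs(perm - exact), 0.03)
})

test_that("KNNr is invariant to point reordering and rejects degenerate input", {
  set.seed(9)
  pts <- cbind(rnorm(12), rnorm(12))
  labs <- rep(c("a", "b"), 6)
  ord <- sample(12)
  r1 <- knnr_test(pts, labs, n_perm = 499, seed = 3)
  r2 <- knnr_test(pts[ord, ], labs[ord], n_perm = 499, seed = 3)
  expect_equal(r1$statistic, r2$statistic)

  expect_error(knnr_test(pts, rep("a", 12), n_perm = 99, seed = 1), "2 groups")
  expect_error(knnr_test(pts, labs, k = 11, n_perm = 99, seed = 1), "k must")
  expect_error(knnr_test(pts, labs, n_perm = 99), "seed")
})

test_that("Wilcoxon W follows the pair-count convention with its symmetry identity", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$statistic, 0)
  expect_equal(wilcoxon_rank_sum(c(3, 4), c(1, 2))$statistic, 4)
  x <- c(1, 2, 5, 7); y <- c(2, 3, 8)
  expect_equal(wilcoxon_rank_sum(x, y)$statistic +
                 wilcoxon_rank_sum(y, x)$statistic, length(x) * length(y))
  same <- c(1, 2, 3)
  expect_equal(wilcoxon_rank_sum(same, same)$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1), "empty")
})

test_that("Kruskal-Wallis matches the direct rank-sum formula and handles degenerate input", {
  # hand-rank oracle on {1,2},{3,4},{5,6}: ranks are the values themselves
  vals <- 1:6
  grp <- rep(c("g1", "g2", "g3"), each = 2)
  R <- tapply(rank(vals), grp, sum)
  H <- 12 / (6 * 7) * sum(R^2 / 2) - 3 * 7
  got <- kruskal_wallis(vals, grp)
  expect_equal(got$statistic, unname(H))
  expect_equal(got$df, 2)

  same <- kruskal_wallis(rep(5, 6), grp)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # two-group case agrees with the Wilcoxon decision on tie-free data
  x <- c(1.3, 2.2, 5.9); y <- c(3.1, 4.7, 8.2, 9.9)
  kp <- kruskal_wallis(c(x, y), rep(c("a", "b"), c(3, 4)))$p_value
  wp <- wilcoxon_rank_sum(x, y)$p_value
  expect_equal(kp < 0.05, wp < 0.05)
})

test_that("Holm adjustment matches the step-down formula and is monotone", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  set.seed(1)
  p <- runif(20)
  expect_true(all(holm_adjust(p) >= p))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("pairwise group tests produce the full comparison table with Holm p per element", {
  src <- generate_sources(synthetic_design(n_sources_per_group = 10, seed = 4))
  tbl <- pairwise_group_tests(src)
  expect_equal(nrow(tbl), 12) # 6 pairs x 2 elements
  expect_true(all(tbl$p_holm >= tbl$p_value))
})

test_that("generalized Shapiro-Wilk flags bimodality and rejects singular covariance", {
  set.seed(21)
  bimodal <- rbind(cbind(rnorm(40, -5, 0.3), rnorm(40, -5, 0.3)),
                   cbind(rnorm(40, 5, 0.3), rnorm(40, 5, 0.3)))
  res <- bivariate_normality(bimodal, n_mc = 400, seed = 8)
  expect_lt(res$p_value, 0.01)

  sing <- cbind(1:20, 2 * (1:20))
  expect_error(bivariate_normality(sing), "singular")
  expect_error(bivariate_normality(matrix(rnorm(8), 4, 2)), "n >= 5")
})

test_that("regression of d15N on d13C recovers an exact line and its summaries", {
  x <- seq(-18, -11, length.out = 10)
  pts <- tibble::tibble(d13C = x, d15N = 2 * x + 1)
  reg <- suppressWarnings(correlate_and_regress(pts)) # exact fit warns in summary.lm
  expect_equal(reg$r, 1)
  expect_equal(reg$slope, 2)
  expect_equal(reg$intercept, 1)
  expect_equal(glance(reg)$slope, 2)
  expect_equal(nrow(suppressWarnings(tidy(reg))), 2)

  flat <- tibble::tibble(d13C = rep(-15, 5), d15N = rnorm(5))
  expect_error(correlate_and_regress(flat), "zero variance")

  # slope CI covers 0 for pure noise
  set.seed(3)
  noise <- tibble::tibble(d13C = rnorm(50), d15N = rnorm(50))
  td <- tidy(correlate_and_regress(noise))
  sl <- td[td$term == "slope", ]
  expect_true(abs(sl$estimate) < qt(0.995, 48) * sl$std.error)
})

test_that("confidence band is widest away from the mean abscissa", {
  set.seed(6)
  pts <- tibble::tibble(d13C = rnorm(30, -14), d15N = rnorm(30, 13))
  reg <- correlate_and_regress(pts)
  band <- regression_band(reg, c(-20, mean(pts$d13C), -8))
  w <- band$upr - band$lwr
  expect_gt(w[1], w[2])
  expect_gt(w[3], w[2])
})

test_that("baboon residuals below the regression line follow the line arithmetic", {
  reg <- suppressWarnings(correlate_and_regress(tibble::tibble(
    d13C = seq(-18, -11, length.out = 20),
    d15N = 0.9 * seq(-18, -11, length.out = 20) + 26.4
  )))
  on_line <- tibble::tibble(d13C = -15, d15N = 0.9 * -15 + 26.4)
  expect_equal(baboon_offset_report(on_line, reg)$residual_below, 0)

  bab <- tibble::tibble(d13C = -21.9, d15N = 5.4)
  rep <- baboon_offset_report(bab, reg)
  expect_equal(rep$predicted_d15N, 0.9 * -21.9 + 26.4) # 6.69
  expect_equal(rep$residual_below, 1.29)
  expect_equal(unname(attr(rep, "range")["min"]), 1.29)
})
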