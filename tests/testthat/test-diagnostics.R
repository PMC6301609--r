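test_that("Gelman-Rubin follows its closed form and detects separated chains", {
  # identical chains: B = 0, R-hat = sqrt((n-1)/n) = sqrt(3/4)
  expect_equal(gelman_rubin(cbind(1:4, 1:4)), sqrt(3 / 4))

  # two equal-variance chains with means 10 SDs apart: plug in the formula
  set.seed(1)
  n <- 2000
  a <- rnorm(n); b <- rnorm(n) + 10
  got <- gelman_rubin(cbind(a, b))
  W <- (var(a) + var(b)) / 2
  B <- n * var(c(mean(a), mean(b)))
  expect_equal(got, sqrt(((n - 1) / n * W + B / n) / W))
  expect_gt(got, 1.05)

  # near 1 for splits of one long stationary stream
  x <- rnorm(10000)
  expect_lt(abs(gelman_rubin(matrix(x, ncol = 2)) - 1), 0.01)

  expect_error(gelman_rubin(cbind(rep(1, 10), rep(1, 10))), "degenerate")
  expect_error(gelman_rubin(matrix(1:4, ncol = 1)), "chains")
})

test_that("Gelman-Rubin is invariant under joint affine transformation", {
  set.seed(4)
  ch <- cbind(rnorm(500), rnorm(500, 0.3))
  expect_equal(gelman_rubin(ch), gelman_rubin(3.7 * ch - 11))
})

test_that("Gelman-Rubin agrees with coda on well-behaved chains", {
  skip_if_not_installed("coda")
  set.seed(8)
  ch <- cbind(rnorm(5000), rnorm(5000))
  ours <- gelman_rubin(ch)
  theirs <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(ch[, 1]),
                                              coda::mcmc(ch[, 2])))$psrf[1]
  expect_equal(ours, theirs, tolerance = 0.01)
})

test_that("Geweke z catches trends, flips sign under reversal, and matches coda", {
  set.seed(3)
  trended <- rnorm(5000) + seq(0, 5, length.out = 5000)
  expect_gt(abs(geweke_z(trended)), 5)
  # with equal windows the reversed chain gives exactly the negated score
  z <- geweke_z(trended, 0.3, 0.3)
  expect_equal(geweke_z(rev(trended), 0.3, 0.3), -z, tolerance = 1e-9)

  calm <- 7 + rnorm(2000, sd = 1e-3)
  expect_lt(abs(geweke_z(calm, 0.4, 0.4)), 3)

  expect_error(geweke_z(rnorm(100), 0.6, 0.6), "overlap")
  expect_error(geweke_z(rnorm(50), 0.1, 0.5), ">= 10")

  skip_if_not_installed("coda")
  set.seed(12)
  x <- as.numeric(arima.sim(list(ar = 0.4), 4000))
  expect_equal(geweke_z(x), unname(coda::geweke.diag(coda::mcmc(x))$z),
               tolerance = 1e-6)
})

test_that("convergence report applies the R-hat and Geweke thresholds", {
  mkfit <- function(chs) structure(list(chains = chs), class = "simm_fit")
  set.seed(6)
  good <- lapply(1:3, function(i) {
    m <- matrix(rnorm(4000), ncol = 4)
    colnames(m) <- source_groups()
    m
  })
  rep_good <- convergence_report(mkfit(good))
  expect_true(rep_good$pass_rhat)
  expect_equal(nrow(rep_good$rhat), 4)
  expect_equal(nrow(rep_good$geweke), 12)

  # shift one chain far away: R-hat must fail
  bad <- good
  bad[[2]] <- bad[[2]] + 50
  expect_false(convergence_report(mkfit(bad))$pass_rhat)

  # inject a strong within-chain trend: Geweke must fail
  drift <- good
  drift[[1]][, 1] <- drift[[1]][, 1] + seq(0, 8, length.out = 1000)
  expect_false(convergence_report(mkfit(drift))$pass_geweke)
})

test_that("escalation stops at the first passing rung and never passes a failing report", {
  # deterministic stand-in chains: a seed whose iid chains pass both
  # diagnostics represents a converged sampler, separated chains a broken one
  good_fit <- function(seed) {
    set.seed(seed)
    chs <- lapply(1:3, function(i) {
      m <- matrix(rnorm(4000), ncol = 4)
      colnames(m) <- source_groups()
      m
    })
    structure(list(chains = chs), class = "simm_fit")
  }
  bad_fit <- function(seed) {
    f <- good_fit(seed)
    f$chains[[2]] <- f$chains[[2]] + 20
    f
  }
  passing_seed <- 107 # fixed fixture seed; see assertion below
  stopifnot(convergence_report(good_fit(passing_seed))$pass_geweke)
  ladder <- mcmc_ladder(seed = 1)

  calls <- 0
  res <- run_until_converged(function(cfg) {
    calls <<- calls + 1
    if (calls >= 2) good_fit(passing_seed) else bad_fit(1)
  }, ladder)
  expect_true(res$converged)
  expect_equal(res$report$escalation_level, 2)
  expect_true(res$report$pass_rhat && res$report$pass_geweke)

  res_bad <- run_until_converged(function(cfg) bad_fit(2), ladder)
  expect_false(res_bad$converged)
  expect_false(res_bad$report$pass_rhat)
  expect_equal(res_bad$report$escalation_level, length(ladder))

  one <- run_until_converged(function(cfg) good_fit(passing_seed), ladder[1])
  expect_true(one$converged)
  expect_error(run_until_converged(function(cfg) good_fit(1), list()), "non-empty")
})
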