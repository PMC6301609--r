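# Shared fixtures and independent oracles, built in code at test time.

# A clean four-source distribution table for toy model problems:
# well-separated groups, equal concentrations unless stated.
toy_dist <- function(sd = 0.5, conc_C = c(45, 45, 45, 45),
                     conc_N = c(10, 10, 10, 10)) {
  tibble::tibble(
    group = source_groups(),
    mu13C = c(-25, -21, -14, -13), sd13C = sd,
    mu15N = c(5, 8, 11, 16), sd15N = sd,
    conc_C = conc_C, conc_N = conc_N
  )
}

# TEF scenario helper with explicit values (avoids the named presets).
scen <- function(e13m, e13s, e15m, e15s, name = "custom") {
  tef_scenario(name, e13m, e13s, e15m, e15s)
}

# Batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) draw vector.
mcse <- function(x, n_batches = 30) {
  b <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(i) mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  sd(means) / sqrt(n_batches)
}

# Dense-grid posterior over the simplex restricted to `active` sources
# (others fixed at 0): an independent route to marginal posterior
# summaries, by direct quadrature instead of MCMC.
grid_posterior <- function(consumer, sources, scenario, active = 1:3,
                           step = 0.01, prior_alpha = NULL) {
  K <- nrow(sources)
  if (is.null(prior_alpha)) prior_alpha <- rep(1, K)
  m <- length(active)
  g <- seq(0, 1, by = step)
  pts <- expand.grid(rep(list(g), m - 1))
  pts <- pts[rowSums(pts) <= 1 + 1e-12, , drop = FALSE]
  P <- matrix(0, nrow(pts), K)
  P[, active[seq_len(m - 1)]] <- as.matrix(pts)
  P[, active[m]] <- pmax(0, 1 - rowSums(as.matrix(pts)))
  lp <- apply(P, 1, function(p) {
    prior <- sum((prior_alpha - 1) * log(pmax(p[active], 1e-300)))
    simm_log_likelihood(consumer, p, sources, scenario) + prior
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(P = P, w = w)
}

grid_marginal_quantile <- function(gp, k, probs) {
  ord <- order(gp$P[, k])
  x <- gp$P[ord, k]
  cw <- cumsum(gp$w[ord])
  vapply(probs, function(q) x[which(cw >= q)[1]], numeric(1))
}

# Independent point-in-polygon oracle: p lies in the convex hull iff the
# triangle fan from p over the hull edges has total area equal to the
# hull area (strictly larger when p is outside).
area_sum_inside <- function(poly, p, tol = 1e-9) {
  v <- as.matrix(poly[, c("d13C", "d15N")])
  n <- nrow(v)
  tri <- function(a, b, c) abs((b[1] - a[1]) * (c[2] - a[2]) -
                               (b[2] - a[2]) * (c[1] - a[1])) / 2
  fan <- sum(vapply(seq_len(n), function(i) {
    tri(v[i, ], v[if (i == n) 1 else i + 1, ], p)
  }, numeric(1)))
  abs(fan - polygon_area(poly)) <= tol * (1 + polygon_area(poly))
}

# Exact KNNr permutation p-value by full enumeration of distinct label
# assignments (feasible only for tiny n).
knnr_exact_p <- function(points, labels, k = 1) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  if (k == 1) nn <- matrix(nn, ncol = 1)
  score <- function(lab) sum(lab[nn] == rep(lab, k))
  obs <- score(labels)
  g1 <- sum(labels == labels[1])
  combos <- utils::combn(n, g1)
  stats <- apply(combos, 2, function(idx) {
    lab <- rep("b", n); lab[idx] <- "a"; score(lab)
  })
  mean(stats >= obs)
}

# Small consumers table with known deltas for ranking tests.
consumers_raw <- function(d13C, d15N = rep(12, length(d13C)),
                          ids = sprintf("H%02d", seq_along(d13C))) {
  tibble::tibble(consumer_id = ids, sex = "unknown", d13C = d13C, d15N = d15N)
}
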