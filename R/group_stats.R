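#' Per-group isotopic summary
#'
#' Means and standard deviations of \eqn{\delta^{13}}C, \eqn{\delta^{15}}N
#' and mean elemental concentrations per food group — the numbers behind
#' mean-and-error-bar biplots of source groups.
#'
#' @param sources Sources tibble (validated).
#' @return Tibble with one row per group: `group`, `n`, `mean_d13C`,
#'   `sd_d13C`, `mean_d15N`, `sd_d15N`, `mean_pct_C`, `mean_pct_N`.
#' @export
group_summary <- function(sources) {
  dplyr::summarise(
    dplyr::group_by(sources, .data$group),
    n = dplyr::n(),
    mean_d13C = mean(.data$d13C), sd_d13C = sd(.data$d13C),
    mean_d15N = mean(.data$d15N), sd_d15N = sd(.data$d15N),
    mean_pct_C = mean(.data$pct_C, na.rm = TRUE),
    mean_pct_N = mean(.data$pct_N, na.rm = TRUE),
    .groups = "drop"
  )
}

#' K-nearest-neighbour randomization (KNNr) test of group separation
#'
#' Permutation test of multivariate group distinctness in
#' (\eqn{\delta^{13}}C, \eqn{\delta^{15}}N) space. The statistic is the
#' total count, over all points, of same-label points among each point's
#' `k` Euclidean nearest neighbours (self excluded; distance ties broken by
#' point index order, so the statistic is deterministic). Significance is
#' assessed by randomly permuting the labels: since the neighbour graph
#' does not depend on labels, each permutation only re-scores the fixed
#' neighbour lists. p = (1 + #permutation statistics >= observed) /
#' (1 + n_perm).
#'
#' Axes are used in raw permil units (unscaled), matching how isotope
#' biplots are drawn.
#'
#' @param points Two-column matrix or data frame of (d13C, d15N).
#' @param labels Group label per point (>= 2 groups, each with >= 2 points).
#' @param k Number of neighbours (default 1); must satisfy k <= n - 2.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Integer seed (mandatory: the permutation draw must be
#'   reproducible).
#' @return One-row tibble: `statistic_name` ("KNNr_count"), `statistic`,
#'   `p_value`, `k`, `n_perm`, `n_per_group` (list column).
#' @export
knnr_test <- function(points, labels, k = 1, n_perm = 9999, seed) {
  if (missing(seed)) abort("knnr_test: seed is mandatory")
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  labels <- as.character(labels)
  n <- nrow(pts)
  if (length(labels) != n) abort("labels must match points")
  tab <- table(labels)
  if (length(tab) < 2) abort("knnr_test needs >= 2 groups")
  if (any(tab < 2)) abort("each group needs >= 2 points")
  if (k < 1 || k >= n - 1) abort("k must satisfy 1 <= k <= n - 2")

  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  # k nearest neighbours per point; ties broken by index order
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  if (k == 1) nn <- matrix(nn, ncol = 1)

  score <- function(lab) sum(lab[nn] == rep(lab, k))
  obs <- score(labels)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm_ge <- 0L
  for (b in seq_len(n_perm)) {
    if (score(sample(labels)) >= obs) perm_ge <- perm_ge + 1L
  }
  tibble::tibble(
    statistic_name = "KNNr_count", statistic = as.numeric(obs),
    p_value = (1 + perm_ge) / (1 + n_perm),
    k = k, n_perm = n_perm, n_per_group = list(c(tab))
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test of `x` versus `y`, reporting the W statistic in
#' the convention W = (rank sum of x) - n_x(n_x+1)/2, i.e. the number of
#' (x_i, y_j) pairs with x_i > y_j (ties counted 1/2). Exact p for small
#' tie-free samples, normal approximation with continuity and tie
#' correction otherwise (the default behaviour of [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors (non-empty).
#' @return One-row tibble: `statistic_name` ("W"), `statistic`, `p_value`,
#'   `n_x`, `n_y`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("wilcoxon_rank_sum: empty input")
  wt <- suppressWarnings(wilcox.test(x, y))
  tibble::tibble(
    statistic_name = "W", statistic = unname(wt$statistic),
    p_value = wt$p.value, n_x = length(x), n_y = length(y)
  )
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' H statistic with tie correction, df = #groups - 1, chi-square p-value
#' (delegated to [stats::kruskal.test()]). When every value is identical,
#' H = 0 and p = 1 (rather than an error), since no between-group signal
#' exists by construction.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 groups).
#' @return One-row tibble: `statistic_name` ("chi2"), `statistic`, `df`,
#'   `p_value`, `n_per_group` (list column).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) abort("kruskal_wallis needs >= 2 groups")
  if (length(unique(values)) == 1) {
    return(tibble::tibble(
      statistic_name = "chi2", statistic = 0,
      df = length(unique(groups)) - 1, p_value = 1,
      n_per_group = list(c(table(groups)))
    ))
  }
  kt <- kruskal.test(values, factor(groups))
  tibble::tibble(
    statistic_name = "chi2", statistic = unname(kt$statistic),
    df = unname(kt$parameter), p_value = kt$p.value,
    n_per_group = list(c(table(groups)))
  )
}

#' Holm step-down adjustment of p-values
#'
#' Family-wise error rate control by the Holm step-down procedure
#' (delegated to [stats::p.adjust()]); output order matches input order and
#' adjusted values are never smaller than the raw ones.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Pairwise Wilcoxon tests between food groups with Holm adjustment
#'
#' Runs [wilcoxon_rank_sum()] on every unordered pair of groups for each of
#' \eqn{\delta^{13}}C and \eqn{\delta^{15}}N, Holm-adjusting p-values
#' within each element's family of comparisons — a tidy version of the
#' classic food-group comparison table.
#'
#' @param sources Sources tibble.
#' @param elements Columns to test (default `c("d13C", "d15N")`).
#' @return Tibble: `element`, `group_a`, `group_b`, `W`, `p_value`,
#'   `p_holm`.
#' @export
pairwise_group_tests <- function(sources, elements = c("d13C", "d15N")) {
  grps <- sort(unique(sources$group))
  pairs <- utils::combn(grps, 2, simplify = FALSE)
  out <- purrr::map_dfr(elements, function(el) {
    res <- purrr::map_dfr(pairs, function(pr) {
      x <- sources[[el]][sources$group == pr[1]]
      y <- sources[[el]][sources$group == pr[2]]
      w <- wilcoxon_rank_sum(x, y)
      tibble::tibble(element = el, group_a = pr[1], group_b = pr[2],
                     W = w$statistic, p_value = w$p_value)
    })
    res$p_holm <- holm_adjust(res$p_value)
    res
  })
  out
}

# Whitening transform: standardized principal-component scores. Under the
# null the scores are iid standard normal in every coordinate; departures
# from normality concentrate along the data's own axes, where the
# univariate Shapiro-Wilk has power.
whiten_pc <- function(X) {
  S <- stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < .Machine$double.eps * max(e$values) * 100) {
    abort("singular covariance: multivariate normality test undefined")
  }
  scale(X, center = TRUE, scale = FALSE) %*%
    e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values))
}

mvw_statistic <- function(X) {
  Z <- whiten_pc(X)
  mean(apply(Z, 2, function(z) shapiro.test(z)$statistic))
}

#' Generalized Shapiro-Wilk test of bivariate (multivariate) normality
#'
#' Standardizes the data by the empirical mean and the inverse symmetric
#' square root of the empirical covariance, applies the univariate
#' Shapiro-Wilk test to each transformed coordinate, and averages the
#' coordinate statistics into the generalized statistic MVW. Because MVW is
#' affine-invariant, its null distribution depends only on (n, d); the
#' p-value is computed against a parametric-bootstrap reference of
#' `n_mc` standard-normal datasets of the same shape (left-tailed: small
#' MVW indicates non-normality), p = (1 + #null <= observed) / (1 + n_mc).
#' A precomputed reference (`null_stats`) can be supplied to amortize the
#' simulation across many tests of the same shape.
#'
#' @param points Matrix/data frame, one row per observation (n >= 5).
#' @param n_mc Monte-Carlo null size (default 500).
#' @param seed Integer seed for the null simulation.
#' @param null_stats Optional numeric vector of precomputed null MVW values
#'   for this (n, d) (see [mvw_null_reference()]).
#' @return One-row tibble: `statistic_name` ("MVW"), `statistic`,
#'   `p_value`, `n`, `d`.
#' @export
bivariate_normality <- function(points, n_mc = 500, seed = 1, null_stats = NULL) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  if (nrow(X) < 5) abort("bivariate_normality needs n >= 5")
  obs <- mvw_statistic(X)
  if (is.null(null_stats)) {
    null_stats <- mvw_null_reference(nrow(X), ncol(X), n_mc = n_mc, seed = seed)
  }
  tibble::tibble(
    statistic_name = "MVW", statistic = obs,
    p_value = (1 + sum(null_stats <= obs)) / (1 + length(null_stats)),
    n = nrow(X), d = ncol(X)
  )
}

#' Null reference distribution for the MVW statistic
#'
#' @param n,d Sample size and dimension.
#' @param n_mc Number of simulated null datasets.
#' @param seed Integer seed.
#' @return Numeric vector of `n_mc` null MVW statistics.
#' @export
mvw_null_reference <- function(n, d, n_mc = 500, seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(n_mc),
         function(i) mvw_statistic(matrix(rnorm(n * d), n, d)),
         numeric(1))
}

#' Correlation and linear regression of d15N on d13C
#'
#' Pearson product-moment correlation plus an ordinary least-squares fit of
#' \eqn{\delta^{15}}N on \eqn{\delta^{13}}C, the standard summary of the
#' marine-terrestrial mixing continuum in consumers. Returns a fitted
#' object carrying the underlying [stats::lm] fit; [generics::tidy()] and
#' [generics::glance()] methods give coefficient- and fit-level summaries,
#' and [regression_band()] the pointwise 95% confidence band.
#'
#' @param points Data frame with `d13C` and `d15N` columns (n >= 3).
#' @return Object of class `"iso_regression"`: list with `r`, `F`,
#'   `df1`, `df2`, `p_value`, `slope`, `intercept`, `n` and `fit` (the lm).
#' @export
correlate_and_regress <- function(points) {
  if (nrow(points) < 3) abort("correlate_and_regress needs n >= 3")
  if (stats::var(points$d13C) == 0) abort("zero variance in d13C")
  fit <- lm(d15N ~ d13C, data = points)
  sm <- summary(fit)
  structure(
    list(
      r = cor(points$d13C, points$d15N),
      F = unname(sm$fstatistic[1]),
      df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
      p_value = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                          sm$fstatistic[3], lower.tail = FALSE),
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      n = nrow(points), fit = fit
    ),
    class = "iso_regression"
  )
}

#' @export
print.iso_regression <- function(x, ...) {
  cat("Isotope regression: d15N = ",
      format(round(x$slope, 2)), " * d13C + ", format(round(x$intercept, 2)),
      "\n", sep = "")
  cat("  r = ", format(round(x$r, 3)),
      ", F(", x$df1, ", ", x$df2, ") = ", format(round(x$F, 2)),
      ", p = ", format.pval(x$p_value, digits = 3), ", n = ", x$n, "\n",
      sep = "")
  invisible(x)
}

#' @rdname correlate_and_regress
#' @param x An `iso_regression` object.
#' @param ... Unused.
#' @export
tidy.iso_regression <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname correlate_and_regress
#' @export
glance.iso_regression <- function(x, ...) {
  tibble::tibble(r = x$r, F = x$F, df1 = x$df1, df2 = x$df2,
                 p.value = x$p_value, slope = x$slope,
                 intercept = x$intercept, n = x$n)
}

#' Pointwise 95% confidence band of an isotope regression
#'
#' @param reg An `iso_regression` object.
#' @param d13C Numeric vector of abscissae at which to evaluate the band.
#' @param level Confidence level (default 0.95).
#' @return Tibble: `d13C`, `fit`, `lwr`, `upr`.
#' @export
regression_band <- function(reg, d13C, level = 0.95) {
  pr <- predict(reg$fit, newdata = data.frame(d13C = d13C),
                interval = "confidence", level = level)
  tibble::tibble(d13C = d13C, fit = pr[, "fit"],
                 lwr = pr[, "lwr"], upr = pr[, "upr"])
}

#' Residuals of reference consumers below the human regression line
#'
#' For each reference individual (e.g. corrected baboon hair values),
#' reports how far its observed \eqn{\delta^{15}}N falls below the value
#' the consumer regression predicts at its \eqn{\delta^{13}}C:
#' residual_below = predicted - observed (positive = below the line).
#'
#' @param baboons Tibble with `d13C` and `d15N` (corrected values).
#' @param reg An `iso_regression` fitted on the consumers.
#' @return Tibble of per-individual `d13C`, `d15N`, `predicted_d15N`,
#'   `residual_below`, with `min`/`max` of the residuals in the
#'   `"range"` attribute.
#' @export
baboon_offset_report <- function(baboons, reg) {
  pred <- reg$intercept + reg$slope * baboons$d13C
  out <- tibble::tibble(
    d13C = baboons$d13C, d15N = baboons$d15N,
    predicted_d15N = pred, residual_below = pred - baboons$d15N
  )
  attr(out, "range") <- c(min = min(out$residual_below),
                          max = max(out$residual_below))
  out
}
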