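#' Gelman-Rubin potential scale reduction factor
#'
#' R-hat compares between- and within-chain variance of one scalar
#' variable across m chains of n retained draws:
#' R-hat = sqrt(((n-1)/n W + B/n) / W), with W the mean within-chain
#' variance and B = n x variance of the chain means. Values near 1
#' indicate the chains are sampling the same distribution.
#'
#' @param chains n x m numeric matrix (one column per chain) or list of
#'   equal-length numeric vectors; m >= 2, n >= 4.
#' @return R-hat (scalar).
#' @examples
#' gelman_rubin(cbind(1:4, 1:4))  # B = 0 -> sqrt(3/4)
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2 || n < 4) abort("gelman_rubin needs >= 2 chains of >= 4 draws")
  W <- mean(apply(chains, 2, var))
  if (W == 0) abort("degenerate chain: zero within-chain variance")
  B <- n * var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Spectral density at frequency zero, AR-fit estimator: fit an AR(p) model
# (order by AIC) and evaluate S(0) = sigma^2 / (1 - sum(phi))^2. On iid
# chains the selected order is usually 0, giving the plain variance.
spectrum0_ar <- function(x) {
  if (var(x) == 0) return(0)
  fit <- ar(x, aic = TRUE)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence z-score
#'
#' Compares the mean of an early window (first `frac_a` of the chain) with
#' a late window (last `frac_b`), standardized by spectral-density-at-zero
#' standard errors so autocorrelation within windows is accounted for:
#' z = (mean_A - mean_B) / sqrt(S_A(0)/n_A + S_B(0)/n_B). Under
#' stationarity z is approximately standard normal.
#'
#' @param chain Numeric vector of draws for one variable.
#' @param frac_a,frac_b Window fractions (defaults 0.1 and 0.5); the
#'   windows must not overlap and each must hold >= 10 draws.
#' @return z (scalar).
#' @export
geweke_z <- function(chain, frac_a = 0.1, frac_b = 0.5) {
  n <- length(chain)
  if (frac_a + frac_b > 1) abort("geweke windows must not overlap")
  a_end <- ceiling(1 + frac_a * (n - 1))
  b_start <- floor(n - frac_b * (n - 1))
  if (a_end < 10 || (n - b_start + 1) < 10) {
    abort("each geweke window needs >= 10 draws")
  }
  a <- chain[seq_len(a_end)]
  b <- chain[seq.int(b_start, n)]
  va <- spectrum0_ar(a) / length(a)
  vb <- spectrum0_ar(b) / length(b)
  if (va + vb == 0) abort("zero-variance geweke windows")
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Convergence report for a mixing-model fit
#'
#' Computes per-variable R-hat across chains and per-variable, per-chain
#' Geweke z for every source proportion. The run passes when R-hat < 1.05
#' for all variables and at most 5% of variables per chain have |z| >
#' 1.96 (with 4 source proportions that means none may fail).
#'
#' @param fit A `simm_fit`.
#' @param rhat_threshold R-hat pass threshold (default 1.05).
#' @param z_threshold |z| threshold (default 1.96).
#' @param max_fail_frac Maximum tolerated fraction of variables per chain
#'   outside the z threshold (default 0.05).
#' @return List of class `"convergence_report"`: `rhat` (tibble variable,
#'   rhat), `geweke` (tibble variable, chain, z), `pass_rhat`,
#'   `pass_geweke`, `escalation_level` (filled by
#'   [run_until_converged()], 1 otherwise).
#' @export
convergence_report <- function(fit, rhat_threshold = 1.05,
                               z_threshold = 1.96, max_fail_frac = 0.05) {
  vars <- colnames(fit$chains[[1]])
  rhat <- tibble::tibble(
    variable = vars,
    rhat = vapply(vars, function(v) {
      gelman_rubin(lapply(fit$chains, function(ch) ch[, v]))
    }, numeric(1))
  )
  gw <- purrr::map_dfr(seq_along(fit$chains), function(ci) {
    tibble::tibble(
      variable = vars, chain = ci,
      z = vapply(vars, function(v) geweke_z(fit$chains[[ci]][, v]), numeric(1))
    )
  })
  frac_fail <- dplyr::summarise(dplyr::group_by(gw, .data$chain),
                                frac = mean(abs(.data$z) > z_threshold))
  structure(
    list(
      rhat = rhat, geweke = gw,
      pass_rhat = all(rhat$rhat < rhat_threshold),
      pass_geweke = all(frac_fail$frac <= max_fail_frac),
      escalation_level = 1L
    ),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence: R-hat ", if (x$pass_rhat) "PASS" else "FAIL",
      " (max ", format(round(max(x$rhat$rhat), 4)), "), Geweke ",
      if (x$pass_geweke) "PASS" else "FAIL",
      ", escalation level ", x$escalation_level, "\n", sep = "")
  invisible(x)
}

#' Escalate MCMC run length until convergence
#'
#' Runs the supplied fitting closure at each rung of an increasing ladder
#' of run lengths, stopping at the first rung whose fit passes both the
#' R-hat and Geweke checks. If the ladder is exhausted the last fit is
#' returned with its (failing) report — non-convergence is a reported
#' state, never silently passed.
#'
#' @param fit_fn Function taking an [mcmc_config()] and returning a
#'   `simm_fit`.
#' @param ladder Non-empty list of [mcmc_config()]s with increasing
#'   `chain_length` (e.g. [mcmc_ladder()]).
#' @return List: `fit`, `report` (with `escalation_level` set to the rung
#'   used), `converged`.
#' @export
run_until_converged <- function(fit_fn, ladder) {
  if (length(ladder) == 0) abort("ladder must be non-empty")
  lens <- vapply(ladder, function(c) c$chain_length, numeric(1))
  if (is.unsorted(lens, strictly = TRUE) && length(lens) > 1) {
    abort("ladder chain lengths must be increasing")
  }
  fit <- NULL; report <- NULL
  for (r in seq_along(ladder)) {
    fit <- fit_fn(ladder[[r]])
    report <- convergence_report(fit)
    report$escalation_level <- r
    if (report$pass_rhat && report$pass_geweke) {
      return(list(fit = fit, report = report, converged = TRUE))
    }
  }
  list(fit = fit, report = report, converged = FALSE)
}
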