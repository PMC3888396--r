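# The Raschpower planning computation: expected pattern-frequency dataset,
# Cramer-Rao bound on the variance of the group-effect estimator, and the
# normal-approximation power of the Wald test.

#' Expected response-pattern frequencies implied by a study design
#'
#' Before any data are collected, the assumed design (sample sizes, group
#' effect, item difficulties, latent variance) implies an expected frequency
#' for every one of the `2^J` response patterns in each group:
#' `N_g * P(pattern | mu_g, sigma2)` with the group means derived from the
#' zero-overall-mean constraint.  This "planning dataset" plays the role of
#' the data in the power computation.
#'
#' @param items An [item_bank()].
#' @param design A [study_design()].
#' @param quad_order Number of Gauss-Hermite nodes (default 40).
#'
#' @return A tibble with `2^(J+1)` rows and columns `group` (0/1), `pattern`
#'   (integer id, item 1 = least-significant bit), `bits` (character) and
#'   `expected_frequency`.  Frequencies in each group sum to that group's
#'   sample size.
#' @examples
#' build_planning_dataset(canonical_difficulties(5),
#'                        study_design(100, 100, gamma = 0.5))
#' @export
build_planning_dataset <- function(items, design, quad_order = 40) {
  j <- length(items)
  ids <- 0:(2^j - 1)
  bits <- pattern_bits_string(ids, j)
  p0 <- pattern_prob_vector(items, design$mu0, design$sigma2, quad_order)
  p1 <- pattern_prob_vector(items, design$mu1, design$sigma2, quad_order)
  tibble(
    group = rep(c(0L, 1L), each = 2^j),
    pattern = c(ids, ids),
    bits = c(bits, bits),
    expected_frequency = c(design$n0 * p0, design$n1 * p1)
  )
}

#' Cramer-Rao bound on the variance of the group-effect estimator
#'
#' Fits the latent regression Rasch model to the expected planning
#' frequencies by marginal maximum likelihood with the item difficulties and
#' the latent variance fixed at their planning values and the group effect
#' free, then inverts the information for the group effect at the maximiser.
#' Because the weights are the expected frequencies, the observed
#' information equals the expected Fisher information and its inverse is the
#' Cramer-Rao lower bound on the variance of an unbiased estimator of
#' \eqn{\gamma}; the maximiser itself reproduces the planning \eqn{\gamma}.
#'
#' @param planning A planning dataset from [build_planning_dataset()].
#' @param items,design The item bank and design the dataset was built from.
#' @param quad_order Number of Gauss-Hermite nodes (default 40).
#'
#' @return The variance bound (positive scalar), with the maximising group
#'   effect attached as attribute `gamma_hat`.
#' @examples
#' d <- study_design(50, 50, gamma = 0)
#' it <- canonical_difficulties(5)
#' cramer_rao_variance(build_planning_dataset(it, d), it, d)  # 0.0818
#' @export
cramer_rao_variance <- function(planning, items, design, quad_order = 40) {
  j <- length(items)
  w0 <- w1 <- numeric(2^j)
  i0 <- planning$group == 0
  w0[planning$pattern[i0] + 1L] <- planning$expected_frequency[i0]
  w1[planning$pattern[!i0] + 1L] <- planning$expected_frequency[!i0]
  fit <- fit_gamma_weights(w0, w1, design$n0, design$n1, items,
                           design$sigma2, quad_order)
  if (!fit$converged) {
    abort(sprintf(paste0("planning fit did not converge (gamma_hat = %.6f, ",
                         "information = %.3e)"), fit$gamma_hat, fit$info))
  }
  if (abs(fit$gamma_hat - design$gamma) > 1e-6) {
    abort(sprintf(paste0("planning fit maximiser %.8f differs from the ",
                         "planning gamma %.8f"), fit$gamma_hat, design$gamma))
  }
  structure(fit$var_hat, gamma_hat = fit$gamma_hat)
}

#' Power of the Wald test from a variance bound
#'
#' Normal-approximation power of the two-sided Wald test of the group effect
#' at level `alpha`, using the Cramer-Rao variance bound as the variance of
#' the estimator:
#' \deqn{1 - \beta = \Phi\!\left(\gamma/\sqrt{v} - z_{1-\alpha/2}\right),}
#' for \eqn{\gamma \ge 0}.  The lower rejection region is omitted, so at
#' \eqn{\gamma = 0} the value is \eqn{\alpha/2}.
#'
#' @param gamma Group effect (assumed nonnegative).
#' @param var_cr Variance (bound) of the group-effect estimator.
#' @param alpha Two-sided significance level.
#'
#' @return The predicted power, a probability.
#' @examples
#' power_cr(0.5, 0.0411)  # about 0.694
#' @export
power_cr <- function(gamma, var_cr, alpha = 0.05) {
  if (var_cr <= 0 || !is.finite(var_cr)) abort("`var_cr` must be a positive real")
  if (gamma < 0) abort("`gamma` must be nonnegative; code the groups so the effect is positive")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  pnorm(gamma / sqrt(var_cr) - qnorm(1 - alpha / 2))
}

#' A priori power of the two-group latent-trait comparison (Raschpower)
#'
#' The full planning pipeline: build the expected pattern-frequency dataset
#' for the design, obtain the Cramer-Rao bound on the variance of the
#' group-effect estimator by marginal maximum likelihood, and convert it to
#' the predicted power of the Wald test via [power_cr()].
#'
#' @inheritParams build_planning_dataset
#'
#' @return An object of class `raschpower`: a list with elements `var_cr`,
#'   `se_cr`, `power`, `alpha`, `gamma_hat`, `design`, `items`,
#'   `quad_order`.  Supports `print()`, [tidy()] and [glance()].
#' @examples
#' raschpower(canonical_difficulties(5), study_design(100, 100, gamma = 0.5))
#' @export
raschpower <- function(items, design, quad_order = 40) {
  planning <- build_planning_dataset(items, design, quad_order)
  v <- cramer_rao_variance(planning, items, design, quad_order)
  structure(
    list(var_cr = as.numeric(v), se_cr = sqrt(as.numeric(v)),
         power = power_cr(abs(design$gamma), as.numeric(v), design$alpha),
         alpha = design$alpha, gamma_hat = attr(v, "gamma_hat"),
         design = design, items = items, quad_order = quad_order),
    class = "raschpower"
  )
}

#' @export
print.raschpower <- function(x, ...) {
  d <- x$design
  cat("Raschpower a priori power analysis\n")
  cat(sprintf("  design: n0 = %d, n1 = %d, J = %d items, gamma = %g, sigma2 = %g\n",
              d$n0, d$n1, length(x$items), d$gamma, d$sigma2))
  cat(sprintf("  Cramer-Rao variance of the group effect: %.4f (SE %.4f)\n",
              x$var_cr, x$se_cr))
  cat(sprintf("  power of the two-sided Wald test at alpha = %g: %.1f%%\n",
              x$alpha, 100 * x$power))
  invisible(x)
}

#' @rdname raschpower
#' @param x A `raschpower` object.
#' @param ... Unused.
#' @method tidy raschpower
#' @export
tidy.raschpower <- function(x, ...) {
  d <- x$design
  tibble(n0 = d$n0, n1 = d$n1, j = length(x$items), gamma = d$gamma,
         sigma2 = d$sigma2, alpha = x$alpha,
         var_cr = x$var_cr, se_cr = x$se_cr, power = x$power)
}

#' @rdname raschpower
#' @method glance raschpower
#' @export
glance.raschpower <- function(x, ...) {
  tibble(var_cr = x$var_cr, power = x$power, quad_order = x$quad_order)
}

#' Predicted power over a range of sample sizes
#'
#' Convenience wrapper running [raschpower()] for several per-group sample
#' sizes at a fixed effect, variance and item bank; the result feeds a
#' power-versus-sample-size curve.
#'
#' @param items An [item_bank()].
#' @param ng Vector of per-group sample sizes (`n0 = n1 = ng`).
#' @param gamma,sigma2,alpha Design parameters as in [study_design()].
#' @param quad_order Number of Gauss-Hermite nodes.
#'
#' @return A tibble with columns `ng`, `var_cr`, `power`.
#' @export
raschpower_curve <- function(items, ng, gamma, sigma2 = 1, alpha = 0.05,
                             quad_order = 40) {
  purrr::map_dfr(ng, function(n) {
    rp <- raschpower(items, study_design(n, n, gamma, sigma2, alpha), quad_order)
    tibble(ng = n, var_cr = rp$var_cr, power = rp$power)
  })
}

#' Smallest per-group sample size reaching a target power
#'
#' Simple search convenience: doubles the per-group sample size until the
#' predicted power reaches the target, then bisects on integers.
#'
#' @param items An [item_bank()].
#' @param gamma Expected group effect (> 0).
#' @param target_power Target power in (0, 1), default 0.8.
#' @param sigma2,alpha As in [study_design()].
#' @param quad_order Number of Gauss-Hermite nodes.
#'
#' @return The smallest `ng` with predicted power at or above the target.
#' @export
required_sample_size <- function(items, gamma, target_power = 0.8,
                                 sigma2 = 1, alpha = 0.05, quad_order = 40) {
  if (gamma <= 0) abort("`gamma` must be positive to reach a power target")
  pw <- function(n) raschpower(items, study_design(n, n, gamma, sigma2, alpha),
                               quad_order)$power
  hi <- 8L
  while (pw(hi) < target_power && hi < 2^20) hi <- hi * 2L
  lo <- max(2L, hi %/% 2L)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}
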