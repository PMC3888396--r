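# Marginal Rasch-model machinery: item response function, response-pattern
# probabilities integrated over a normal latent trait by Gauss-Hermite
# quadrature, and the weighted marginal log-likelihood used by both the
# planning computation and the estimation on simulated data.

# cache of Gauss-Hermite rules and pattern matrices, keyed by order / J
.rp_cache <- new.env(parent = emptyenv())

# nodes/weights for integrals against the standard normal density:
# int f(t) phi(t) dt = sum w_k f(sqrt(2) x_k) with w_k = w^GH_k / sqrt(pi)
gh_rule <- function(order) {
  if (order < 2) abort("quadrature order must be at least 2")
  key <- paste0("gh", order)
  if (is.null(.rp_cache[[key]])) {
    gh <- pracma::gaussHermite(order)
    .rp_cache[[key]] <- list(x = gh$x, w = gh$w / sqrt(pi))
  }
  .rp_cache[[key]]
}

# 2^J x J binary matrix; pattern k (0-based row k+1) has item j as bit j-1,
# i.e. item 1 is the least-significant bit of the pattern integer
pattern_matrix <- function(j) {
  if (j > 20) {
    abort(sprintf("J = %d items would enumerate 2^%d response patterns; J <= 20 is required", j, j))
  }
  key <- paste0("pm", j)
  if (is.null(.rp_cache[[key]])) {
    k <- 0:(2^j - 1)
    m <- vapply(seq_len(j), function(b) bitwAnd(k, bitwShiftL(1L, b - 1L)) > 0L,
                integer(2^j))
    .rp_cache[[key]] <- matrix(as.numeric(m), nrow = 2^j, ncol = j)
  }
  .rp_cache[[key]]
}

pattern_bits_string <- function(pattern, j) {
  pm <- pattern_matrix(j)
  apply(pm[pattern + 1L, , drop = FALSE], 1L, paste0, collapse = "")
}

#' Rasch item response function
#'
#' Probability of a positive response to an item of difficulty `delta` for a
#' subject with latent-trait value `theta`:
#' \eqn{P(X = 1 \mid \theta, \delta) = e^{\theta-\delta}/(1+e^{\theta-\delta})}.
#' Evaluated through `plogis()`, which is numerically stable far into the
#' tails (|theta - delta| up to several hundred).
#'
#' @param theta Latent-trait value(s).
#' @param delta Item difficulty(ies); recycled against `theta`.
#'
#' @return Probability in (0, 1), vectorised.
#' @examples
#' item_response_probability(0, 0)         # 0.5
#' item_response_probability(1, -0.5)
#' @export
item_response_probability <- function(theta, delta) {
  if (!all(is.finite(theta)) || !all(is.finite(delta))) {
    abort("`theta` and `delta` must be finite")
  }
  plogis(theta - delta)
}

# core: vector of marginal probabilities of all 2^J patterns for one group,
# Theta ~ N(mu, sigma2).  Change of variables theta = mu + sqrt(2 sigma2) x.
# Per-item log-probabilities are combined in log space so that patterns at
# extreme nodes do not underflow item-by-item.
pattern_prob_vector <- function(delta, mu, sigma2, quad_order = 40) {
  if (sigma2 <= 0 || !is.finite(sigma2)) abort("`sigma2` must be a positive real")
  gh <- gh_rule(quad_order)
  pm <- pattern_matrix(length(delta))
  theta <- mu + sqrt(2 * sigma2) * gh$x
  eta <- outer(theta, as.numeric(delta), "-")
  logp <- -log1p(exp(-eta))           # log P(X=1 | theta)
  logq <- -log1p(exp(eta))            # log P(X=0 | theta)
  lognode <- tcrossprod(logp, pm) + tcrossprod(logq, 1 - pm)  # nodes x patterns
  as.vector(crossprod(exp(lognode), gh$w))
}

#' Marginal probability of one response pattern
#'
#' Probability of observing a full response pattern under the Rasch model
#' with the latent trait integrated out over \eqn{N(\mu, \sigma^2)}:
#' \deqn{P(x) = \int \prod_j P(x_j \mid \theta, \delta_j)\,
#'   \phi(\theta; \mu, \sigma^2)\, d\theta,}
#' evaluated by fixed Gauss-Hermite quadrature.
#'
#' @param pattern Binary vector of length `J` (responses in item order), or a
#'   single pattern integer in `0:(2^J - 1)` with item 1 as the
#'   least-significant bit.
#' @param items An [item_bank()] (or numeric difficulty vector).
#' @param mu Latent-trait mean of the group.
#' @param sigma2 Latent-trait variance.
#' @param quad_order Number of quadrature nodes (default 40).
#'
#' @return A probability in (0, 1).
#' @examples
#' pattern_probability(c(1, 1, 0, 0, 0), canonical_difficulties(5), 0, 1)
#' @export
pattern_probability <- function(pattern, items, mu, sigma2, quad_order = 40) {
  j <- length(items)
  if (length(pattern) == j && all(pattern %in% c(0, 1))) {
    id <- sum(pattern * 2^(seq_len(j) - 1))
  } else if (length(pattern) == 1L && pattern >= 0 && pattern < 2^j) {
    id <- as.integer(pattern)
  } else {
    abort("`pattern` must be a binary vector of length J or a pattern integer")
  }
  pattern_prob_vector(items, mu, sigma2, quad_order)[id + 1L]
}

#' Marginal probabilities of all 2^J response patterns
#'
#' Enumerates every possible response pattern of a `J`-item dichotomous
#' questionnaire and computes its marginal probability for a group with
#' latent trait \eqn{N(\mu, \sigma^2)}.  The probabilities sum to one.
#' Pattern integers encode item 1 as the least-significant bit; the `bits`
#' column lists responses to items 1..J left to right.
#'
#' @inheritParams pattern_probability
#'
#' @return A tibble with columns `pattern` (integer id), `bits` (character)
#'   and `probability`, one row per pattern.
#' @examples
#' pattern_probabilities(item_bank(0), mu = 0, sigma2 = 1)
#' @export
pattern_probabilities <- function(items, mu, sigma2, quad_order = 40) {
  j <- length(items)
  p <- pattern_prob_vector(items, mu, sigma2, quad_order)
  tibble(
    pattern = 0:(2^j - 1),
    bits = pattern_bits_string(0:(2^j - 1), j),
    probability = p
  )
}

# weighted marginal log-likelihood in gamma given per-group weight vectors
# over all 2^J patterns; group means recomputed from gamma each call
weighted_loglik <- function(gamma, w0, w1, n0, n1, delta, sigma2, quad_order) {
  mus <- group_means(gamma, n0, n1)
  p0 <- pattern_prob_vector(delta, mus[["mu0"]], sigma2, quad_order)
  p1 <- pattern_prob_vector(delta, mus[["mu1"]], sigma2, quad_order)
  bad <- (w0 > 0 & p0 <= 0) | (w1 > 0 & p1 <= 0)
  if (any(bad)) {
    warn("a pattern with positive weight has zero marginal probability; log-likelihood is -Inf")
    return(-Inf)
  }
  sum(w0[w0 > 0] * log(p0[w0 > 0])) + sum(w1[w1 > 0] * log(p1[w1 > 0]))
}

#' Marginal log-likelihood of weighted pattern data
#'
#' Log-likelihood of the latent regression Rasch model for data summarised
#' as (possibly fractional) weights on response patterns per group, with the
#' item difficulties and the latent variance held at their assumed values
#' and the group means recomputed from `gamma` under the zero-overall-mean
#' constraint.  This is the objective maximised both by the planning
#' computation (on expected frequencies) and by the estimation on simulated
#' data (on observed counts).
#'
#' @param data A data frame with columns `group` (0/1), `pattern` (integer
#'   pattern id) and `weight` (nonnegative), e.g. a planning dataset from
#'   [build_planning_dataset()] with `expected_frequency` renamed, or
#'   collapsed counts.  A column named `expected_frequency` or `count` is
#'   accepted in place of `weight`.
#' @param items An [item_bank()].
#' @param design A [study_design()]; supplies `n0`, `n1`, `sigma2`.
#' @param gamma Group effect at which to evaluate the log-likelihood
#'   (defaults to the design value).
#' @param quad_order Number of Gauss-Hermite nodes.
#'
#' @return The scalar log-likelihood (`-Inf`, with a warning, if a weighted
#'   pattern has zero probability).
#' @export
marginal_loglik <- function(data, items, design, gamma = design$gamma,
                            quad_order = 40) {
  wcol <- intersect(c("weight", "expected_frequency", "count"), names(data))
  if (length(wcol) == 0) abort("`data` needs a weight/expected_frequency/count column")
  w <- data[[wcol[1]]]
  if (any(w < 0)) abort("pattern weights must be nonnegative")
  if (all(w == 0)) abort("pattern weights must not all be zero")
  j <- length(items)
  w0 <- w1 <- numeric(2^j)
  i0 <- data$group == 0
  # accumulate duplicated pattern rows
  a0 <- rowsum(w[i0], data$pattern[i0])
  a1 <- rowsum(w[!i0], data$pattern[!i0])
  w0[as.integer(rownames(a0)) + 1L] <- a0
  w1[as.integer(rownames(a1)) + 1L] <- a1
  weighted_loglik(gamma, w0, w1, design$n0, design$n1, items, design$sigma2,
                  quad_order)
}

# maximise the weighted marginal log-likelihood over gamma alone and invert
# the observed information (central finite difference of the log-likelihood).
# On expected-frequency data the observed information equals the expected
# Fisher information, so 1/info is the Cramer-Rao bound.
fit_gamma_weights <- function(w0, w1, n0, n1, delta, sigma2,
                              quad_order = 40, interval = c(-10, 10),
                              h = 1e-4, tol = 1e-10) {
  ll <- function(g) weighted_loglik(g, w0, w1, n0, n1, delta, sigma2, quad_order)
  opt <- suppressWarnings(optimize(ll, interval, maximum = TRUE, tol = tol))
  ghat <- opt$maximum
  at_boundary <- min(ghat - interval[1], interval[2] - ghat) < 1e-3
  info <- -(ll(ghat + h) - 2 * opt$objective + ll(ghat - h)) / h^2
  converged <- is.finite(opt$objective) && !at_boundary &&
    is.finite(info) && info > 0
  list(gamma_hat = ghat,
       var_hat = if (converged) 1 / info else NA_real_,
       loglik = opt$objective, info = info, converged = converged)
}
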