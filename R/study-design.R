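#' Group means under the zero-mean identifiability constraint
#'
#' The latent regression Rasch model compares the latent-trait means of two
#' independent groups through the group effect \eqn{\gamma = \mu_1 - \mu_0}.
#' The model is identified by fixing the overall latent mean to zero, where
#' the overall mean weights \eqn{\mu_0} and \eqn{\mu_1} by the group sample
#' sizes.  Solving the two linear constraints gives
#' \eqn{\mu_0 = -n_1\gamma/(n_0+n_1)} and \eqn{\mu_1 = n_0\gamma/(n_0+n_1)}.
#'
#' @param gamma Group effect (difference in latent means, latent-trait units).
#' @param n0,n1 Group sample sizes (positive counts).
#'
#' @return Named numeric vector `c(mu0 = , mu1 = )`.
#' @examples
#' group_means(0.5, 100, 100)  # symmetric split: -0.25, 0.25
#' group_means(0.8, 100, 300)
#' @export
group_means <- function(gamma, n0, n1) {
  if (!is.finite(gamma)) abort("`gamma` must be finite")
  if (n0 < 1 || n1 < 1) abort("both groups need at least one subject")
  n <- n0 + n1
  c(mu0 = -n1 * gamma / n, mu1 = n0 * gamma / n)
}

#' Study design for a two-group latent-trait comparison
#'
#' Bundles the planning parameters of a cross-sectional two-group study of a
#' latent trait measured by a dichotomous Rasch questionnaire: the group
#' sample sizes, the expected group effect, the common latent-trait
#' variance and the significance level.  The group means `mu0`, `mu1` are
#' derived from the zero-overall-mean identifiability constraint via
#' [group_means()].
#'
#' @param n0,n1 Expected sample size in each group.
#' @param gamma Expected group effect \eqn{\gamma} (latent-trait units).
#' @param sigma2 Latent-trait variance \eqn{\sigma^2}, assumed equal in both
#'   groups.  Default 1.
#' @param alpha Two-sided significance level of the Wald test.  Default 0.05.
#'
#' @return An object of class `study_design`: a list with fields `n0`, `n1`,
#'   `gamma`, `sigma2`, `alpha`, `mu0`, `mu1`.
#' @examples
#' study_design(n0 = 100, n1 = 100, gamma = 0.5)
#' @export
study_design <- function(n0, n1, gamma, sigma2 = 1, alpha = 0.05) {
  if (sigma2 <= 0 || !is.finite(sigma2)) abort("`sigma2` must be a positive real")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  mus <- group_means(gamma, n0, n1)
  structure(
    list(n0 = n0, n1 = n1, gamma = gamma, sigma2 = sigma2, alpha = alpha,
         mu0 = unname(mus["mu0"]), mu1 = unname(mus["mu1"])),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> two-group latent-trait comparison\n")
  cat(sprintf("  n0 = %d, n1 = %d, gamma = %g, sigma2 = %g, alpha = %g\n",
              x$n0, x$n1, x$gamma, x$sigma2, x$alpha))
  cat(sprintf("  group means (overall mean 0): mu0 = %g, mu1 = %g\n",
              x$mu0, x$mu1))
  invisible(x)
}
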