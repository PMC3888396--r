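---
title: "Power determination for two-group Rasch comparisons: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power determination for two-group Rasch comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschpower)
```

## The problem

Patient-reported outcomes are measured through questionnaires of
dichotomous items and modelled as a latent trait: an unobservable
subject-level variable $\theta$ that drives the item responses. When two
independent groups (say, treatment arms) are to be compared on such an
outcome and the analysis model is the Rasch model, the classical
two-sample normal power formula is too optimistic — the latent endpoint is
estimated through a measurement model, which inflates the variance of the
group-difference estimator. This package computes the power of that
comparison directly from the measurement model, before any data exist, and
provides the simulation machinery to audit the computation.

## Model

The Rasch model for subject $i$ and item $j$ with difficulty $\delta_j$ is

$$P(X_{ij} = 1 \mid \theta_i, \delta_j)
  = \frac{e^{\theta_i - \delta_j}}{1 + e^{\theta_i - \delta_j}},$$

with the usual assumptions of unidimensionality, monotonicity and local
independence. The latent regression variant adds a binary group covariate:
group $g$ has latent law $N(\mu_g, \sigma^2)$, the group effect is
$\gamma = \mu_1 - \mu_0$, and the variance is common to both groups.
Identifiability requires a location constraint; we fix the *weighted
overall latent mean* to zero,
$(N_0\mu_0 + N_1\mu_1)/(N_0 + N_1) = 0$, giving
$\mu_0 = -N_1\gamma/(N_0+N_1)$ and $\mu_1 = N_0\gamma/(N_0+N_1)$
(`group_means()`). The alternative constraint — centring the difficulties —
is not implemented; all fits in the package recompute $(\mu_0, \mu_1)$ from
$\gamma$ under the zero-mean form, so the one free structural parameter is
$\gamma$ itself.

Estimation is by marginal maximum likelihood: the latent trait is
integrated out over its assumed normal law, so a subject contributes the
marginal probability of their full response pattern. For $J$ dichotomous
items there are $2^J$ patterns; the package enumerates them (guarded at
$J \le 20$) and works with per-group pattern weights throughout, which
makes likelihood evaluation cost independent of the number of subjects.

## The planning computation

At the planning stage the "data" are the *expected* pattern frequencies
implied by the assumed design: $N_g \cdot P(\text{pattern} \mid \mu_g,
\sigma^2)$ for each group and pattern (`build_planning_dataset()`). The
latent regression model is then fitted to these fractional frequencies
with $\delta$ and $\sigma^2$ held at their planning values and $\gamma$
free. On expected data the maximiser reproduces the planning $\gamma$ (the
package verifies this to $10^{-6}$ and aborts otherwise) and the observed
information at the maximum equals the expected Fisher information, so its
inverse is the Cramér–Rao lower bound $\mathrm{var}_{CR}$ on the variance
of an unbiased estimator of $\gamma$ (`cramer_rao_variance()`). The
predicted power of the two-sided Wald test is

$$1 - \beta \;=\; \Phi\!\left(\frac{\gamma}{\sqrt{\mathrm{var}_{CR}}}
   - z_{1-\alpha/2}\right),$$

taken literally for $\gamma \ge 0$: the lower rejection region is omitted,
so the null design $\gamma = 0$ returns $\alpha/2$, not $\alpha$
(`power_cr()`). Whether to fit $\gamma$ alone or jointly with
$(\delta, \sigma^2)$ on the planning dataset was a genuinely open design
choice; we verified numerically that at these designs the two give the
same $\gamma$-information (the cross-information vanishes on expected
data), and fit $\gamma$ alone — it is faster and keeps the planning fit
identical to the simulation-side fit.

```{r example}
items <- canonical_difficulties(5)
raschpower(items, study_design(n0 = 100, n1 = 100, gamma = 0.5))
```

## Numerical choices

* **Quadrature.** Marginal pattern probabilities use fixed (non-adaptive)
  Gauss–Hermite quadrature with the change of variables
  $\theta = \mu + \sqrt{2\sigma^2}\,x$, default order 40. At the working
  variance $\sigma^2 = 1$ and $|\mu| \le 3$ the rule is fully converged:
  orders 30 and 60 agree to below $10^{-9}$ per pattern, and order 40
  matches a dense-trapezoid oracle ($10^5$ points over $\pm 10\sigma$) to
  $10^{-8}$. Convergence degrades for much wider latent distributions
  (at $\sigma^2 = 4$, $J = 10$ the 30-vs-60 difference grows to about
  $10^{-5}$); users planning designs with $\sigma^2 \gg 1$ should raise
  `quad_order`. Adaptive quadrature was deliberately avoided: it adds
  complexity without accuracy benefit at these designs, and a fixed rule
  makes the likelihood a smooth deterministic function of $\gamma$.
* **Log-space products.** Per-item log-probabilities are accumulated in
  log space (`log1p` forms) before exponentiation, so patterns evaluated
  at extreme quadrature nodes do not underflow item by item.
* **Optimisation.** The marginal log-likelihood is concave in the single
  parameter $\gamma$; we use golden-section/parabolic search
  (`stats::optimize`) on $[-10, 10]$ with tolerance $10^{-10}$.
* **Information.** The information for $\gamma$ is the negative central
  second difference of the log-likelihood at the maximiser with step
  $h = 10^{-4}$; a property test confirms agreement with a coarser step,
  and the planning value is invariant to reasonable step choices.
* **Degenerate fits.** A fit is flagged non-converged — never silently
  reported — when the maximiser hits the search boundary, the information
  is non-positive, or a group consists entirely of extreme (all-zero /
  all-one) patterns, which carry no information about $\gamma$.
  Non-converged Monte-Carlo replications are dropped and counted, and a
  scenario fails outright if more than 1% drop, since silent drops would
  bias rejection rates. In practice no drops occur at the study designs.
* **Pattern encoding.** Patterns are integers $0 \dots 2^J - 1$ with item
  1 as the least-significant bit; the `bits` column spells out items
  1..J left to right. The encoding is arbitrary but fixed, and file
  exports use the bit string.

## The simulator and what it does (not) emulate

`simulate_dataset()` draws each group's latent traits and generates
responses as independent Bernoulli draws given the trait. Beyond the
normal law, the latent trait can follow a **standardised beta**
distribution: a raw $\mathrm{Beta}(\omega, \tau)$ draw is centred and
scaled by its own moments, then mapped to the target mean and variance.
Three canonical shapes probe distinct violations of normality: U-shaped
$\mathrm{Beta}(0.4, 0.4)$ (respondents cluster at both extremes), L-shaped
$\mathrm{Beta}(1, 4)$ (mostly negative responders) and J-shaped
$\mathrm{Beta}(4, 1)$ (mostly positive responders). The standardisation is
affine, so the target mean and variance are exact in distribution, the
density silhouette is preserved, and the group effect enters purely as a
location shift — both groups share the shape and scale, matching the
equal-variance assumption of the analysis model. How a non-normal trait
should be anchored to the design moments is a modelling choice; a
within-group affine standardisation is the only transform that preserves
the shape while honouring the mean and variance constraints, and it is the
canonical choice here.

The study conditions are a factorial grid (`scenario_grid()`):
$N_g \in \{50, 100, 200, 300, 500\}$ per group, $J \in \{5, 10\}$ with
difficulty sets at regular normal percentiles
(`canonical_difficulties()`), $\gamma \in \{0, 0.2, 0.5, 0.8\}$,
$\sigma^2 = 1$, and the three beta shapes — 120 scenarios, replicated 1000
times each in full runs. The difficulty sets are deliberately *overlaid*
with the latent-trait distribution: the questionnaire is neither too easy
nor too hard, precision is roughly constant over the trait's range, and
floor/ceiling effects are absent. Passing simulations therefore show
robustness to the trait's *shape* under a well-targeted instrument; they
do not speak to mistargeted instruments, differential item functioning,
multidimensional traits, informative missingness, or misspecified
$\sigma^2$, none of which are modelled.

Reproducibility: every scenario takes a master seed that spawns one child
seed per replication through a single `sample.int()` call, so replications
are individually reproducible and grid results are identical whatever the
execution order; `run_grid()` additionally derives per-scenario seeds from
the grid master seed by scenario id and can checkpoint/resume.

## Problem sizes in the shipped checks

The package's own test suite exercises full 1000-replication scenarios at
$N_g = 500$ for the three headline Monte-Carlo summaries (a J = 5
type-I-error cell, a J = 10 effect-recovery cell, a J = 5 variance cell)
and reduced replication counts (15–300) elsewhere; a J = 5, $N_g = 500$
scenario at 1000 replications takes a few seconds on one core, a J = 10
one under a minute. Confidence intervals for rejection rates are exact
Clopper–Pearson intervals, which reproduce published-style brackets where
Wald intervals do not; rates are reported to 3 decimals, variances to 4,
powers to 3 in the formatted tables.

## Known limitations

* Dichotomous items only; no partial-credit/rating-scale models, no
  discrimination parameters, no conditional maximum likelihood.
* The planning fit fixes $\delta$ and $\sigma^2$; uncertainty in those
  inputs is not propagated.
* One independent reference implementation of this planning computation
  exists in the Stata ecosystem; for long questionnaires at small samples
  its published variance values differ from ours in the third decimal,
  consistent with coarser numerical integration there, while our values
  agree with the converged quadrature limit and with the simulation-based
  variance estimates this package computes.
* The power formula is the one-sided normal approximation above; for
  designs with tiny information it understates the contribution of the
  opposite rejection tail.
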