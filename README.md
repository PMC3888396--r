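# raschpower

Power analysis for comparing a latent trait between two independent groups
when the data are item responses analysed with a Rasch model.

Patient-reported outcomes (quality of life, anxiety, fatigue, pain) are
measured through questionnaires of dichotomous items, not observed directly.
Studies comparing such outcomes between two groups are routinely analysed
with item response theory, where the classical two-sample power formula
understates the required sample size: the endpoint is a *latent* variable,
and estimating it through a model adds uncertainty. This package implements
the Raschpower method for a priori power determination under the
dichotomous Rasch model, together with a seeded Monte-Carlo harness for
checking the method's operating characteristics — including when the
normality assumption on the latent trait is violated.

## The model and the method

For subject *i* with latent trait θᵢ and item *j* with difficulty δⱼ, the
Rasch model is

P(Xᵢⱼ = 1 | θᵢ, δⱼ) = exp(θᵢ − δⱼ) / (1 + exp(θᵢ − δⱼ)).

The latent regression variant gives the two groups latent means μ₀ and μ₁
with common variance σ², group effect γ = μ₁ − μ₀, identified by fixing the
sample-size-weighted overall mean to zero:
μ₀ = −N₁γ/(N₀+N₁), μ₁ = N₀γ/(N₀+N₁).

At the planning stage no responses exist, but the assumed design
(N₀, N₁, γ, σ², δ) implies an expected frequency N_g · P(pattern | μ_g, σ²)
for each of the 2ᴶ response patterns in each group, with the pattern
probabilities obtained by integrating the Rasch likelihood over the normal
latent trait (Gauss–Hermite quadrature). Fitting the latent regression
Rasch model to this expected dataset by marginal maximum likelihood — γ
free, δ and σ² fixed — and inverting the Fisher information at the maximum
yields the Cramér–Rao bound var_CR on the variance of the group-effect
estimator. The predicted power of the two-sided Wald test at level α is

1 − β = Φ( γ / √var_CR − z₁₋α/₂ ).

The Monte-Carlo side simulates subject-level data with latent traits drawn
from a normal distribution or from standardised beta distributions
(U-shaped Beta(0.4, 0.4), L-shaped Beta(1, 4), J-shaped Beta(4, 1), each
rescaled to the design mean and variance), estimates γ with the same
normal-assumption model, and compares empirical rejection rates, effect
estimates and variances with the planning predictions.

## Worked example

```r
library(raschpower)

items  <- canonical_difficulties(5)          # (-0.97, -0.43, 0, 0.44, 0.98)
design <- study_design(n0 = 100, n1 = 100, gamma = 0.5, sigma2 = 1)
raschpower(items, design)
#> Raschpower a priori power analysis
#>   design: n0 = 100, n1 = 100, J = 5 items, gamma = 0.5, sigma2 = 1
#>   Cramer-Rao variance of the group effect: 0.0411 (SE 0.2027)
#>   power of the two-sided Wald test at alpha = 0.05: 69.4%
```

A study of 100 subjects per group answering this 5-item questionnaire has
69.4% power to detect a half-standard-deviation group difference; with the
10-item bank (`canonical_difficulties(10)`) the same design reaches 81.2%.
Checking the prediction by simulation under a non-normal (L-shaped) latent
trait:

```r
run_scenario(items, study_design(500, 500, gamma = 0),
             latent_distribution("beta", shape = "L"),
             reps = 1000, seed = 101) |>
  dplyr::select(rejection_rate, ci_lower, ci_upper, var_s, var_cr)
#> # A tibble: 1 × 5
#>   rejection_rate ci_lower ci_upper   var_s  var_cr
#>            <dbl>    <dbl>    <dbl>   <dbl>   <dbl>
#> 1          0.047   0.0347   0.0620 0.00818 0.00818
```

The empirical type-I error stays at the nominal 5% and the mean simulated
variance of the estimator matches the planning bound, although the trait
is far from normal. `scenario_grid()` enumerates the full 120-scenario
robustness study (`run_grid()` executes it, with checkpointing),
`make_tables()` shapes the results into report tables, and
`autoplot()` draws power against sample size. A thin command-line wrapper
ships in `inst/cli/raschpower` (subcommands `plan` and `simulate`).

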