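Package: raschpower
Title: Power Analysis for Two-Group Latent Trait Comparisons Under the
    Rasch Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A priori power determination for the comparison of a latent
    trait (a patient-reported outcome such as quality of life) between two
    independent groups analysed with a dichotomous Rasch model.  The
    Raschpower planning computation builds the dataset of expected
    response-pattern frequencies implied by the assumed design, fits the
    latent regression Rasch model to it by marginal maximum likelihood and
    obtains the Cramer-Rao bound on the variance of the group-effect
    estimator, from which the power of the Wald test follows.  A seeded
    Monte-Carlo harness simulates subject-level data from normal or
    shape-parameterised beta latent-trait distributions to check empirical
    type-I error and power against the planning predictions, including
    under violations of the normality assumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
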