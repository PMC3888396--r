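test_that("item response function matches the logistic and stays stable in the tails", {
  expect_equal(item_response_probability(0, 0), 0.5)
  for (d in c(-2, 0, 1.3)) {
    expect_equal(item_response_probability(d, d), 0.5)
  }
  # frozen oracle value: logistic(0.97 - (-0.97)) = logistic(1.94)
  expect_equal(item_response_probability(0.97, -0.97), 0.874352,
               tolerance = 1e-6)
  expect_equal(item_response_probability(700, 0), 1, tolerance = 1e-12)
  expect_gt(item_response_probability(-700, 0), 0)
  expect_error(item_response_probability(NA, 0), "finite")
  expect_error(item_response_probability(0, Inf), "finite")
})

test_that("group means satisfy the weighted zero-mean and difference constraints", {
  expect_equal(group_means(0.5, 100, 100), c(mu0 = -0.25, mu1 = 0.25))
  expect_equal(group_means(0, 50, 500), c(mu0 = 0, mu1 = 0))
  expect_equal(group_means(0.8, 100, 300), c(mu0 = -0.6, mu1 = 0.2))
  for (case in list(c(0.37, 13, 88), c(-1.2, 500, 50))) {
    m <- group_means(case[1], case[2], case[3])
    expect_equal((case[2] * m[["mu0"]] + case[3] * m[["mu1"]]) / sum(case[2:3]),
                 0, tolerance = 1e-12)
    expect_equal(m[["mu1"]] - m[["mu0"]], case[1], tolerance = 1e-12)
  }
  expect_error(group_means(0.5, 0, 10), "at least one")
})

test_that("single-item pattern probability is exact by symmetry and limits", {
  expect_equal(pattern_probability(1, item_bank(0), 0, 1), 0.5,
               tolerance = 1e-10)
  # strongly positive latent mean: the all-ones pattern is certain
  expect_equal(pattern_probability(rep(1, 5), canonical_difficulties(5),
                                   mu = 50, sigma2 = 1), 1, tolerance = 1e-6)
  expect_error(pattern_probability(1, item_bank(0), 0, -1), "positive")
})

test_that("Gauss-Hermite marginal probabilities match the dense trapezoid oracle", {
  it5 <- canonical_difficulties(5)
  for (case in list(list(mu = 0, s2 = 1, pat = rep(0, 5)),
                    list(mu = -0.25, s2 = 1, pat = c(1, 0, 1, 1, 0)),
                    list(mu = 0.6, s2 = 2.5, pat = c(1, 1, 0, 0, 1)))) {
    got <- pattern_probability(case$pat, it5, case$mu, case$s2,
                               quad_order = 60)
    want <- trapezoid_pattern_prob(case$pat, d5_ref, case$mu, case$s2)
    expect_lt(abs(got - want), 1e-8)
  }
})

test_that("pattern probabilities are a proper distribution over all 2^J patterns", {
  set.seed(11)
  for (rep in 1:5) {
    j <- sample(1:6, 1)
    items <- item_bank(runif(j, -2, 2))
    mu <- runif(1, -3, 3)
    s2 <- runif(1, 0.2, 4)
    pp <- pattern_probabilities(items, mu, s2)
    expect_equal(nrow(pp), 2^j)
    expect_true(all(pp$probability > 0 & pp$probability < 1))
    expect_equal(sum(pp$probability), 1, tolerance = 1e-10)
  }
  # exchangeable items: P(01) = P(10)
  pp2 <- pattern_probabilities(item_bank(c(0, 0)), 0, 1)
  expect_equal(pp2$probability[pp2$bits == "01"],
               pp2$probability[pp2$bits == "10"], tolerance = 1e-12)
})

test_that("quadrature is converged at the working variance: order 30 agrees with order 60", {
  it10 <- canonical_difficulties(10)
  for (mu in c(-3, -0.4, 0, 2.2)) {
    p30 <- pattern_probabilities(it10, mu, 1, quad_order = 30)$probability
    p60 <- pattern_probabilities(it10, mu, 1, quad_order = 60)$probability
    expect_lt(max(abs(p30 - p60)), 1e-9)
  }
})

test_that("the all-ones pattern probability increases strictly with the latent mean", {
  it5 <- canonical_difficulties(5)
  mus <- seq(-2, 2, by = 0.5)
  p <- vapply(mus, function(m) pattern_probability(rep(1, 5), it5, m, 1),
              numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("pattern enumeration refuses exponential blow-up beyond J = 20", {
  expect_error(pattern_probabilities(item_bank(rep(0, 21)), 0, 1),
               "J <= 20")
})

test_that("the weighted marginal log-likelihood matches naive summation and peaks at the generating effect", {
  # single pattern, single item, null effect: log(1/2)
  w <- tibble::tibble(group = 0L, pattern = 1L, weight = 1)
  d <- study_design(10, 10, gamma = 0)
  expect_equal(marginal_loglik(w, item_bank(0), d, gamma = 0), log(0.5),
               tolerance = 1e-10)

  # expected planning frequencies are maximised at the generating gamma
  it5 <- canonical_difficulties(5)
  des <- study_design(100, 100, gamma = 0.2)
  plan <- build_planning_dataset(it5, des)
  plan$weight <- plan$expected_frequency
  ll <- vapply(c(0, 0.2, 0.4),
               function(g) marginal_loglik(plan, it5, des, gamma = g),
               numeric(1))
  expect_gt(ll[2], ll[1])
  expect_gt(ll[2], ll[3])

  # collapsed-weight likelihood equals subject-by-subject summation
  set.seed(5)
  des2 <- study_design(30, 40, gamma = 0.5)
  dat <- simulate_dataset(it5, des2, latent_distribution("normal"))
  x <- as.matrix(dat[paste0("item_", 1:5)])
  counts <- tibble::tibble(group = dat$group,
                           pattern = as.integer(x %*% 2^(0:4)),
                           weight = 1)
  for (g in c(0, 0.5)) {
    expect_equal(marginal_loglik(counts, it5, des2, gamma = g),
                 naive_subject_loglik(dat, d5_ref, 1, g, 30, 40),
                 tolerance = 1e-10)
  }
})

test_that("weighted patterns with zero probability flag the likelihood as -Inf", {
  # an all-ones pattern in a group whose latent mean sits 100 units below
  # the difficulties has probability below the double-precision underflow
  w <- tibble::tibble(group = 0L, pattern = 2^10 - 1, weight = 1)
  d <- study_design(10, 10, gamma = 200)
  expect_warning(
    val <- marginal_loglik(w, canonical_difficulties(10), d, gamma = 200),
    "zero marginal probability"
  )
  expect_identical(val, -Inf)
})
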