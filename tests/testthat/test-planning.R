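it5 <- canonical_difficulties(5)
it10 <- canonical_difficulties(10)

test_that("planning datasets carry normalised expected frequencies per group", {
  # single neutral item, null effect: all four group-pattern cells equal 5
  plan1 <- build_planning_dataset(item_bank(0), study_design(10, 10, gamma = 0))
  expect_equal(nrow(plan1), 4)
  expect_equal(plan1$expected_frequency, rep(5, 4), tolerance = 1e-10)

  des <- study_design(100, 100, gamma = 0.5)
  plan <- build_planning_dataset(it5, des)
  expect_equal(nrow(plan), 64)
  sums <- tapply(plan$expected_frequency, plan$group, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-8)

  # the higher-mean group endorses everything more often
  ones <- plan[plan$bits == "11111", ]
  expect_gt(ones$expected_frequency[ones$group == 1],
            ones$expected_frequency[ones$group == 0])
})

test_that("the Cramer-Rao variance reproduces reference planning values", {
  des <- study_design(50, 50, gamma = 0)
  v <- cramer_rao_variance(build_planning_dataset(it5, des), it5, des)
  expect_equal(round(as.numeric(v), 4), 0.0818)
  expect_equal(attr(v, "gamma_hat"), 0, tolerance = 1e-6)

  des2 <- study_design(100, 100, gamma = 0.5)
  v2 <- cramer_rao_variance(build_planning_dataset(it5, des2), it5, des2)
  expect_equal(round(as.numeric(v2), 4), 0.0411)
  expect_equal(attr(v2, "gamma_hat"), 0.5, tolerance = 1e-6)
})

test_that("information adds over independent subjects: doubling N halves the variance", {
  v1 <- raschpower(it5, study_design(80, 120, gamma = 0.3))$var_cr
  v2 <- raschpower(it5, study_design(160, 240, gamma = 0.3))$var_cr
  expect_equal(v2, v1 / 2, tolerance = 1e-6)
})

test_that("the variance bound moves as theory predicts across designs", {
  ngs <- c(50, 100, 200)
  v_by_n <- vapply(ngs, function(n)
    raschpower(it5, study_design(n, n, gamma = 0))$var_cr, numeric(1))
  expect_true(all(diff(v_by_n) < 0))

  # weakly increasing in the effect size
  v_by_g <- vapply(c(0, 0.2, 0.5, 0.8), function(g)
    raschpower(it5, study_design(100, 100, gamma = g))$var_cr, numeric(1))
  expect_true(all(diff(v_by_g) >= -1e-8))

  # longer questionnaire, smaller variance
  expect_lt(raschpower(it10, study_design(100, 100, gamma = 0.5))$var_cr,
            raschpower(it5, study_design(100, 100, gamma = 0.5))$var_cr)

  # about twice the known-trait variance sigma2 * 2/Ng at J = 5
  ratio <- raschpower(it5, study_design(50, 50, gamma = 0))$var_cr / (2 / 50)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.3)
})

test_that("power formula omits the lower tail and matches reference powers", {
  expect_equal(power_cr(0, var_cr = 0.04, alpha = 0.05), pnorm(qnorm(0.025)),
               tolerance = 1e-12)
  expect_equal(round(power_cr(0.5, 0.0411), 3), 0.694)
  expect_equal(round(power_cr(0.5, 0.0310), 3), 0.811)
  expect_error(power_cr(0.5, -1), "positive")
  expect_error(power_cr(-0.1, 0.04), "nonnegative")
})

test_that("the full pipeline is internally consistent and monotone in design strength", {
  rp <- raschpower(it5, study_design(100, 100, gamma = 0.5))
  expect_s3_class(rp, "raschpower")
  expect_equal(rp$power,
               pnorm(rp$design$gamma / rp$se_cr - qnorm(1 - rp$alpha / 2)),
               tolerance = 1e-12)
  expect_equal(rp$se_cr, sqrt(rp$var_cr), tolerance = 1e-15)

  p_n <- vapply(c(50, 100, 300), function(n)
    raschpower(it5, study_design(n, n, gamma = 0.5))$power, numeric(1))
  expect_true(all(diff(p_n) > 0))
  p_g <- vapply(c(0.2, 0.5, 0.8), function(g)
    raschpower(it5, study_design(100, 100, gamma = g))$power, numeric(1))
  expect_true(all(diff(p_g) > 0))
  expect_gt(raschpower(it10, study_design(100, 100, gamma = 0.5))$power,
            raschpower(it5, study_design(100, 100, gamma = 0.5))$power)

  td <- tidy(rp)
  expect_equal(td$var_cr, rp$var_cr)
  expect_named(glance(rp), c("var_cr", "power", "quad_order"))
})

test_that("finite-difference information agrees with a coarser second difference", {
  des <- study_design(100, 100, gamma = 0.2)
  plan <- build_planning_dataset(it5, des)
  v <- as.numeric(cramer_rao_variance(plan, it5, des))
  plan$weight <- plan$expected_frequency
  h <- 1e-3
  ll <- function(g) marginal_loglik(plan, it5, des, gamma = g)
  info <- -(ll(0.2 + h) - 2 * ll(0.2) + ll(0.2 - h)) / h^2
  expect_equal(1 / info, v, tolerance = 1e-4)
})

test_that("sample-size search inverts the power curve", {
  n <- required_sample_size(it5, gamma = 0.5, target_power = 0.8)
  expect_gte(raschpower(it5, study_design(n, n, 0.5))$power, 0.8)
  expect_lt(raschpower(it5, study_design(n - 1, n - 1, 0.5))$power, 0.8)
})
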