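test_that("both weight sets give a unit-variance composite without rescaling", {
  for (set in 1:2) {
    ws <- weight_set(set)
    expect_equal(drop(t(ws$weights) %*% ws$sigma_mm %*% ws$weights), 1,
                 tolerance = 1e-12)
  }
})

test_that("the cross-covariance rule ties the composite to the predictor", {
  for (set in 1:2) {
    pop <- make_population(weight_set(set))
    # Cov(X, M) = W'(0.4 Sigma_mm W) = 0.4 since Var(M) = 1
    expect_equal(pop$rho, 0.4, tolerance = 1e-12)
    expect_equal(pop$zeta_m, 1 - 0.16, tolerance = 1e-12)
  }
})

test_that("error variances solve the unit-variance constraints", {
  pop <- make_population(weight_set(1))
  expect_equal(pop$theta_x, rep(0.51, 3))
  expect_equal(pop$theta_y, c(0.51, 0.36, 0.19))
  # Var(zeta_Y) from the product-moment identity; all nine observables and
  # the three constructs then have unit analytic variance
  am <- analytic_moments(pop)
  expect_equal(unname(diag(am$sigma)), rep(1, 9), tolerance = 1e-12)
  expect_equal(pop$zeta_y + am$r_squared[["Y"]], 1, tolerance = 1e-12)
})

test_that("the reduced form of the outcome equation is exact", {
  for (set in 1:2) {
    rf <- analytic_moments(make_population(weight_set(set)))$reduced_form
    expect_equal(unname(rf), c(0.46, 0.08, -0.08), tolerance = 1e-12)
  }
})

test_that("implied R-squared values are identical across weight sets", {
  # the structural level (rho = 0.4, identical coefficients) is shared, so
  # the derived R-squared pair is the same for both sets
  r1 <- analytic_moments(make_population(weight_set(1)))$r_squared
  r2 <- analytic_moments(make_population(weight_set(2)))$r_squared
  expect_equal(r1, r2)
  expect_equal(unname(r1), c(0.16, 0.3924), tolerance = 1e-12)
})

test_that("sampling is reproducible and matches the analytic moments", {
  pop <- make_population(weight_set(2))
  d1 <- generate_sample(pop, 200, seed = 31)
  d2 <- generate_sample(pop, 200, seed = 31)
  expect_identical(d1, d2)
  big <- generate_sample(pop, 1e6, seed = 13)
  S <- cov(as.matrix(big))
  expect_lt(max(abs(S - analytic_moments(pop)$sigma)), 0.005)
  # centering of the product term keeps the outcome mean at zero
  expect_lt(max(abs(colMeans(big))), 0.005)
  expect_error(generate_sample(pop, 0), "positive integer")
})

test_that("indicator-component covariances follow the stated chain", {
  pop <- make_population(weight_set(1))
  am <- analytic_moments(pop)
  s_mx <- 0.4 * as.numeric(pop$sigma_mm %*% pop$weights)
  for (j in 1:3)
    expect_equal(am$sigma[paste0("x", 1), paste0("m", j)], 0.7 * s_mx[j])
})

test_that("a non-PD component correlation matrix is rejected", {
  expect_error(weight_set(list(weights = c(1, 1, 1), cor = c(0.9, 0.9, -0.9))),
               "not positive definite")
})
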