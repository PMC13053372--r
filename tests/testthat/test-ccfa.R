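test_that("implied covariance reduces to identity in the degenerate case", {
  expect_equal(ccfa_implied_cov(diag(3), diag(3), rep(0, 3)), diag(3))
})

test_that("implied covariance matches a hand-computed 2x2 case", {
  # composite block with loadings [[1, .3], [.5, 1]], unit uncorrelated
  # constructs, no error terms: Sigma = Lambda Lambda'
  lam <- matrix(c(1, 0.5, 0.3, 1), 2, 2)
  sig <- ccfa_implied_cov(lam, diag(2), c(0, 0))
  expect_equal(sig, matrix(c(1.09, 0.8, 0.8, 1.25), 2, 2))
})

test_that("implied covariance rejects mismatched dimensions", {
  expect_error(ccfa_implied_cov(diag(3), diag(2), rep(0, 3)), "dimension")
  expect_error(ccfa_implied_cov(diag(3), diag(3), rep(0, 2)), "dimension")
})

test_that("population parameters reproduce the analytic observable covariance", {
  for (set in 1:2) {
    pop <- make_population(weight_set(set))
    pp <- pop_ccfa_params(pop)
    implied <- ccfa_implied_cov(pp$lambda, pp$phi, pp$theta)
    expect_equal(implied, analytic_moments(pop)$sigma, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("fitting an exactly implied covariance recovers the parameters", {
  # self-consistency at the simulation model
  pop <- make_population(weight_set(2))
  fit <- fit_ccfa(sample_cov = analytic_moments(pop)$sigma, n = 1000,
                  blocks = sim_model())
  expect_true(fit$converged)
  expect_true(fit$admissible)
  expect_lt(fit$discrepancy, 1e-10)
  pp <- pop_ccfa_params(pop)
  expect_equal(fit$block_lambda$M, pp$lambda[4:6, c("M", "nu1", "nu2")],
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(fit$phi[c("M", "X", "Y"), c("M", "X", "Y")],
               pp$phi[c("M", "X", "Y"), c("M", "X", "Y")],
               tolerance = 1e-5, ignore_attr = TRUE)
  # saturated structural part: construct covariances are unrestricted, so the
  # exact population construct covariance is reproduced
  expect_equal(fit$phi["X", "M"], 0.7 * 0.725 * 0.4, tolerance = 1e-6)
})

test_that("local identification holds for random admissible models (K = 2..4)", {
  set.seed(421)
  for (K in 2:4) {
    comp <- composite("C", paste0("c", seq_len(K)))
    blocks <- list(latent("F", c("f1", "f2", "f3")), comp)
    parm <- cmsem:::ccfa_parameterization(blocks)
    # random admissible parameter point
    repeat {
      theta0 <- numeric(parm$n_par)
      theta0[seq_len(parm$n_lam)] <- runif(parm$n_lam, 0.4, 1.1) *
        sample(c(-1, 1), parm$n_lam, replace = TRUE)
      phi <- matrix(0, parm$q, parm$q)
      phi[parm$phi_free] <- runif(parm$n_phi, 0.05, 0.2)
      phi <- phi + t(phi)
      diag(phi) <- runif(parm$q, 0.6, 1.2)
      phi_v <- phi[parm$phi_free]
      theta0[parm$n_lam + seq_len(parm$n_phi)] <- phi_v
      theta0[parm$n_lam + parm$n_phi + seq_len(parm$n_theta)] <-
        runif(parm$n_theta, 0.3, 0.7)
      m <- cmsem:::ccfa_expand(parm, theta0)
      sig <- ccfa_implied_cov(m$lambda, m$phi, m$theta)
      if (cmsem:::is_pd(sig)) break
    }
    fit <- fit_ccfa(sample_cov = sig, n = 500, blocks = blocks,
                    start = theta0)
    expect_true(fit$converged)
    expect_lt(fit$discrepancy, 1e-10)
    expect_equal(fit$par, theta0, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("large samples recover the population-covariance fit", {
  pop <- make_population(weight_set(2))
  target <- fit_ccfa(sample_cov = analytic_moments(pop)$sigma, n = 1e6,
                     blocks = sim_model())
  dat <- generate_sample(pop, 1e6, seed = 99)
  fit <- fit_ccfa(dat, sim_model())
  expect_true(fit$admissible)
  expect_lt(max(abs(fit$block_lambda$M - target$block_lambda$M)), 0.01)
  expect_lt(max(abs(fit$lambda - target$lambda)), 0.01)
})

test_that("degenerate data are refused with a diagnostic", {
  pop <- make_population(weight_set(1))
  dat <- generate_sample(pop, 100, seed = 5)
  dat$m2 <- 1   # constant column -> singular S
  expect_error(fit_ccfa(dat, sim_model()), "not positive definite")
  expect_error(fit_ccfa(dat[1:5, ], sim_model()), "more observations")
  expect_error(fit_ccfa(dat[-(1:9)], sim_model()), "missing model column")
})

test_that("the admissibility screen classifies fits correctly", {
  pop <- make_population(weight_set(1))
  dat <- generate_sample(pop, 400, seed = 17)
  fit <- fit_ccfa(dat, sim_model())
  expect_true(fit$converged)
  expect_identical(admissibility_check(fit)$reason, "admissible")

  bad <- fit
  bad$converged <- FALSE
  expect_identical(admissibility_check(bad)$reason, "no convergence")

  bad <- fit
  bad$theta[1] <- -0.05
  expect_identical(admissibility_check(bad)$reason, "negative variance")

  bad <- fit
  bad$block_lambda$M <- matrix(c(1, 2, 0.5, 1, 2, 0.5, 1, 2, 0.5), 3, 3)
  expect_identical(admissibility_check(bad)$reason, "singular loading matrix")
})
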