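test_that("the quadrature rule integrates against the standard normal", {
  r <- gh_rule(24)
  expect_equal(sum(r$weights), 1, tolerance = 1e-12)
  expect_equal(sort(r$nodes), -rev(sort(r$nodes)), tolerance = 1e-10)
  # exact for polynomial moments of N(0, 1)
  expect_equal(sum(r$weights * r$nodes^2), 1, tolerance = 1e-10)
  expect_equal(sum(r$weights * r$nodes^4), 3, tolerance = 1e-8)
  expect_error(gh_rule(nodes = c(-1, 1), weights = c(0.7, 0.7)),
               "sum to 1")
  expect_error(gh_rule(nodes = c(-1, 2), weights = c(0.5, 0.5)),
               "symmetric")
})

test_that("conditional moments are linear-Gaussian in the latent predictor", {
  pop <- make_population(weight_set(1))
  m <- pop_lms_model(pop)
  # without interaction the covariance is constant in x
  m0 <- m; m0$d <- 0
  cm1 <- conditional_moments(m0, -1.3)
  cm2 <- conditional_moments(m0, 2.1)
  expect_equal(cm1$cov, cm2$cov)
  # at x = 0 the interaction contributes nothing
  expect_equal(conditional_moments(m, 0)$mean,
               conditional_moments(m0, 0)$mean)
  expect_equal(conditional_moments(m, 0)$cov,
               conditional_moments(m0, 0)$cov)
  # hand-derived entries at general x
  x <- 0.8
  s <- m$c + m$d * x
  cm <- conditional_moments(m, x)
  expect_equal(cm$mean[["score"]], m$a * x)
  expect_equal(cm$cov["score", "y1"], s * m$zeta_m)        # lambda_y1 = 1
  expect_equal(cm$cov["y1", "y1"], s^2 * m$zeta_m + m$zeta_y + m$theta_y[1])
  expect_true(cmsem:::is_pd(cm$cov))
})

test_that("the compiled likelihood matches a plain-R mixture of Gaussians", {
  pop <- make_population(weight_set(2))
  dat <- scored_sample(pop, 60, seed = 8)
  m <- pop_lms_model(pop)
  r <- gh_rule(16)
  ll <- marginal_loglik(m, dat, r)
  lp <- sapply(seq_len(r$m), function(k) {
    cm <- conditional_moments(m, r$nodes[k])
    cmsem:::dmvnorm_log(as.matrix(dat[names(cm$mean)]), cm$mean, cm$cov) +
      log(r$weights[k])
  })
  expect_equal(ll, sum(cmsem:::log_sum_exp_rows(lp)), tolerance = 1e-10)
})

test_that("with no interaction the marginal likelihood is the closed form", {
  pop <- make_population(weight_set(1), d = 0)
  dat <- scored_sample(pop, 500, seed = 9)
  m <- pop_lms_model(pop)
  expect_equal(m$d, 0)
  ll_quad <- marginal_loglik(m, dat, gh_rule(48))
  im <- cmsem:::lms_implied_moments(m)
  ll_exact <- sum(cmsem:::dmvnorm_log(as.matrix(dat[names(im$mean)]),
                                      im$mean, im$cov))
  expect_lt(abs(ll_quad - ll_exact) / nrow(dat), 1e-8)
})

test_that("quadrature agrees with brute-force grid integration", {
  pop <- make_population(weight_set(2))
  dat <- scored_sample(pop, 1, seed = 10)
  m <- pop_lms_model(pop)       # d != 0: genuinely non-normal density
  ll <- marginal_loglik(m, dat, gh_rule(48))
  grid <- seq(-10, 10, length.out = 1e5)
  obs <- as.matrix(dat[c(paste0("x", 1:3), "score", paste0("y", 1:3))])
  lp <- vapply(grid, function(x) {
    cm <- conditional_moments(m, x)
    cmsem:::dmvnorm_log(obs, cm$mean, cm$cov)
  }, numeric(1))
  dens <- exp(lp) * stats::dnorm(grid)
  ll_grid <- log(pracma::trapz(grid, dens))
  expect_lt(abs(ll - ll_grid), 1e-6)
})

test_that("refining the rule leaves the likelihood unchanged", {
  pop <- make_population(weight_set(1))
  dat <- scored_sample(pop, 400, seed = 12)
  m <- pop_lms_model(pop)
  l32 <- marginal_loglik(m, dat, gh_rule(32))
  l64 <- marginal_loglik(m, dat, gh_rule(64))
  expect_lt(abs(l64 - l32) / nrow(dat), 1e-6)
})

test_that("large-sample estimates recover the structural truth", {
  pop <- make_population(weight_set(2))
  dat <- scored_sample(pop, 3e4, seed = 14)
  fit <- fit_lms(dat, x = paste0("x", 1:3), score = "score",
                 y = paste0("y", 1:3))
  expect_true(fit$admissible)
  expect_lt(max(abs(fit$standardized - c(0.4, 0.3, 0.4, 0.2))), 0.02)
  # raw estimates sit on the first-indicator scale of the outcome
  expect_equal(fit$model$b, 0.7 * 0.3, tolerance = 0.03)
})

test_that("node refinement does not move the estimates", {
  pop <- make_population(weight_set(1))
  dat <- scored_sample(pop, 500, seed = 15)
  f24 <- fit_lms(dat, x = paste0("x", 1:3), score = "score",
                 y = paste0("y", 1:3), nodes = 24)
  f48 <- fit_lms(dat, x = paste0("x", 1:3), score = "score",
                 y = paste0("y", 1:3), nodes = 48)
  expect_lt(max(abs(f24$par - f48$par)), 1e-4)
})

test_that("standardization is exact at the population and scale-equivariant", {
  pop <- make_population(weight_set(1))
  stub <- structure(list(model = pop_lms_model(pop), sd_score = 1),
                    class = "lms_fit")
  expect_equal(lms_standardize(stub), c(a = 0.4, b = 0.3, c = 0.4, d = 0.2),
               tolerance = 1e-12)
  # rescaling the score column leaves the standardized solution invariant
  dat <- scored_sample(pop, 500, seed = 16)
  f1 <- fit_lms(dat, x = paste0("x", 1:3), score = "score",
                y = paste0("y", 1:3))
  dat$score <- 2 * dat$score
  f2 <- fit_lms(dat, x = paste0("x", 1:3), score = "score",
                y = paste0("y", 1:3))
  expect_lt(max(abs(f1$standardized - f2$standardized)), 1e-3)
  # degenerate implied variance is an error
  broken <- stub
  broken$model$b <- broken$model$c <- broken$model$d <- 0
  broken$model$zeta_y <- 0
  expect_error(lms_standardize(broken), "variance")
})

test_that("the moderation z-test follows the normal reference", {
  stub <- structure(list(model = list(d = 0), se = c(d = 1)),
                    class = "lms_fit")
  mt <- moderation_test(stub)
  expect_equal(mt$z, 0)
  expect_equal(mt$p_value, 1)
  expect_false(mt$reject)
  stub$model$d <- stats::qnorm(0.975)
  mt <- moderation_test(stub)
  expect_equal(mt$p_value, 0.05, tolerance = 1e-10)
})

test_that("empty or incomplete data are rejected", {
  pop <- make_population(weight_set(1))
  dat <- scored_sample(pop, 50, seed = 18)
  expect_error(fit_lms(dat[0, ], x = paste0("x", 1:3), score = "score",
                       y = paste0("y", 1:3)), "empty")
  expect_error(fit_lms(dat[, -1], x = paste0("x", 1:3), score = "score",
                       y = paste0("y", 1:3)), "missing column")
})
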