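test_that("the three-step pipeline produces a complete, consistent fit", {
  pop <- make_population(weight_set(2))
  dat <- generate_sample(pop, 500, seed = 101)
  fit <- cms(dat, sim_model())
  expect_s3_class(fit, "cms")
  expect_true(fit$admissible)
  # step 2 consistency: weights are the transpose-inverse of the step-1
  # loadings, and the stored score is the centered weighted combination
  lam <- fit$ccfa$block_lambda$M
  expect_equal(fit$weights, solve(t(lam)), ignore_attr = TRUE)
  expect_equal(fit$w, first_column_weights(lam), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_lt(abs(mean(fit$score$score)), 1e-12)
  # step 3 exposes 18 parameters for the 3+1+3-variable interaction model
  expect_identical(length(fit$lms$par), 18L)
  expect_identical(length(fit$lms$standardized), 4L)

  s <- summary(fit)
  expect_s3_class(s, "summary.cms")
  expect_identical(nrow(s$table), 18L)
  expect_true(all(is.finite(s$table$se)))
  expect_equal(s$moderation$z, s$table["d", "z"])
  expect_equal(coef(fit), fit$lms$standardized)
  expect_equal(unname(coef(fit, standardized = FALSE)["d"]),
               fit$lms$model$d)
  expect_identical(dim(vcov(fit)), c(18L, 18L))
  expect_equal(as.numeric(logLik(fit)), fit$lms$logLik)
  expect_output(print(fit), "Standardized structural estimates")
  expect_output(print(s), "Moderation z-test")
})

test_that("refitting the same data reproduces identical estimates", {
  pop <- make_population(weight_set(1))
  dat <- generate_sample(pop, 300, seed = 55)
  f1 <- cms(dat, sim_model())
  f2 <- cms(dat, sim_model())
  expect_identical(f1$lms$par, f2$lms$par)
  expect_identical(f1$w, f2$w)
})

test_that("simulate() from a fit is seed-reproducible", {
  pop <- make_population(weight_set(2))
  dat <- generate_sample(pop, 400, seed = 66)
  fit <- cms(dat, sim_model())
  d1 <- simulate(fit, seed = 1, n = 100)
  d2 <- simulate(fit, seed = 1, n = 100)
  expect_identical(d1, d2)
  expect_identical(nrow(d1), 100L)
  expect_identical(ncol(d1), 7L)
})

test_that("inadmissible step-1 fits are flagged, not errors", {
  pop <- make_population(weight_set(1))
  # tiny sample: find a draw whose step-1 fit fails, confirm the pipeline
  # reports the stage and reason instead of raising
  found <- FALSE
  for (i in 1:60) {
    dat <- generate_sample(pop, 60, seed = 1000 + i)
    fit <- try(cms(dat, sim_model()), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (!fit$admissible) {
      expect_match(fit$inadmissible_reason, "step")
      expect_error(coef(fit), "inadmissible")
      found <- TRUE
      break
    }
  }
  expect_true(found)
})
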