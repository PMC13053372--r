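test_that("weights are the transpose-inverse of the loadings", {
  expect_equal(loadings_to_weights(diag(3)), diag(3))
  lam <- matrix(c(1, 0.5, 0.3, 1), 2, 2)
  W <- loadings_to_weights(lam)
  expect_equal(W, solve(t(lam)))                       # brute-force oracle
  expect_equal(t(W) %*% lam, diag(2), tolerance = 1e-10)
})

test_that("singular loadings are refused", {
  lam <- matrix(c(1, 2, 0.5, 1), 2, 2)
  lam[2, ] <- 2 * lam[1, ]                              # proportional rows
  expect_error(loadings_to_weights(lam), "singular")
  expect_error(loadings_to_weights(matrix(1, 2, 3)), "square")
})

test_that("closed-form first-column weights equal the full inverse", {
  expect_equal(first_column_weights(diag(4)), c(1, 0, 0, 0))
  set.seed(7)
  for (K in c(3L, 6L)) {
    lam <- random_banded_lambda(K)
    expect_equal(first_column_weights(lam), solve(t(lam))[, 1],
                 tolerance = 1e-12)
  }
})

test_that("closed form matches the generic inverse on many banded matrices", {
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    K <- sample(2:8, 1)
    lam <- random_banded_lambda(K)
    worst <- max(worst, max(abs(first_column_weights(lam) -
                                  solve(t(lam))[, 1])))
  }
  expect_lt(worst, 1e-10)
})

test_that("non-banded input is a contract violation", {
  lam <- diag(3); lam[3, 2] <- 0.4                      # below-band cell
  expect_error(first_column_weights(lam), "banded")
})

test_that("column-1 scaling inverts the weights and preserves the score span", {
  set.seed(11)
  lam <- random_banded_lambda(4)
  w1 <- first_column_weights(lam)
  lam2 <- lam
  lam2[, 1] <- 3 * lam2[, 1]
  # the band pattern requires a unit diagonal only in construction, not in
  # the closed form; rescaling column 1 rescales the weights by 1/3
  expect_equal(first_column_weights(lam2), w1 / 3, tolerance = 1e-12)
})

test_that("scores are centered weighted combinations of the components", {
  pop <- make_population(weight_set(1))
  dat <- generate_sample(pop, 500, seed = 3)
  blk <- composite("M", c("m1", "m2", "m3"))
  s1 <- compute_scores(dat, blk, c(1, 0, 0))
  expect_equal(s1$score, dat$m1 - mean(dat$m1))
  set.seed(4)
  w <- rnorm(3)
  s2 <- compute_scores(dat, blk, w)
  expect_lt(abs(mean(s2$score)), 1e-12)
  expect_error(compute_scores(dat[, -4], blk, w), "missing component")
})

test_that("population weights give scores that track the true composite", {
  pop <- make_population(weight_set(2))
  dat <- generate_sample(pop, 1e5, seed = 21, keep_truth = TRUE)
  sc <- compute_scores(dat, composite("M", c("m1", "m2", "m3")), pop$weights)
  expect_gte(cor(sc$score, dat$M), 0.999)
})
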