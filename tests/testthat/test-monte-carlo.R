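test_that("bias, variance and MSE follow their definitions", {
  est <- matrix(c(0.4, 0.4, 0.4, 0.2, 0.2, 0.2), 3, 2)
  s <- mc_summarize(est, truth = c(0.4, 0.2))
  expect_equal(s$bias, c(0, 0))
  expect_equal(s$variance, c(0, 0))
  expect_equal(s$mse, c(0, 0))

  est2 <- est + 1
  s2 <- mc_summarize(est2, truth = c(0.4, 0.2))
  expect_equal(s2$bias, c(1, 1))
  expect_equal(s2$variance, c(0, 0))
  expect_equal(s2$mse, c(1, 1))

  # MSE = bias^2 + variance holds exactly for arbitrary draws
  set.seed(2)
  est3 <- matrix(rnorm(200), 50, 4)
  s3 <- mc_summarize(est3, truth = rep(0, 4))
  expect_equal(s3$mse, s3$bias^2 + s3$variance)

  # the printed-formula variant sums squared deviations from the truth
  s4 <- mc_summarize(est2, truth = c(0.4, 0.2), variance_about = "truth")
  expect_equal(s4$variance, c(3 / 2, 3 / 2))
  expect_error(mc_summarize(est[1, , drop = FALSE], c(0.4, 0.2)),
               "at least two")
})

test_that("power is the fraction of rejections", {
  expect_equal(estimate_power(c(TRUE, TRUE, FALSE, TRUE)), 0.75)
  expect_equal(estimate_power(rep(FALSE, 10)), 0)
  expect_error(estimate_power(logical(0)), "no test decisions")
})

test_that("derived seeds are deterministic and order-free", {
  s1 <- vapply(1:50, function(i) cmsem:::derive_seed(123, i), integer(1))
  s2 <- vapply(50:1, function(i) cmsem:::derive_seed(123, i), integer(1))
  expect_identical(s1, rev(s2))
  expect_true(all(s1 >= 0 & s1 < 2^31))
  expect_identical(anyDuplicated(s1), 0L)
})

test_that("a single-replication condition yields one admissible estimate set", {
  r <- run_condition(mc_condition(weight_set = 2, n = 250, reps = 2,
                                  seed = 77))
  expect_identical(nrow(r$estimates), 2L)
  expect_false(anyNA(r$estimates))
  expect_identical(length(r$decisions), 2L)
  expect_identical(r$total_draws, r$inadmissible + 2L)
  expect_equal(r$share_inadmissible,
               r$inadmissible / r$total_draws)
  expect_error(mc_condition(weight_set = 2, n = 250, reps = 0))
})

test_that("reruns with the same master seed are identical", {
  r1 <- run_condition(mc_condition(1, 250, reps = 3, seed = 42))
  r2 <- run_condition(mc_condition(1, 250, reps = 3, seed = 42))
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$decisions, r2$decisions)
})

test_that("the study driver writes tables and a manifest", {
  out <- file.path(tempdir(), "cmsem-mc-out")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  conds <- list(mc_condition(1, 250, reps = 2, seed = 5),
                mc_condition(2, 250, reps = 2, seed = 6))
  study <- run_study(conditions = conds, out_dir = out)
  expect_identical(nrow(study$power), 2L)
  expect_true(all(file.exists(file.path(out, c(
    "estimates_ws1_n250.csv", "estimates_ws2_n250.csv",
    "inadmissibility_summary.csv", "power_summary.csv", "manifest.txt")))))
  est <- read.csv(file.path(out, "estimates_ws1_n250.csv"))
  expect_identical(nrow(est), 2L)
  expect_true(all(c("a", "b", "c", "d", "reject", "seed") %in% names(est)))
  manifest <- readLines(file.path(out, "manifest.txt"))
  expect_true(any(grepl("master_seed", manifest)))
})
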