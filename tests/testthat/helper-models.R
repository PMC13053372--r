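# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

sim_model <- function() {
  cms_model(predictor = latent("X", c("x1", "x2", "x3")),
            mediator = composite("M", c("m1", "m2", "m3")),
            outcome = latent("Y", c("y1", "y2", "y3")))
}

# A random banded H-O loading matrix (unit diagonal, nonzero band and first
# column), rejection-sampled to stay well conditioned (an admissible fit
# implies weights can be extracted stably).
random_banded_lambda <- function(K) {
  repeat {
    lam <- diag(K)
    lam[2:K, 1] <- runif(K - 1, -1.2, 1.2)
    for (j in 2:K) lam[j - 1, j] <- runif(1, 0.2, 1.2) * sample(c(-1, 1), 1)
    if (kappa(lam, exact = TRUE) < 1e4) return(lam)
  }
}

# Population-level CCFA parameters (Lambda, Phi, theta in the order used by
# the fitted model) for the simulation population; the implied covariance of
# these parameters must reproduce the analytic observable covariance.
pop_ccfa_params <- function(pop) {
  w <- pop$weights
  smm <- pop$sigma_mm
  lcol_raw <- as.numeric(smm %*% w)        # Cov(m, M) for the unit-scale M
  alpha <- lcol_raw[1]                     # scale fixed by lambda_11 = 1
  lcol <- lcol_raw / alpha
  phi_M <- alpha^2                         # Var of the rescaled composite
  Rres <- smm - outer(lcol, lcol) * phi_M
  bf <- cmsem:::ho_band_factor(Rres)
  # constructs in model order: X, M, nu1, nu2, Y
  lambda <- matrix(0, 9, 5,
                   dimnames = list(pop$vars, c("X", "M", "nu1", "nu2", "Y")))
  lambda[1:3, "X"] <- pop$lambda_x / pop$lambda_x[1]
  lambda[4:6, "M"] <- lcol
  lambda[4, "nu1"] <- bf$lam[1]; lambda[5, "nu1"] <- 1
  lambda[5, "nu2"] <- bf$lam[2]; lambda[6, "nu2"] <- 1
  lambda[7:9, "Y"] <- pop$lambda_y / pop$lambda_y[1]
  phi <- matrix(0, 5, 5, dimnames = dimnames(lambda)[c(2, 2)])
  sx <- pop$lambda_x[1]; sy <- pop$lambda_y[1]
  cov_XY <- pop$b + pop$c * pop$rho
  cov_MY <- pop$b * pop$rho + pop$c * pop$var_M
  phi["X", "X"] <- sx^2
  phi["Y", "Y"] <- sy^2
  phi["M", "M"] <- phi_M
  phi["X", "M"] <- phi["M", "X"] <- sx * alpha * pop$rho
  phi["X", "Y"] <- phi["Y", "X"] <- sx * sy * cov_XY
  phi["M", "Y"] <- phi["Y", "M"] <- alpha * sy * cov_MY
  phi[c("nu1", "nu2"), c("nu1", "nu2")] <- bf$phi
  theta <- c(pop$theta_x, 0, 0, 0, pop$theta_y)
  list(lambda = lambda, phi = phi, theta = theta)
}

# LMS model equal to the simulation population expressed on the fitted scale
# (latent X standardized, Y scale set by its first indicator).
pop_lms_model <- function(pop, score_var = "score") {
  sy <- pop$lambda_y[1]
  lms_model(lambda_x = pop$lambda_x, theta_x = pop$theta_x,
            a = pop$rho, zeta_m = pop$zeta_m,
            tau = -sy * pop$d * pop$rho,
            b = sy * pop$b, c = sy * pop$c, d = sy * pop$d,
            zeta_y = sy^2 * pop$zeta_y,
            lambda_y = pop$lambda_y / sy,
            theta_y = pop$theta_y,
            x_vars = paste0("x", 1:3), score_var = score_var,
            y_vars = paste0("y", 1:3))
}

# Sample from the population with the composite score appended (population
# weights), for direct LMS fits.
scored_sample <- function(pop, n, seed) {
  dat <- generate_sample(pop, n, seed = seed, keep_truth = TRUE)
  sc <- compute_scores(dat, composite("M", c("m1", "m2", "m3")), pop$weights)
  dat$score <- sc$score
  dat
}
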