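# Population model for validating CMS: a standardized moderated mediation
# system with a latent predictor X (three indicators, loadings 0.7), a
# composite mediator M built from three components, and a latent outcome Y
# (loadings 0.7, 0.8, 0.9):
#   M = a X + zeta_M,                      a = 0.4
#   Y = b X + c M + d (X M - rho) + zeta_Y, (b, c, d) = (0.3, 0.4, 0.2)
# with rho = Cov(X, M) = 0.4 and error variances solved so that X, M, Y and
# all nine observed variables have unit variance.

#' Preset composite weight sets for the population model
#'
#' Two configurations of population weights and component correlations, both
#' normalized so the composite has unit variance:
#' * Set 1: weights (0.2, 0.4, 0.6), all component correlations 0.5.
#' * Set 2: weights (0.4, 0.5, 0.5), correlations r12 = 0.25, r13 = 0.4,
#'   r23 = 0.16.
#'
#' @param set 1 or 2, or a list with elements `weights` (length 3) and
#'   `cor` (length 3: r12, r13, r23) for a custom configuration.
#' @return An object of class `"weight_set"`: list with `weights`, `sigma_mm`
#'   (component covariance matrix) and `label`.
#' @export
weight_set <- function(set = 1) {
  if (is.list(set)) {
    w <- set$weights; r <- set$cor; label <- set$label %||% "custom"
  } else if (identical(as.integer(set), 1L)) {
    w <- c(0.2, 0.4, 0.6); r <- c(0.5, 0.5, 0.5); label <- "1"
  } else if (identical(as.integer(set), 2L)) {
    w <- c(0.4, 0.5, 0.5); r <- c(0.25, 0.4, 0.16); label <- "2"
  } else stop("'set' must be 1, 2, or a list(weights=, cor=)", call. = FALSE)
  stopifnot(length(w) == 3L, length(r) == 3L)
  sigma <- diag(3)
  sigma[1, 2] <- sigma[2, 1] <- r[1]
  sigma[1, 3] <- sigma[3, 1] <- r[2]
  sigma[2, 3] <- sigma[3, 2] <- r[3]
  dimnames(sigma) <- list(paste0("m", 1:3), paste0("m", 1:3))
  if (!is_pd(sigma))
    stop("component covariance matrix is not positive definite", call. = FALSE)
  structure(list(weights = w, sigma_mm = sigma, label = label),
            class = "weight_set")
}

#' Assemble the population model
#'
#' Solves all derived variances of the standardized population: measurement
#' error variances for unit indicator variances, `Var(zeta_M) = 1 - a^2`, and
#' `Var(zeta_Y)` from the moment identity for
#' `Var(b X + c M + d (X M - rho))` with `(X, M)` bivariate standard normal
#' (`Var(X M) = 1 + rho^2`, zero odd cross-moments). The component block is
#' tied to `X` by the cross-covariance rule `Cov(m, X) = rho * Sigma_mm w`,
#' which makes the composite carry all covariance between its components and
#' the rest of the system.
#'
#' @param ws a [weight_set()] (or 1/2, passed through).
#' @param a,b,c,d structural coefficients (defaults 0.4, 0.3, 0.4, 0.2; the
#'   interaction strength `d` may be set to 0 for type-I-error studies).
#' @return An object of class `"population_model"`.
#' @export
make_population <- function(ws = weight_set(1), a = 0.4, b = 0.3, c = 0.4,
                            d = 0.2) {
  if (!inherits(ws, "weight_set")) ws <- weight_set(ws)
  lambda_x <- c(0.7, 0.7, 0.7)
  lambda_y <- c(0.7, 0.8, 0.9)
  theta_x <- 1 - lambda_x^2
  theta_y <- 1 - lambda_y^2
  w <- ws$weights
  smm <- ws$sigma_mm
  var_M <- drop(t(w) %*% smm %*% w)
  # cross-covariance rule Cov(m, X) = a * Sigma_mm W ; then
  # Cov(X, M) = w' Cov(m, X) = a * Var(M)
  s_mx <- as.numeric(a * smm %*% w)
  rho <- drop(t(w) %*% s_mx)
  zeta_m <- var_M - rho^2 / 1        # Var(M) - a^2 Var(X) when Var(M)=1
  # Var(Y) = 1: Var(bX + cM + d(XM - rho)) + zeta_y = 1 with
  # Var(XM) = Var(X)Var(M) + rho^2, Cov(X, XM) = Cov(M, XM) = 0.
  var_syst <- b^2 + c^2 * var_M + 2 * b * c * rho +
    d^2 * (var_M + rho^2)
  zeta_y <- 1 - var_syst
  if (zeta_y <= 0)
    stop("structural coefficients imply Var(Y) > 1; no valid error variance",
         call. = FALSE)
  structure(list(
    weight_set = ws, weights = w, sigma_mm = smm,
    lambda_x = lambda_x, lambda_y = lambda_y,
    theta_x = theta_x, theta_y = theta_y,
    a = a, b = b, c = c, d = d,
    s_mx = s_mx, rho = rho, var_M = var_M,
    zeta_m = zeta_m, zeta_y = zeta_y,
    vars = c(paste0("x", 1:3), paste0("m", 1:3), paste0("y", 1:3))
  ), class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Moderated mediation population model (weight set ", x$weight_set$label,
      ")\n", sep = "")
  cat(sprintf("  weights: (%s);  Cov(X, M) = %.3f\n",
              paste(x$weights, collapse = ", "), x$rho))
  cat(sprintf("  structural: a = %.2f, b = %.2f, c = %.2f, d = %.2f\n",
              x$a, x$b, x$c, x$d))
  cat(sprintf("  Var(zeta_M) = %.4f, Var(zeta_Y) = %.4f\n",
              x$zeta_m, x$zeta_y))
  invisible(x)
}

#' Draw a sample from the population model
#'
#' Follows the generating procedure of the validation study: the exogenous
#' vector `(X, m1..m3, delta1..3, eps1..3, zeta_Y)` is drawn from a
#' multivariate normal distribution whose only off-diagonal covariances are
#' `Cov(m, X) = a Sigma_mm w` and the component block `Sigma_mm`. The
#' endogenous variables follow deterministically: `M = w'm`, the indicators
#' from their measurement equations, and `Y` from the structural equation with
#' the mean-centered product term. `zeta_M` is implicit (`M - a X`), not
#' drawn, so the composite fully accounts for the covariances between its
#' components and the other variables.
#'
#' @param pop a [make_population()] model.
#' @param n sample size (>= 1).
#' @param seed optional integer seed (same seed, same table).
#' @param keep_truth if `TRUE`, append the latent truth columns `X`, `M`, `Y`
#'   (for testing only).
#' @return A data frame with columns `x1..x3, m1..m3, y1..y3` (plus truth
#'   columns on request); the seed used is stored as attribute `"seed"`.
#' @export
generate_sample <- function(pop, n, seed = NULL, keep_truth = FALSE) {
  stopifnot(inherits(pop, "population_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # exogenous covariance: X, m1..3, delta1..3, eps1..3, zetaY (11 x 11)
  q <- 11L
  V <- diag(c(1, rep(0, 3), pop$theta_x, pop$theta_y, pop$zeta_y))
  V[2:4, 2:4] <- pop$sigma_mm
  V[1, 2:4] <- V[2:4, 1] <- pop$s_mx
  Z <- MASS::mvrnorm(n, mu = rep(0, q), Sigma = V)
  if (n == 1L) Z <- matrix(Z, nrow = 1L)
  X <- Z[, 1]
  m <- Z[, 2:4, drop = FALSE]
  delta <- Z[, 5:7, drop = FALSE]
  eps <- Z[, 8:10, drop = FALSE]
  zy <- Z[, 11]
  M <- as.numeric(m %*% pop$weights)
  Y <- pop$b * X + pop$c * M + pop$d * (X * M - pop$rho) + zy
  xs <- outer(X, pop$lambda_x) + delta
  ys <- eps + outer(Y, pop$lambda_y)
  out <- data.frame(xs, m, ys)
  names(out) <- pop$vars
  if (keep_truth) { out$X <- X; out$M <- M; out$Y <- Y }
  attr(out, "seed") <- seed
  out
}

#' Analytic moments of the population model
#'
#' Expands the structural system using bivariate-normal product-moment
#' identities: the reduced form of the outcome equation
#' (`Y = (b + c a) X + (d a) X^2 + (c zeta_M + d X zeta_M + zeta_Y) - d rho`),
#' the full 9 x 9 observable covariance matrix, and the implied R-squared
#' values for mediator and outcome.
#'
#' @param pop a [make_population()] model.
#' @return List with `sigma` (9 x 9 observable covariance), `reduced_form`
#'   (named vector: `linear = b + c a`, `quadratic = d a`,
#'   `constant = -d rho`), and `r_squared` (named vector for `M` and `Y`).
#' @export
analytic_moments <- function(pop) {
  stopifnot(inherits(pop, "population_model"))
  with(pop, {
    cov_XY <- b + c * rho                  # Cov(X, XM) = 0
    cov_MY <- b * rho + c * var_M          # Cov(M, XM) = 0 (odd moments)
    smw <- as.numeric(sigma_mm %*% weights)
    cov_mY <- b * s_mx + c * smw
    sig <- matrix(0, 9, 9, dimnames = list(vars, vars))
    sig[1:3, 1:3] <- outer(lambda_x, lambda_x) + diag(theta_x)
    sig[4:6, 4:6] <- sigma_mm
    sig[7:9, 7:9] <- outer(lambda_y, lambda_y) + diag(theta_y)
    sig[1:3, 4:6] <- outer(lambda_x, s_mx)
    sig[4:6, 1:3] <- t(sig[1:3, 4:6])
    sig[1:3, 7:9] <- outer(lambda_x, lambda_y) * cov_XY
    sig[7:9, 1:3] <- t(sig[1:3, 7:9])
    sig[4:6, 7:9] <- outer(cov_mY, lambda_y)
    sig[7:9, 4:6] <- t(sig[4:6, 7:9])
    list(
      sigma = sig,
      reduced_form = c(linear = b + c * a, quadratic = d * a,
                       constant = -d * rho),
      r_squared = c(M = rho^2 / var_M,
                    Y = b^2 + c^2 * var_M + 2 * b * c * rho +
                      d^2 * (var_M + rho^2)),
      construct_cov = c(cov_XM = rho, cov_XY = cov_XY, cov_MY = cov_MY)
    )
  })
}
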