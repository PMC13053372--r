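# Step 3 of CMS: latent moderated structural equations (LMS) on the
# score-augmented model. The structural system is
#   M = a X + zeta_M            (M observed: the composite score)
#   Y = tau + b X + c M + d X M + zeta_Y
# with a reflective block for the latent predictor X (variance fixed to 1) and
# for the latent outcome Y (first loading fixed to 1). Conditional on X = t
# the observed vector is Gaussian, so the marginal likelihood is a weighted
# mixture over Gauss-Hermite nodes for the standard-normal latent dimension.

#' Gauss-Hermite quadrature rule for the standard normal density
#'
#' Nodes and weights for integrating against N(0, 1): probabilists' transform
#' of the Gauss-Hermite rule, with weights normalized to sum to one exactly.
#'
#' @param m number of nodes (default 24).
#' @param nodes,weights optionally supply a custom rule; it is validated
#'   (weights must sum to 1 within 1e-12 and nodes must be symmetric about 0).
#' @return An object of class `"gh_rule"` with elements `m`, `nodes`,
#'   `weights`.
#' @export
gh_rule <- function(m = 24, nodes = NULL, weights = NULL) {
  if (is.null(nodes) != is.null(weights))
    stop("supply both 'nodes' and 'weights' or neither", call. = FALSE)
  if (is.null(nodes)) {
    if (m < 2) stop("'m' must be at least 2", call. = FALSE)
    gh <- pracma::gaussHermite(m)
    nodes <- gh$x * sqrt(2)
    weights <- gh$w / sqrt(pi)
    weights <- weights / sum(weights)
  }
  if (length(nodes) != length(weights))
    stop("nodes and weights must have equal length", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("quadrature weights must sum to 1", call. = FALSE)
  if (max(abs(sort(nodes) + rev(sort(nodes)))) > 1e-8)
    stop("quadrature nodes must be symmetric about 0", call. = FALSE)
  structure(list(m = length(nodes), nodes = as.numeric(nodes),
                 weights = as.numeric(weights)), class = "gh_rule")
}

#' @export
print.gh_rule <- function(x, ...) {
  cat("Gauss-Hermite rule for N(0,1), m =", x$m, "nodes\n")
  invisible(x)
}

#' Parameter set of the latent-interaction structural model
#'
#' @param lambda_x loadings of the latent predictor's indicators (its variance
#'   is fixed to 1 for scale, so all loadings are free).
#' @param theta_x measurement-error variances of the predictor indicators.
#' @param a effect of the predictor on the composite score.
#' @param zeta_m residual variance of the score equation.
#' @param tau intercept of the outcome equation (the only intercept; it
#'   absorbs the product-term mean shift `-d Cov(X, M)` under centered data).
#' @param b,c,d outcome-equation coefficients for the predictor, the score,
#'   and their interaction.
#' @param zeta_y residual variance of the outcome equation.
#' @param lambda_y outcome-indicator loadings; the first must equal 1 (scale
#'   constraint).
#' @param theta_y measurement-error variances of the outcome indicators.
#' @param x_vars,score_var,y_vars column names used to pull data.
#' @return An object of class `"lms_model"`.
#' @export
lms_model <- function(lambda_x, theta_x, a, zeta_m, tau, b, c, d, zeta_y,
                      lambda_y, theta_y,
                      x_vars = paste0("x", seq_along(lambda_x)),
                      score_var = "score",
                      y_vars = paste0("y", seq_along(lambda_y))) {
  stopifnot(length(theta_x) == length(lambda_x),
            length(theta_y) == length(lambda_y),
            length(lambda_x) >= 2L, length(lambda_y) >= 2L)
  if (abs(lambda_y[1] - 1) > 1e-12)
    stop("the first outcome loading must be fixed to 1 (scale constraint)",
         call. = FALSE)
  structure(list(lambda_x = as.numeric(lambda_x),
                 theta_x = as.numeric(theta_x),
                 a = a, zeta_m = zeta_m, tau = tau, b = b, c = c, d = d,
                 zeta_y = zeta_y, lambda_y = as.numeric(lambda_y),
                 theta_y = as.numeric(theta_y),
                 x_vars = x_vars, score_var = score_var, y_vars = y_vars),
            class = "lms_model")
}

# parameter vector <-> model (lambda_y[1] excluded: fixed)
lms_par_vector <- function(model) {
  c(model$lambda_x, model$theta_x, model$a, model$zeta_m, model$tau,
    model$b, model$c, model$d, model$zeta_y, model$lambda_y[-1L],
    model$theta_y)
}

lms_par_names <- function(qx, qy) {
  c(paste0("lambda_x", seq_len(qx)), paste0("theta_x", seq_len(qx)),
    "a", "zeta_m", "tau", "b", "c", "d", "zeta_y",
    paste0("lambda_y", 1 + seq_len(qy - 1L)), paste0("theta_y", seq_len(qy)))
}

lms_vector_to_model <- function(par, template) {
  qx <- length(template$lambda_x); qy <- length(template$lambda_y)
  lms_model(lambda_x = par[seq_len(qx)],
            theta_x = par[qx + seq_len(qx)],
            a = par[2 * qx + 1], zeta_m = par[2 * qx + 2],
            tau = par[2 * qx + 3], b = par[2 * qx + 4], c = par[2 * qx + 5],
            d = par[2 * qx + 6], zeta_y = par[2 * qx + 7],
            lambda_y = c(1, par[2 * qx + 7 + seq_len(qy - 1L)]),
            theta_y = par[2 * qx + 6 + qy + seq_len(qy)],
            x_vars = template$x_vars, score_var = template$score_var,
            y_vars = template$y_vars)
}

#' Conditional moments of the observed variables given the latent predictor
#'
#' Conditional on `X = x` the model is linear-Gaussian: the score has mean
#' `a x` and variance `zeta_m`; the outcome construct has mean
#' `tau + b x + (c + d x) a x` with the slope `(c + d x)` propagating the
#' score residual variance into the outcome block; predictor indicators have
#' mean `lambda_x x` and diagonal error covariance.
#'
#' @param model an [lms_model()].
#' @param x scalar latent predictor value.
#' @return List with `mean` (length qx + 1 + qy) and `cov` (symmetric PSD
#'   matrix), ordered as (x-indicators, score, y-indicators).
#' @export
conditional_moments <- function(model, x) {
  stopifnot(inherits(model, "lms_model"), is.numeric(x), length(x) == 1L)
  qx <- length(model$lambda_x); qy <- length(model$lambda_y)
  s <- model$c + model$d * x
  eta <- model$tau + model$b * x + s * model$a * x
  mean <- c(model$lambda_x * x, model$a * x, model$lambda_y * eta)
  p <- qx + 1L + qy
  cov <- matrix(0, p, p)
  cov[seq_len(qx), seq_len(qx)] <- diag(model$theta_x, qx)
  im <- qx + 1L
  iy <- qx + 1L + seq_len(qy)
  cov[im, im] <- model$zeta_m
  cov[im, iy] <- cov[iy, im] <- model$lambda_y * s * model$zeta_m
  cov[iy, iy] <- outer(model$lambda_y, model$lambda_y) *
    (s^2 * model$zeta_m + model$zeta_y) + diag(model$theta_y, qy)
  nm <- c(model$x_vars, model$score_var, model$y_vars)
  dimnames(cov) <- list(nm, nm)
  names(mean) <- nm
  list(mean = mean, cov = cov)
}

# Closed-form unconditional moments when d = 0 (linear-Gaussian model):
# used as the exact-likelihood oracle for the quadrature approximation.
lms_implied_moments <- function(model) {
  qx <- length(model$lambda_x); qy <- length(model$lambda_y)
  var_m <- model$a^2 + model$zeta_m
  cov_xm <- model$a
  ey <- model$tau            # E[Y] with d = 0 (E[XM] drops out)
  var_y <- model$b^2 + model$c^2 * var_m + 2 * model$b * model$c * cov_xm +
    model$zeta_y
  cov_xy <- model$b + model$c * cov_xm
  cov_my <- model$b * cov_xm + model$c * var_m
  p <- qx + 1L + qy
  mean <- c(rep(0, qx), 0, model$lambda_y * ey)
  cov <- matrix(0, p, p)
  ix <- seq_len(qx); im <- qx + 1L; iy <- qx + 1L + seq_len(qy)
  cov[ix, ix] <- outer(model$lambda_x, model$lambda_x) + diag(model$theta_x, qx)
  cov[ix, im] <- cov[im, ix] <- model$lambda_x * cov_xm
  cov[ix, iy] <- outer(model$lambda_x, model$lambda_y) * cov_xy
  cov[iy, ix] <- t(cov[ix, iy])
  cov[im, im] <- var_m
  cov[im, iy] <- cov[iy, im] <- model$lambda_y * cov_my
  cov[iy, iy] <- outer(model$lambda_y, model$lambda_y) * var_y +
    diag(model$theta_y, qy)
  nm <- c(model$x_vars, model$score_var, model$y_vars)
  dimnames(cov) <- list(nm, nm)
  names(mean) <- nm
  list(mean = mean, cov = cov)
}

# Assemble (X, M, Y) numeric matrices from data by the model's column names.
lms_data_matrices <- function(model, data, center = FALSE) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("data table is empty", call. = FALSE)
  need <- c(model$x_vars, model$score_var, model$y_vars)
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("data are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyNA(data[need])) stop("data contain missing values", call. = FALSE)
  X <- as.matrix(data[model$x_vars])
  M <- as.numeric(data[[model$score_var]])
  Y <- as.matrix(data[model$y_vars])
  if (center) {
    X <- scale(X, scale = FALSE)
    M <- M - mean(M)
    Y <- scale(Y, scale = FALSE)
  }
  list(X = X, M = M, Y = Y)
}

#' Quadrature-approximated marginal log-likelihood
#'
#' Per-observation density is the quadrature mixture
#' `sum_k w_k Gaussian(obs; mu(x_k), Sigma(x_k))` over the latent predictor
#' dimension; the function returns the sum of the log densities. Non-positive
#' variance parameters yield a large negative value (driving an optimizer back
#' into the admissible region) rather than an error.
#'
#' @param model an [lms_model()].
#' @param data data frame or matrix with the model's columns; assumed
#'   centered (see [fit_lms()]).
#' @param rule a [gh_rule()] with at least 8 nodes.
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(model, data, rule = gh_rule(24)) {
  stopifnot(inherits(model, "lms_model"), inherits(rule, "gh_rule"))
  if (rule$m < 8) stop("quadrature rule needs at least 8 nodes", call. = FALSE)
  d <- lms_data_matrices(model, data)
  lms_loglik_cpp(lms_par_vector(model), d$X, d$M, d$Y, rule$nodes,
                 log(rule$weights))
}

# Starting values from the data alone: one-factor principal-component
# approximations per block and proxy-score regressions.
lms_default_start <- function(X, M, Y) {
  start_block <- function(Z) {
    C <- cov(Z)
    e <- eigen(C, symmetric = TRUE)
    f <- e$vectors[, 1] * sqrt(max(e$values[1], 0.1))
    if (sum(f) < 0) f <- -f
    f
  }
  fx <- start_block(X)
  lam_x <- 0.9 * fx
  theta_x <- pmax(diag(cov(X)) - lam_x^2, 0.1)
  fs <- as.numeric(scale(X %*% fx))
  a <- 0.9 * cov(fs, M)
  zeta_m <- max(var(M) - a^2, 0.1)
  fy <- start_block(Y)
  lam_y <- fy / fy[1]
  scale_y <- fy[1]
  theta_y <- pmax(diag(cov(Y)) - (lam_y * scale_y)^2, 0.1)
  fsy <- as.numeric(Y %*% fy) / sum(fy^2)   # proxy for the Y construct
  fit0 <- stats::lm.fit(cbind(1, fs, M), fsy)
  cf <- fit0$coefficients
  zeta_y <- max(var(fit0$residuals), 0.05)
  list(lambda_x = lam_x, theta_x = theta_x, a = a, zeta_m = zeta_m,
       tau = cf[1], b = cf[2], c = cf[3], d = 0, zeta_y = zeta_y,
       lambda_y = lam_y, theta_y = theta_y)
}

#' Fit the latent-interaction model by full-information maximum likelihood
#'
#' Maximizes the quadrature-approximated marginal likelihood over all
#' measurement and structural parameters jointly (the score equation is part
#' of the same likelihood, not a separate regression). Maximization is direct
#' quasi-Newton (BFGS) with finite-difference gradients evaluated in compiled
#' code, followed by Newton polishing steps using the numeric observed-
#' information Hessian; that Hessian, inverted, provides the standard errors.
#' Weight/score uncertainty from the earlier CMS steps is not propagated.
#'
#' @param data data frame with indicator columns and the composite score.
#' @param x,score,y column names of the predictor indicators, the score, and
#'   the outcome indicators.
#' @param nodes number of Gauss-Hermite nodes (default 24).
#' @param start optional [lms_model()] or named list of start values.
#' @param se compute the Hessian-based standard errors (default `TRUE`;
#'   needed for [moderation_test()] and admissibility).
#' @param maxit BFGS iteration cap.
#' @param center center all columns first (default `TRUE`; the score is
#'   already mean-zero by construction, see [compute_scores()]).
#' @return An object of class `"lms_fit"`: `model` (estimates), `par`, `se`,
#'   `vcov`, `logLik`, `converged`, `admissible`, `standardized` (see
#'   [lms_standardize()]), `sd_score`, `n`, `nodes`.
#' @export
fit_lms <- function(data, x, score, y, nodes = 24, start = NULL, se = TRUE,
                    maxit = 500L, center = TRUE) {
  template <- lms_model(lambda_x = rep(0.7, length(x)),
                        theta_x = rep(0.5, length(x)),
                        a = 0.3, zeta_m = 0.8, tau = 0, b = 0.2, c = 0.3,
                        d = 0, zeta_y = 0.5,
                        lambda_y = c(1, rep(1, length(y) - 1L)),
                        theta_y = rep(0.5, length(y)),
                        x_vars = x, score_var = score, y_vars = y)
  dm <- lms_data_matrices(template, data, center = center)
  n <- nrow(dm$X)
  qx <- length(x); qy <- length(y)
  rule <- gh_rule(nodes)
  logw <- log(rule$weights)

  if (is.null(start)) start <- lms_default_start(dm$X, dm$M, dm$Y)
  if (inherits(start, "lms_model")) {
    par0 <- lms_par_vector(start)
  } else {
    template[names(start)] <- start
    par0 <- lms_par_vector(template)
  }

  negll <- function(p) -lms_loglik_cpp(p, dm$X, dm$M, dm$Y, rule$nodes, logw)
  neggr <- function(p) -lms_grad_cpp(p, dm$X, dm$M, dm$Y, rule$nodes, logw,
                                     h = 1e-6, central = FALSE)
  opt <- optim(par0, negll, neggr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  par_hat <- opt$par

  # Newton polishing with the (central-difference) gradient and Hessian
  H <- NULL
  g <- NULL
  for (it in seq_len(4L)) {
    g <- lms_grad_cpp(par_hat, dm$X, dm$M, dm$Y, rule$nodes, logw,
                      h = 1e-5, central = TRUE)
    if (max(abs(g)) < 1e-2) break
    H <- lms_hess_cpp(par_hat, dm$X, dm$M, dm$Y, rule$nodes, logw)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    f_cur <- negll(par_hat)
    cand <- par_hat - step
    ok <- FALSE
    for (half in 0:6) {
      if (negll(cand) <= f_cur + 1e-10) { ok <- TRUE; break }
      cand <- par_hat - step / 2^(half + 1)
    }
    if (!ok) break
    par_hat <- cand
    H <- NULL
  }
  g <- lms_grad_cpp(par_hat, dm$X, dm$M, dm$Y, rule$nodes, logw,
                    h = 1e-5, central = TRUE)
  converged <- opt$convergence == 0L || max(abs(g)) < 1e-2

  names(par_hat) <- lms_par_names(qx, qy)
  model_hat <- lms_vector_to_model(unname(par_hat), template)
  ll <- lms_loglik_cpp(par_hat, dm$X, dm$M, dm$Y, rule$nodes, logw)

  se_vec <- rep(NA_real_, length(par_hat))
  vc <- NULL
  hessian_nd <- NA
  if (se) {
    if (is.null(H))
      H <- lms_hess_cpp(par_hat, dm$X, dm$M, dm$Y, rule$nodes, logw)
    hessian_nd <- is_pd(-(H + t(H)) / 2)
    if (hessian_nd) {
      vc <- tryCatch(solve(-(H + t(H)) / 2), error = function(e) NULL)
      if (!is.null(vc) && all(diag(vc) > 0)) {
        se_vec <- sqrt(diag(vc))
        dimnames(vc) <- list(names(par_hat), names(par_hat))
      } else hessian_nd <- FALSE
    }
  }
  names(se_vec) <- names(par_hat)

  sd_score <- sd(dm$M)
  fit <- structure(list(
    model = model_hat, par = par_hat, se = se_vec, vcov = vc,
    logLik = ll, converged = converged, hessian_nd = hessian_nd,
    n = n, nodes = rule$m, sd_score = sd_score,
    counts = opt$counts, se_computed = se
  ), class = "lms_fit")
  adm <- admissibility_check(fit)
  fit$admissible <- adm$admissible
  fit$inadmissible_reason <- adm$reason
  fit$standardized <- if (adm$admissible) lms_standardize(fit) else
    rep(NA_real_, 4)
  fit
}

#' @export
admissibility_check.lms_fit <- function(fit) {
  if (!isTRUE(fit$converged))
    return(list(admissible = FALSE, reason = "no convergence"))
  m <- fit$model
  if (any(c(m$theta_x, m$theta_y, m$zeta_m, m$zeta_y) < 0))
    return(list(admissible = FALSE, reason = "negative variance"))
  if (isTRUE(fit$se_computed)) {
    if (!isTRUE(fit$hessian_nd))
      return(list(admissible = FALSE,
                  reason = "Hessian not negative definite"))
    if (any(!is.finite(fit$se)))
      return(list(admissible = FALSE, reason = "standard errors unavailable"))
  }
  list(admissible = TRUE, reason = "admissible")
}

#' Standardized structural estimates
#'
#' Scales each linear coefficient by SD(predictor)/SD(outcome) and the
#' interaction coefficient by SD(X) * SD(score) / SD(Y). The latent predictor
#' has SD 1 by its scale constraint; the score SD is empirical (from the
#' analysis sample); the outcome SD comes from the model-implied unconditional
#' variance
#' `Var(Y) = b^2 + c^2 Var(M) + 2 a b c + d^2 (Var(M) + a^2) + zeta_y`
#' with `Var(M) = a^2 + zeta_m`.
#'
#' @param fit an admissible `"lms_fit"`.
#' @return Named vector of standardized `a`, `b`, `c`, `d`.
#' @export
lms_standardize <- function(fit) {
  stopifnot(inherits(fit, "lms_fit"))
  m <- fit$model
  sd_m <- fit$sd_score
  var_m_model <- m$a^2 + m$zeta_m
  var_y <- m$b^2 + m$c^2 * var_m_model + 2 * m$a * m$b * m$c +
    m$d^2 * (var_m_model + m$a^2) + m$zeta_y
  if (!is.finite(var_y) || var_y <= 0 || sd_m <= 0)
    stop("zero or negative implied variance; cannot standardize",
         call. = FALSE)
  sd_y <- sqrt(var_y)
  c(a = m$a / sd_m, b = m$b / sd_y, c = m$c * sd_m / sd_y,
    d = m$d * sd_m / sd_y)
}

#' z-test of the moderation (interaction) effect
#'
#' `z = d / SE(d)` with a two-sided normal p-value, using the LMS
#' observed-information standard error.
#'
#' @param fit an `"lms_fit"` (or `"cms"` fit).
#' @param alpha significance level (default 0.05).
#' @return List with `z`, `p_value`, `reject`, `estimate`, `se`, `alpha`.
#' @export
moderation_test <- function(fit, alpha = 0.05) UseMethod("moderation_test")

#' @export
moderation_test.lms_fit <- function(fit, alpha = 0.05) {
  d_hat <- fit$model$d
  se_d <- fit$se[["d"]]
  z <- d_hat / se_d
  p <- 2 * pnorm(-abs(z))
  list(z = z, p_value = p, reject = is.finite(p) && p < alpha,
       estimate = d_hat, se = se_d, alpha = alpha)
}

#' @export
print.lms_fit <- function(x, digits = 3, ...) {
  cat("Latent moderated structural equations fit (FIML, ", x$nodes,
      " quadrature nodes)\n", sep = "")
  cat(sprintf("  n = %d, logLik = %.3f, converged: %s, admissible: %s\n",
              x$n, x$logLik, x$converged, x$admissible))
  if (!x$admissible) cat("  reason:", x$inadmissible_reason, "\n")
  tab <- cbind(Estimate = x$par, `Std. Error` = x$se,
               z = x$par / x$se)
  cat("\n"); print(round(tab, digits))
  if (all(is.finite(x$standardized))) {
    cat("\nStandardized structural estimates:\n")
    print(round(x$standardized, digits))
  }
  invisible(x)
}

#' @export
coef.lms_fit <- function(object, standardized = FALSE, ...) {
  if (standardized) return(object$standardized)
  object$par
}

#' @export
vcov.lms_fit <- function(object, ...) object$vcov

#' @export
logLik.lms_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$par), nobs = object$n,
            class = "logLik")
}

#' @export
simulate.lms_fit <- function(object, nsim = 1, seed = NULL, n = object$n,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- object$model
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    Xl <- rnorm(n)
    Ml <- m$a * Xl + rnorm(n, sd = sqrt(max(m$zeta_m, 0)))
    Yl <- m$tau + m$b * Xl + m$c * Ml + m$d * Xl * Ml +
      rnorm(n, sd = sqrt(max(m$zeta_y, 0)))
    dat <- cbind(outer(Xl, m$lambda_x) +
                   matrix(rnorm(n * length(m$lambda_x)), n) %*%
                   diag(sqrt(pmax(m$theta_x, 0))),
                 Ml,
                 outer(Yl, m$lambda_y) +
                   matrix(rnorm(n * length(m$lambda_y)), n) %*%
                   diag(sqrt(pmax(m$theta_y, 0))))
    dat <- as.data.frame(dat)
    names(dat) <- c(m$x_vars, m$score_var, m$y_vars)
    out[[i]] <- dat
  }
  if (nsim == 1) out[[1]] else out
}
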