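# Step 1 of CMS: confirmatory composite/factor analysis (CCFA).
#
# The model couples banded H-O composite blocks with reflective latent blocks,
# leaves all composite-of-interest / latent-variable covariances free
# (saturated structural part) and constrains every excrescent variable to be
# uncorrelated with all composites of interest and latent variables, and with
# excrescent variables of other blocks.

# ---- parameterization ------------------------------------------------------

# Build the full parameter map for a set of blocks: loading matrix skeleton,
# construct covariance skeleton, measurement error skeleton, and the index of
# every free parameter.
ccfa_parameterization <- function(blocks) {
  if (inherits(blocks, "cms_model"))
    blocks <- list(blocks$predictor, blocks$mediator, blocks$outcome)
  if (inherits(blocks, "cms_block")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, inherits, logical(1), "cms_block")))

  obs <- character()
  constructs <- character()
  structural <- character()      # composites of interest + latent variables
  excrescent <- character()
  exc_block <- integer()         # block id of each excrescent variable
  lam_free <- matrix(FALSE, 0, 0)
  lam_fix <- list()              # fixed-to-one cells (row, col)

  # grow Lambda block-diagonally
  Lfree <- NULL
  fixed_cells <- NULL
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    if (anyDuplicated(c(obs, b$vars)))
      stop("observed variables shared across blocks are not supported",
           call. = FALSE)
    if (b$kind == "composite") {
      pat <- build_ho_pattern(b)
      K <- length(b$vars)
      bl_free <- ho_free(pat)
      bl_fix <- which(unclass(pat) == "1", arr.ind = TRUE)
      cn <- colnames(pat)
      structural <- c(structural, b$name)
      excrescent <- c(excrescent, cn[-1L])
      exc_block <- c(exc_block, rep(bi, K - 1L))
    } else {
      K <- length(b$vars)
      bl_free <- matrix(c(FALSE, rep(TRUE, K - 1L)), ncol = 1L)
      bl_fix <- cbind(row = 1L, col = 1L)
      cn <- b$name
      structural <- c(structural, b$name)
    }
    r0 <- length(obs); c0 <- length(constructs)
    newfree <- matrix(FALSE, length(obs) + K, length(constructs) + length(cn))
    if (length(obs)) newfree[seq_len(r0), seq_len(c0)] <- Lfree
    newfree[r0 + seq_len(K), c0 + seq_along(cn)] <- bl_free
    Lfree <- newfree
    fixed_cells <- rbind(fixed_cells,
                         cbind(bl_fix[, 1L] + r0, bl_fix[, 2L] + c0))
    obs <- c(obs, b$vars)
    constructs <- c(constructs, cn)
  }
  p <- length(obs); q <- length(constructs)
  dimnames(Lfree) <- list(obs, constructs)

  is_exc <- constructs %in% excrescent
  exc_of <- integer(q)
  exc_of[match(excrescent, constructs)] <- exc_block

  # free cells of Phi (lower triangle incl. diagonal)
  phi_free <- matrix(FALSE, q, q, dimnames = list(constructs, constructs))
  for (i in seq_len(q)) for (j in seq_len(i)) {
    if (!is_exc[i] && !is_exc[j]) phi_free[i, j] <- TRUE          # saturated
    else if (is_exc[i] && is_exc[j] && exc_of[i] == exc_of[j])
      phi_free[i, j] <- TRUE                                      # within block
  }

  theta_free <- !(obs %in% unlist(lapply(blocks, function(b)
    if (b$kind == "composite") b$vars else character())))

  n_lam <- sum(Lfree); n_phi <- sum(phi_free); n_theta <- sum(theta_free)
  list(blocks = blocks, obs = obs, constructs = constructs,
       structural = structural, excrescent = excrescent,
       lam_free = Lfree, lam_fixed = fixed_cells, phi_free = phi_free,
       theta_free = theta_free, p = p, q = q,
       n_lam = n_lam, n_phi = n_phi, n_theta = n_theta,
       n_par = n_lam + n_phi + n_theta)
}

# Expand a parameter vector into Lambda, Phi, theta.
ccfa_expand <- function(parm, theta_vec) {
  stopifnot(length(theta_vec) == parm$n_par)
  lam <- matrix(0, parm$p, parm$q, dimnames = dimnames(parm$lam_free))
  lam[parm$lam_fixed] <- 1
  lam[parm$lam_free] <- theta_vec[seq_len(parm$n_lam)]
  phi <- matrix(0, parm$q, parm$q,
                dimnames = dimnames(parm$phi_free))
  phi[parm$phi_free] <- theta_vec[parm$n_lam + seq_len(parm$n_phi)]
  phi <- phi + t(phi) - diag(diag(phi))
  th <- numeric(parm$p)
  th[parm$theta_free] <- theta_vec[parm$n_lam + parm$n_phi +
                                     seq_len(parm$n_theta)]
  names(th) <- parm$obs
  list(lambda = lam, phi = phi, theta = th)
}

#' Model-implied covariance matrix of a composite/factor model
#'
#' Assembles `Lambda Phi Lambda' + diag(theta)`: components reproduce exactly
#' as loading-weighted combinations of their composite of interest and
#' excrescent variables (no component-level error), while latent-block
#' indicators add diagonal measurement-error variances.
#'
#' @param lambda p x q loading matrix (observed variables by constructs,
#'   including excrescent variables).
#' @param phi q x q symmetric construct covariance matrix.
#' @param theta length-p vector of measurement-error variances (zero for
#'   components of composites).
#' @return The symmetric p x p implied covariance matrix.
#' @export
#' @examples
#' ccfa_implied_cov(diag(2), diag(2), c(0, 0))  # identity
ccfa_implied_cov <- function(lambda, phi, theta) {
  lambda <- as.matrix(lambda)
  phi <- as.matrix(phi)
  if (ncol(lambda) != nrow(phi) || nrow(phi) != ncol(phi))
    stop("dimension mismatch between loading and construct covariance matrices",
         call. = FALSE)
  if (length(theta) != nrow(lambda))
    stop("dimension mismatch between loading matrix and error variances",
         call. = FALSE)
  if (max(abs(phi - t(phi))) > 1e-10)
    stop("'phi' must be symmetric", call. = FALSE)
  sig <- lambda %*% phi %*% t(lambda) + diag(as.numeric(theta),
                                             nrow = nrow(lambda))
  (sig + t(sig)) / 2
}

# ---- discrepancy & gradient ------------------------------------------------

# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p and its analytic
# gradient; returns a big value when Sigma leaves the PD cone.
ccfa_objective <- function(parm, S, log_det_S) {
  p <- parm$p
  fn <- function(theta_vec) {
    m <- ccfa_expand(parm, theta_vec)
    sig <- m$lambda %*% m$phi %*% t(m$lambda) + diag(m$theta, p)
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    siginv <- chol2inv(ch)
    2 * sum(log(diag(ch))) + sum(siginv * S) - log_det_S - p
  }
  gr <- function(theta_vec) {
    m <- ccfa_expand(parm, theta_vec)
    sig <- m$lambda %*% m$phi %*% t(m$lambda) + diag(m$theta, p)
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(numeric(parm$n_par))
    siginv <- chol2inv(ch)
    A <- siginv - siginv %*% S %*% siginv      # dF/dSigma
    gl <- 2 * (A %*% m$lambda %*% m$phi)
    G <- t(m$lambda) %*% A %*% m$lambda
    gphi <- 2 * G - diag(diag(G))
    c(gl[parm$lam_free], gphi[parm$phi_free], diag(A)[parm$theta_free])
  }
  list(fn = fn, gr = gr)
}

# Closed-form banded factorization L_nu Phi_nu L_nu' = R of a residual
# component covariance for small K; returns NULL when it is not available or
# degenerates (caller falls back to generic starts).
ho_band_factor <- function(R) {
  K <- nrow(R)
  if (K == 2L) {
    if (abs(R[2, 2]) < 1e-8) return(NULL)
    return(list(lam = R[1, 2] / R[2, 2], phi = matrix(R[2, 2], 1, 1)))
  }
  if (K != 3L) return(NULL)
  den <- R[1, 3]^2 - R[1, 1] * R[3, 3]
  if (abs(den) < 1e-10) return(NULL)
  l23 <- (R[1, 2] * R[1, 3] - R[1, 1] * R[2, 3]) / den
  den2 <- R[2, 3] - l23 * R[3, 3]
  if (abs(den2) < 1e-10) return(NULL)
  l12 <- R[1, 3] / den2
  if (abs(l12) < 1e-6) return(NULL)
  phi <- matrix(c(R[1, 1] / l12^2, R[1, 3] / l12,
                  R[1, 3] / l12, R[3, 3]), 2, 2)
  out <- list(lam = c(l12, l23), phi = phi)
  if (any(!is.finite(unlist(out))) || any(abs(out$lam) > 100) ||
      any(diag(phi) < 1e-6)) return(NULL)
  out
}

# Quasi-Newton rounds with Newton polishing until the gradient tolerance is
# met (or the rounds are exhausted): BFGS can stall short of stationarity on
# the flat ridges this likelihood develops in small samples, so each round
# restarts it with a fresh Hessian approximation before polishing again.
ccfa_optimize <- function(obj, start, maxit = 1000L, gtol = 1e-8,
                          rounds = 3L) {
  theta <- start
  for (round in seq_len(rounds)) {
    opt <- optim(theta, obj$fn, obj$gr, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-14))
    theta <- opt$par
    for (it in seq_len(10L)) {
      g <- obj$gr(theta)
      if (max(abs(g)) < gtol) break
      H <- tryCatch(optimHess(theta, obj$fn, obj$gr,
                              control = list(ndeps = rep(1e-5,
                                                         length(theta)))),
                    error = function(e) NULL)
      if (is.null(H)) break
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      f_cur <- obj$fn(theta)
      cand <- theta - step
      ok <- FALSE
      for (half in 0:8) {
        if (obj$fn(cand) <= f_cur + 1e-12) { ok <- TRUE; break }
        cand <- theta - step / 2^(half + 1)
      }
      if (!ok) break
      theta <- cand
    }
    g <- obj$gr(theta)
    if (max(abs(g)) < gtol) break
  }
  f <- obj$fn(theta)
  list(par = theta, value = f,
       converged = is.finite(f) && max(abs(obj$gr(theta))) < gtol)
}

# Starting values. Composite blocks get moment-based starts where possible:
# the composite-of-interest loadings are estimated from the components'
# covariances with the variables outside the block (proportional to the
# loadings under the model), and the excrescent cells from a banded
# factorization of the residual component covariance. Latent blocks and
# remaining cells use generic values; construct covariances come from
# equally weighted proxy scores.
ccfa_start <- function(parm, S, exc_sign = 1) {
  lam0 <- matrix(0, parm$p, parm$q)
  lam0[parm$lam_free] <- 0.5 * exc_sign
  phi0 <- matrix(0, parm$q, parm$q)
  diag(phi0) <- 0.5
  for (bi in seq_along(parm$blocks)) {
    b <- parm$blocks[[bi]]
    if (b$kind != "composite") next
    rows <- match(b$vars, parm$obs)
    jM <- match(b$name, parm$constructs)
    K <- length(rows)
    Smm <- S[rows, rows, drop = FALSE]
    ext <- setdiff(seq_len(parm$p), rows)
    lcol <- rep(1, K)
    if (length(ext)) {
      cvec <- as.numeric(S[rows, ext, drop = FALSE] %*% rep(1, length(ext)))
      if (abs(cvec[1]) > 1e-8) {
        cand <- cvec / cvec[1]
        if (all(is.finite(cand)) && all(abs(cand) < 25)) lcol <- cand
      }
    }
    lam0[rows[-1L], jM] <- lcol[-1L]
    quad <- tryCatch(drop(t(lcol) %*% solve(Smm, lcol)),
                     error = function(e) NA_real_)
    phiM <- if (is.finite(quad) && quad > 1e-8) 1 / quad else 0.5
    phi0[jM, jM] <- phiM
    Rres <- Smm - outer(lcol, lcol) * phiM
    bf <- ho_band_factor(Rres)
    jexc <- jM + seq_len(K - 1L)
    if (!is.null(bf)) {
      lam0[cbind(rows[seq_len(K - 1L)], jexc)] <- bf$lam
      phi0[jexc, jexc] <- bf$phi
    } else {
      phi0[jexc, jexc] <- diag(pmax(diag(Rres)[-1L], 0.1), K - 1L)
    }
  }
  # construct covariances from equally weighted proxy scores
  idx_struct <- match(parm$structural, parm$constructs)
  Wp <- matrix(0, parm$p, length(idx_struct))
  for (k in seq_along(parm$blocks)) {
    b <- parm$blocks[[k]]
    rows <- match(b$vars, parm$obs)
    Wp[rows, k] <- 1 / length(rows)
  }
  phi_proxy <- t(Wp) %*% S %*% Wp
  keep_diag <- diag(phi0)[idx_struct]
  phi0[idx_struct, idx_struct] <- phi_proxy
  is_comp <- vapply(parm$blocks, function(b) b$kind == "composite",
                    logical(1))
  d0 <- diag(phi0)
  d0[idx_struct] <- ifelse(is_comp, keep_diag, diag(phi_proxy))
  diag(phi0) <- d0
  start <- numeric(parm$n_par)
  start[seq_len(parm$n_lam)] <- lam0[parm$lam_free]
  start[parm$n_lam + seq_len(parm$n_phi)] <- phi0[parm$phi_free]
  start[parm$n_lam + parm$n_phi + seq_len(parm$n_theta)] <-
    pmax(0.25 * diag(S)[parm$theta_free], 0.05)
  start
}

#' Fit the step-1 saturated composite/factor model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over the free loadings, construct covariances and error variances of the
#' H-O composite/factor model. All composites of interest and latent
#' variables covary freely (the structural part is saturated); excrescent
#' variables are uncorrelated with them by constraint. Variance parameters are
#' unconstrained during optimization so that Heywood cases surface as
#' inadmissible solutions rather than boundary artifacts.
#'
#' @param data rectangular numeric data (rows = observations); ignored when
#'   `sample_cov` is given.
#' @param blocks a [cms_model()] or list of [composite()]/[latent()] blocks.
#' @param sample_cov optional p x p sample covariance matrix to fit directly.
#' @param n number of observations (required with `sample_cov`).
#' @param start optional start vector for the free parameters.
#' @param maxit,gtol optimizer controls: BFGS iteration cap and the
#'   gradient-infinity-norm tolerance declared for convergence (Newton
#'   polishing steps are applied after BFGS until `gtol` is met).
#' @return An object of class `"ccfa_fit"`: loading matrix `lambda`, construct
#'   covariances `phi`, error variances `theta`, per-block composite loading
#'   matrices `block_lambda`, discrepancy value, `converged` and `admissible`
#'   flags (see [admissibility_check()]), sample covariance, and the free
#'   parameter vector.
#' @export
fit_ccfa <- function(data = NULL, blocks, sample_cov = NULL, n = NULL,
                     start = NULL, maxit = 1000L, gtol = 1e-8) {
  parm <- ccfa_parameterization(blocks)
  if (is.null(sample_cov)) {
    if (is.null(data)) stop("either 'data' or 'sample_cov' is required",
                            call. = FALSE)
    data <- as.data.frame(data)
    missing <- setdiff(parm$obs, names(data))
    if (length(missing))
      stop("data are missing model column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    X <- as.matrix(data[parm$obs])
    if (anyNA(X)) stop("data contain missing values", call. = FALSE)
    n <- nrow(X)
    if (n <= parm$p) stop("need more observations than observed variables",
                          call. = FALSE)
    S <- cov(X) * (n - 1) / n            # ML covariance (divisor n)
  } else {
    S <- as.matrix(sample_cov)
    if (is.null(n)) stop("'n' is required with 'sample_cov'", call. = FALSE)
    if (!is.null(rownames(S)))
      S <- S[parm$obs, parm$obs, drop = FALSE]
  }
  if (nrow(S) != parm$p)
    stop("sample covariance dimension does not match the model", call. = FALSE)
  ch_S <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch_S))
    stop("sample covariance is not positive definite (constant or collinear ",
         "columns?)", call. = FALSE)
  log_det_S <- 2 * sum(log(diag(ch_S)))

  obj <- ccfa_objective(parm, S, log_det_S)
  starts <- if (is.null(start)) {
    list(ccfa_start(parm, S), ccfa_start(parm, S, exc_sign = -1))
  } else list(start)

  best <- NULL
  for (s0 in starts) {
    res <- ccfa_optimize(obj, s0, maxit = maxit, gtol = gtol)
    if (is.null(best) || (res$converged && !best$converged) ||
        (res$converged == best$converged && res$value < best$value))
      best <- res
    if (best$converged) break
  }
  theta_hat <- best$par
  g_final <- obj$gr(theta_hat)
  converged <- best$converged

  m <- ccfa_expand(parm, theta_hat)
  implied <- ccfa_implied_cov(m$lambda, m$phi, m$theta)
  # per-block composite loading matrices (square, banded)
  block_lambda <- list()
  for (b in parm$blocks) {
    if (b$kind != "composite") next
    rows <- match(b$vars, parm$obs)
    cols <- match(c(b$name, paste0("nu", seq_len(length(b$vars) - 1L))),
                  parm$constructs)
    block_lambda[[b$name]] <- m$lambda[rows, cols, drop = FALSE]
  }
  fit <- structure(list(
    lambda = m$lambda, phi = m$phi, theta = m$theta,
    block_lambda = block_lambda, implied = implied,
    discrepancy = obj$fn(theta_hat), gradient_norm = max(abs(g_final)),
    converged = converged, n = n, S = S, parm = parm, par = theta_hat,
    logLik = -0.5 * n * (obj$fn(theta_hat) + log_det_S + parm$p +
                           parm$p * log(2 * pi))
  ), class = "ccfa_fit")
  adm <- admissibility_check(fit)
  fit$admissible <- adm$admissible
  fit$inadmissible_reason <- adm$reason
  fit
}

#' @export
print.ccfa_fit <- function(x, digits = 3, ...) {
  cat("Confirmatory composite/factor analysis (ML)\n")
  cat(sprintf("  n = %d, discrepancy F = %.6g, converged: %s, admissible: %s\n",
              x$n, x$discrepancy, x$converged, x$admissible))
  if (!x$admissible) cat("  reason:", x$inadmissible_reason, "\n")
  cat("\nLoadings:\n"); print(round(x$lambda, digits))
  cat("\nConstruct covariances:\n"); print(round(x$phi, digits))
  cat("\nError variances:\n"); print(round(x$theta, digits))
  invisible(x)
}

#' @export
coef.ccfa_fit <- function(object, ...) object$par

#' @export
logLik.ccfa_fit <- function(object, ...) {
  structure(object$logLik, df = object$parm$n_par, nobs = object$n,
            class = "logLik")
}

# ---- admissibility ---------------------------------------------------------

#' Admissibility screen for fitted models
#'
#' A solution is inadmissible if the optimizer did not converge, any estimated
#' variance is negative (Heywood case), the implied covariance matrix is not
#' positive definite, or (for composite blocks) the estimated loading matrix is
#' numerically singular so that weights cannot be extracted. This is the
#' standard screen used in SEM simulation studies; inadmissible draws are
#' discarded and redrawn by [run_condition()].
#'
#' @param fit a `"ccfa_fit"` or `"lms_fit"` object.
#' @return A list with elements `admissible` (logical) and `reason`
#'   (`"admissible"` or a short diagnostic).
#' @export
admissibility_check <- function(fit) UseMethod("admissibility_check")

#' @export
admissibility_check.ccfa_fit <- function(fit) {
  if (!isTRUE(fit$converged))
    return(list(admissible = FALSE, reason = "no convergence"))
  vars <- c(diag(fit$phi), fit$theta[fit$parm$theta_free])
  if (any(vars < 0))
    return(list(admissible = FALSE, reason = "negative variance"))
  if (!is_pd(fit$implied))
    return(list(admissible = FALSE,
                reason = "implied covariance not positive definite"))
  for (lam in fit$block_lambda) {
    if (!all(is.finite(lam)) || kappa(lam, exact = TRUE) > 1e12)
      return(list(admissible = FALSE, reason = "singular loading matrix"))
  }
  list(admissible = TRUE, reason = "admissible")
}
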