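# Internal numeric helpers shared across modules.

# Cholesky-based check for symmetric positive definiteness.
is_pd <- function(mat, tol = 0) {
  if (any(!is.finite(mat))) return(FALSE)
  ok <- TRUE
  tryCatch(chol(mat), error = function(e) ok <<- FALSE)
  ok
}

# Multivariate normal log-density via Cholesky; x a matrix (rows = obs).
dmvnorm_log <- function(x, mean, sigma) {
  x <- rbind(x)
  p <- ncol(x)
  ch <- chol(sigma)
  centered <- sweep(x, 2L, mean, "-")
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

# Row-wise log-sum-exp for a matrix of log-terms.
log_sum_exp_rows <- function(lp) {
  m <- apply(lp, 1L, max)
  m + log(rowSums(exp(lp - m)))
}

# Deterministic per-draw seed derivation: a fixed LCG-style mix of the master
# seed and the draw counter, kept inside the 32-bit integer range so redraws
# after inadmissible fits are reproducible in any execution order.
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(master) * 48271 + counter * 1000003) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
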