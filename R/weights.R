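# Step 2 of CMS: composite weights from estimated loadings, and scores.

#' Convert composite loadings to composite weights
#'
#' The weight matrix is the transpose-inverse of the composite loading matrix,
#' `W = (Lambda')^-1`; its first column holds the weights of the composite of
#' interest. The round trip `W' Lambda = I` holds to numerical tolerance.
#'
#' @param lambda square, nonsingular composite loading matrix.
#' @param cond_limit condition number above which the loadings are declared
#'   numerically singular and weight extraction refused (default `1e12`).
#' @return The K x K weight matrix.
#' @export
#' @examples
#' loadings_to_weights(diag(3))  # identity
loadings_to_weights <- function(lambda, cond_limit = 1e12) {
  lambda <- as.matrix(lambda)
  if (nrow(lambda) != ncol(lambda))
    stop("loading matrix must be square", call. = FALSE)
  if (!all(is.finite(lambda)) || kappa(lambda, exact = TRUE) > cond_limit)
    stop("loading matrix is singular or near-singular; weights are ",
         "inadmissible", call. = FALSE)
  W <- solve(t(lambda))
  dimnames(W) <- dimnames(lambda)
  W
}

#' Closed-form weights of the composite of interest for banded loadings
#'
#' For a loading matrix in the banded H-O form (full first column, diagonal,
#' and upper band at cells (j-1, j)), the first column of `(Lambda')^-1` has an
#' alternating-sign cofactor form: entry k equals
#' `(-1)^(k-1) * prod(lambda[j-1, j], j = 2..k) * prod(diag(lambda)) /
#'  (prod(lambda[j, j], j = 1..k) * det(Lambda))`.
#'
#' @param lambda square banded loading matrix (see [build_ho_pattern()]).
#' @return Length-K weight vector; equals the first column of
#'   [loadings_to_weights()] elementwise.
#' @export
first_column_weights <- function(lambda) {
  lambda <- as.matrix(lambda)
  K <- nrow(lambda)
  if (ncol(lambda) != K)
    stop("loading matrix must be square", call. = FALSE)
  if (!is_banded_ho(lambda))
    stop("loading matrix does not conform to the banded H-O pattern",
         call. = FALSE)
  det_lambda <- det(lambda)
  if (!is.finite(det_lambda) || abs(det_lambda) < .Machine$double.eps * K)
    stop("loading matrix is singular", call. = FALSE)
  dprod <- prod(diag(lambda))
  w <- numeric(K)
  for (k in seq_len(K)) {
    band <- if (k >= 2) prod(lambda[cbind(seq_len(k - 1L), 2:k)]) else 1
    w[k] <- (-1)^(k - 1) * band * dprod / prod(diag(lambda)[seq_len(k)])
  }
  w / det_lambda
}

#' Composite scores from weights
#'
#' Mean-centers the component columns (using the analysis sample's own means)
#' and combines them linearly with the weight vector, so the resulting score
#' has mean zero. Centering the observed variables means no intercepts are
#' needed for them in the subsequent structural estimation.
#'
#' @param data data frame or matrix containing the component columns.
#' @param block a [composite()] block naming the components (in weight order).
#' @param w weight vector of length K (typically the first column of
#'   [loadings_to_weights()] applied to a [fit_ccfa()] loading estimate).
#' @return An object of class `"composite_score"`: list with `score` (numeric
#'   vector, mean zero), `weights`, and `centers` (component means removed).
#' @export
compute_scores <- function(data, block, w) {
  stopifnot(inherits(block, "cms_block"), block$kind == "composite")
  data <- as.data.frame(data)
  missing <- setdiff(block$vars, names(data))
  if (length(missing))
    stop("data are missing component column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- as.matrix(data[block$vars])
  if (anyNA(X)) stop("components contain missing values", call. = FALSE)
  if (length(w) != ncol(X))
    stop("weight vector length does not match the number of components",
         call. = FALSE)
  centers <- colMeans(X)
  score <- as.numeric(scale(X, center = centers, scale = FALSE) %*% w)
  structure(list(score = score, weights = as.numeric(w), centers = centers,
                 emergent = block$name),
            class = "composite_score")
}

#' @export
print.composite_score <- function(x, digits = 4, ...) {
  cat("Composite score for '", x$emergent, "' (n = ", length(x$score), ")\n",
      sep = "")
  cat("  weights:", paste(round(x$weights, digits), collapse = ", "), "\n")
  cat("  sd(score):", round(sd(x$score), digits), "\n")
  invisible(x)
}
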