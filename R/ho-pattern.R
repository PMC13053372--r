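#' Banded composite-loading pattern of the refined H-O specification
#'
#' For a composite block with K ordered components, the Henseler-Ogasawara
#' specification extracts K composites: the composite of interest plus K-1
#' auxiliary "excrescent" variables that absorb the component variance and
#' covariance not carried by the composite of interest. Identification is
#' achieved by a banded loading pattern:
#'
#' * every diagonal cell (k, k) is fixed to one (one fixed loading per
#'   composite, setting its scale),
#' * column 1 (the composite of interest) is free in rows 2..K,
#' * excrescent column j (j >= 2) is nonzero exactly in rows j-1 and j, the
#'   off-diagonal cell (j-1, j) being free,
#' * all other cells are structural zeros.
#'
#' Hence each excrescent variable relates to exactly two components, each
#' component loads on at most two excrescent variables, and the first and last
#' components touch exactly one excrescent variable each.
#'
#' @param block a [composite()] block (K >= 2 components).
#' @return An object of class `"ho_pattern"`: a K x K character matrix with
#'   entries `"1"` (fixed to one), `"free"`, or `"0"` (structural zero), with
#'   component names as row names and construct names (`<name>`,
#'   `nu1` ... `nu(K-1)`) as column names.
#' @export
#' @examples
#' build_ho_pattern(composite("M", c("m1", "m2", "m3")))
build_ho_pattern <- function(block) {
  if (!inherits(block, "cms_block") || block$kind != "composite")
    stop("'block' must be a composite() block", call. = FALSE)
  K <- length(block$vars)
  if (K < 2L) stop("a composite needs at least two components", call. = FALSE)
  pat <- matrix("0", K, K,
                dimnames = list(block$vars,
                                c(block$name, paste0("nu", seq_len(K - 1L)))))
  diag(pat) <- "1"
  pat[2:K, 1L] <- "free"
  for (j in 2:K) pat[j - 1L, j] <- "free"
  structure(pat, class = c("ho_pattern", class(pat)),
            emergent = block$name, components = block$vars)
}

#' @export
print.ho_pattern <- function(x, ...) {
  cat("H-O composite loading pattern for '", attr(x, "emergent"), "' (K = ",
      nrow(x), ")\n", sep = "")
  m <- unclass(x)
  attr(m, "emergent") <- attr(m, "components") <- NULL
  print(m)
  invisible(x)
}

# Logical mask of free cells in an ho_pattern.
ho_free <- function(pattern) unclass(pattern) == "free"

# Numeric loading matrix from a pattern and values for the free cells
# (filled column-major along the free mask); fixed cells are exactly 1.
ho_lambda <- function(pattern, free_values) {
  free <- ho_free(pattern)
  if (length(free_values) != sum(free))
    stop("expected ", sum(free), " free loading values", call. = FALSE)
  lam <- matrix(0, nrow(pattern), ncol(pattern), dimnames = dimnames(pattern))
  lam[unclass(pattern) == "1"] <- 1
  lam[free] <- free_values
  lam
}

# TRUE if a square numeric matrix conforms to the banded H-O shape
# (full first column allowed; upper band at (j-1, j); zeros elsewhere).
is_banded_ho <- function(lambda, tol = 1e-12) {
  K <- nrow(lambda)
  if (ncol(lambda) != K) return(FALSE)
  allowed <- matrix(FALSE, K, K)
  allowed[, 1L] <- TRUE
  diag(allowed) <- TRUE
  if (K >= 2L) for (j in 2:K) allowed[j - 1L, j] <- TRUE
  all(abs(lambda[!allowed]) <= tol)
}
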