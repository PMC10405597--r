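#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes `||A x - b||_2` subject to `x >= 0`. This is the fitting
#' engine behind all ensemble weight optimizations in the package: columns
#' of `A` hold predicted P(r) or I(q) profiles, `b` the experimental
#' target, and the solution the population fractions. When `weights`
#' (typically 1/sigma) are supplied, rows of `A` and `b` are multiplied by
#' them before solving.
#'
#' The solution satisfies the Karush-Kuhn-Tucker conditions of the
#' constrained problem: the gradient of the squared residual is (to solver
#' tolerance) zero along positive coordinates and non-negative along zero
#' ones.
#'
#' @param design_columns numeric matrix A (m x n).
#' @param target numeric vector b (length m).
#' @param weights optional row weights (length m).
#' @param tol dual-feasibility tolerance (default scaled machine epsilon).
#' @return list `x` (coefficients, length n), `residual_norm`
#'   (`||Ax - b||` on the weighted scale), `passive` (indices of positive
#'   coordinates).
#' @export
nnls_solve <- function(design_columns, target, weights = NULL, tol = NULL) {
  A <- as.matrix(design_columns)
  b <- as.numeric(target)
  if (nrow(A) != length(b)) stop("grid mismatch between design columns and target")
  if (all(b == 0)) stop("all-zero target")
  if (!is.null(weights)) {
    if (length(weights) != length(b)) stop("weights misaligned with target")
    A <- A * weights
    b <- b * weights
  }
  m <- nrow(A); n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(m, n)
  x <- numeric(n)
  passive <- logical(n)          # active-set bookkeeping: TRUE = unconstrained
  w <- drop(crossprod(A, b))     # negative gradient at x = 0
  iter <- 0L; max_iter <- 30L * n
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    w_free <- w; w_free[passive] <- -Inf
    j <- which.max(w_free)
    if (!is.finite(w_free[j]) || w_free[j] <= tol) break
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      sol <- tryCatch(qr.solve(A[, P, drop = FALSE], b),
                      error = function(e) rep(0, length(P)))
      z[P] <- sol
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      denom <- x[neg] - z[neg]
      a_step <- suppressWarnings(min(x[neg][denom > 0] / denom[denom > 0]))
      if (!is.finite(a_step)) { passive[neg] <- FALSE; x[neg] <- 0; next }
      x <- x + a_step * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  r <- b - drop(A %*% x)
  list(x = x, residual_norm = sqrt(sum(r^2)), passive = which(x > 0))
}
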