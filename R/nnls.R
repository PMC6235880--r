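#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves min ||A x - b||_2 subject to x >= 0. This is the numerical core
#' of the signature decomposition: A holds signature profiles, b a
#' mutational catalog, and x the fitted exposures.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @param tol dual-feasibility tolerance; default scales with the problem.
#' @return list with \code{x} (solution), \code{residual}
#'   (||A x - b||_2) and \code{iterations}.
#' @export
nnls_fit <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  if (is.null(tol))
    tol <- 10 * .Machine$double.eps * max(colSums(abs(A))) * max(dim(A))
  x <- numeric(n)
  P <- logical(n)
  iter <- 0L
  itmax <- 30L * n
  repeat {
    w <- crossprod(A, b - A %*% x)[, 1]
    if (!any(!P) || max(w[!P]) <= tol) break
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > itmax) stop("NNLS failed to converge")
      s <- numeric(n)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[P][is.na(s[P])] <- 0  # rank-deficient columns contribute nothing
      if (min(s[P]) > 0) {
        x <- s
        break
      }
      neg <- P & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
  }
  list(x = x, residual = sqrt(sum((A %*% x - b)^2)), iterations = iter)
}
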