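# Lawson-Hanson active-set nonnegative least squares.
# Small dense problems only (deconvolution over 12 cell types,
# sign-constrained refits over a few dozen CpGs), so plain R is adequate.

#' Nonnegative least squares
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0` by the Lawson-Hanson
#' active-set algorithm.
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector (length m).
#' @param tol Dual-feasibility tolerance; default scales with the problem.
#' @param max_iter Outer iteration cap; default `10 * n`.
#' @return List with `x` (solution), `residual_norm`, `iterations`.
#' @export
nnls_solve <- function(A, b, tol = NULL, max_iter = NULL) {
  A <- as.matrix(A); b <- as.numeric(b)
  m <- nrow(A); n <- ncol(A)
  if (length(b) != m) stop_input("length(b) != nrow(A)")
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(crossprod(A, b)), 1) * n)
  max_iter <- max_iter %||% (10L * n)

  x <- rep(0, n)
  passive <- rep(FALSE, n)
  resid <- b
  iter <- 0L
  repeat {
    wgrad <- drop(crossprod(A, resid))
    candidates <- which(!passive & wgrad > tol)
    if (!length(candidates) || iter >= max_iter) break
    iter <- iter + 1L
    passive[candidates[which.max(wgrad[candidates])]] <- TRUE
    repeat {
      P <- which(passive)
      z <- rep(0, n)
      sol <- tryCatch(qr.solve(A[, P, drop = FALSE], b),
                      error = function(e) rep(0, length(P)))
      z[P] <- sol
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio[!is.finite(ratio)] <- 0
      a_step <- min(ratio)
      x <- x + a_step * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    resid <- b - drop(A %*% x)
  }
  list(x = x, residual_norm = sqrt(sum(resid^2)), iterations = iter)
}
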