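# Internal numerical helpers shared across modules.

# Instrument dynamic range in dB; 0 dB = brightest stimulus, 40 dB = dimmest.
.DB_MIN <- 0
.DB_MAX <- 40

.clipDb <- function(x, lo = .DB_MIN, hi = .DB_MAX) pmin(pmax(x, lo), hi)

#' Minimum-norm least squares via SVD pseudoinverse
#'
#' Solves `coef %*% A ~ Y` in the least-squares sense, returning the
#' minimum-Frobenius-norm coefficient matrix when `A` is rank deficient.
#'
#' @param A design matrix, m x N (predictors in rows, observations in columns).
#' @param Y target matrix, p x N.
#' @param tol relative singular value cutoff.
#' @return p x m coefficient matrix.
#' @keywords internal
#' @noRd
.lsMinNorm <- function(A, Y, tol = 1e-10) {
  A <- as.matrix(A)
  Y <- as.matrix(Y)
  stopifnot(ncol(A) == ncol(Y))
  sv <- svd(A)
  if (length(sv$d) == 0L || sv$d[1] == 0) {
    return(matrix(0, nrow(Y), nrow(A)))
  }
  keep <- sv$d > tol * sv$d[1]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  (Y %*% v) %*% (t(u) / d)
}

#' Deterministic child seed derivation
#'
#' Hash-style derivation of per-fold / per-field / per-location seeds from a
#' master seed, so adding strategies or fields does not perturb existing
#' random draws. Always returns a positive integer below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param ... one or more integer indices naming the stream (e.g. fold,
#'   field, location).
#' @return an integer seed.
#' @export
childSeed <- function(seed, ...) {
  idx <- c(...)
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in idx) {
    s <- (s * 48271 + (as.double(i) + 1) * 16807) %% 2147483647
  }
  as.integer(s + 1)
}

# stops unless x is a finite numeric vector of length n
.checkFieldVector <- function(x, n, what = "field") {
  if (!is.numeric(x) || length(x) != n) {
    stop(sprintf("%s must be a numeric vector of length %d", what, n),
         call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
  invisible(TRUE)
}
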