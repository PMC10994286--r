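#' Principal component basis of a visual field dataset
#'
#' Eigendecomposition of the sample covariance of the training fields.
#' With centered data `B = X - mu`, the covariance `S = B B' / (N - 1)` is
#' decomposed and the top `n` eigenvectors retained. The components are the
#' "eigen-visual fields": archetypical patterns of field loss ordered by
#' explained variance. The basis is shared and frozen across all measured
#' subsets when used inside transformed-target principal component
#' regression (see [fitTTPCR()]).
#'
#' @slot mu numeric per-location training mean (dB).
#' @slot components locations x n orthonormal eigenvector matrix.
#' @slot eigenvalues the n retained eigenvalues, non-increasing.
#' @slot allEigenvalues full eigenvalue spectrum (for compressibility
#'   curves).
#' @export
setClass("PCABasis",
  slots = c(
    mu = "numeric",
    components = "matrix",
    eigenvalues = "numeric",
    allEigenvalues = "numeric"
  )
)

setValidity("PCABasis", function(object) {
  W <- object@components
  msg <- character(0)
  if (length(object@mu) != nrow(W)) {
    msg <- c(msg, "mu length must match component rows")
  }
  if (ncol(W) != length(object@eigenvalues)) {
    msg <- c(msg, "one eigenvalue per retained component")
  }
  gram <- crossprod(W)
  if (max(abs(gram - diag(ncol(W)))) > 1e-8) {
    msg <- c(msg, "components must be orthonormal")
  }
  ev <- object@eigenvalues
  if (any(ev < -1e-8) || is.unsorted(rev(ev), strictly = FALSE)) {
    msg <- c(msg, "eigenvalues must be non-negative and non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PCABasis-class retained embedding dimension
#' @param x,object a `PCABasis`.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @rdname PCABasis-class
#' @export
setMethod("embeddingDim", "PCABasis", function(x) ncol(x@components))

#' @rdname PCABasis-class
#' @export
setMethod("show", "PCABasis", function(object) {
  ev <- object@allEigenvalues
  cat(sprintf("PCABasis: %d of %d components, %.1f%% variance retained\n",
              embeddingDim(object), length(ev),
              100 * sum(object@eigenvalues) / max(sum(ev), .Machine$double.eps)))
})

#' Fit a principal component basis
#'
#' Deterministic sign convention: each component's entry of largest absolute
#' value is made positive, so repeated fits are bit-identical.
#'
#' @param x a [VFDataset-class] or locations x fields matrix (at least two
#'   fields).
#' @param n embedding dimension, `1 <= n <= nrow(x)`.
#' @return a [PCABasis-class].
#' @export
fitPCA <- function(x, n) {
  X <- if (methods::is(x, "VFDataset")) dbValues(x) else as.matrix(x)
  d <- nrow(X)
  N <- ncol(X)
  if (N < 2L) stop("need at least two training fields")
  if (n < 1L || n > d) stop(sprintf("embedding dimension must be in [1, %d]", d))
  mu <- rowMeans(X)
  B <- X - mu
  S <- tcrossprod(B) / (N - 1)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  W <- eig$vectors[, seq_len(n), drop = FALSE]
  for (j in seq_len(n)) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  methods::new("PCABasis", mu = mu, components = W,
               eigenvalues = ev[seq_len(n)], allEigenvalues = ev)
}

#' Project fields into / out of a PCA basis
#'
#' `pcaEmbed` maps fields to their low-dimensional embeddings
#' `t = W' (x - mu)`; `pcaExpand` maps embeddings back,
#' `x = W t + mu`. `pcaExpand(pcaEmbed(x))` is the orthogonal projection of
#' `x` onto the basis' affine subspace and is idempotent.
#'
#' @param basis a [PCABasis-class].
#' @param x numeric field vector or locations x fields matrix.
#' @param t numeric embedding vector or n x fields matrix.
#' @return embedding(s) / reconstructed field(s), matching the input shape.
#' @export
pcaEmbed <- function(basis, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(X) != length(basis@mu)) stop("field dimension mismatch")
  T <- crossprod(basis@components, X - basis@mu)
  if (vec) drop(T) else T
}

#' @rdname pcaEmbed
#' @export
pcaExpand <- function(basis, t) {
  vec <- is.null(dim(t))
  T <- if (vec) matrix(t, ncol = 1) else as.matrix(t)
  if (nrow(T) != embeddingDim(basis)) stop("embedding dimension mismatch")
  X <- basis@components %*% T + basis@mu
  if (vec) drop(X) else X
}

#' PCA compressibility curve
#'
#' Training reconstruction RMSE (dB, pooled over locations and fields) when
#' keeping `1..d` principal components. Steeply decreasing then flat for
#' strongly correlated field data; exactly zero with all components.
#'
#' @param x a [VFDataset-class] or matrix.
#' @return numeric vector of length `nrow(x)`, RMSE per embedding dimension.
#' @export
compressibilityCurve <- function(x) {
  X <- if (methods::is(x, "VFDataset")) dbValues(x) else as.matrix(x)
  d <- nrow(X)
  N <- ncol(X)
  basis <- fitPCA(X, d)
  ev <- basis@allEigenvalues
  # residual sum of squares after keeping n comps = (N-1) * sum(ev[(n+1):d])
  tail_ss <- rev(cumsum(rev(ev)))          # sum(ev[n:d]) at index n
  rss <- c(tail_ss[-1], 0) * (N - 1)
  sqrt(rss / (d * N))
}
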