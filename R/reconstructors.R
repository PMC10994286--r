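#' Reconstruction models mapping a measured subset to a full field
#'
#' A `VFReconstructor` predicts all grid thresholds from the thresholds
#' measured at an ordered subset of locations. Four kinds are provided:
#'
#' * **mean** ([fitMean()]) — ignores measurements; returns the training
#'   hill of vision (per-location mean).
#' * **lr** ([fitLR()]) — ordinary linear regression `x = D s + beta`,
#'   solved by minimum-norm least squares.
#' * **ttpcr** ([fitTTPCR()]) — transformed-target principal component
#'   regression: linear regression from `s` to the PCA embeddings of the
#'   full field, expanded back through the frozen basis,
#'   `x = W (D s + beta) + mu`.
#' * **pls** ([fitPLS()]) — rank-constrained predictor `x = W D s + beta`
#'   fitted iteratively by NIPALS partial least squares.
#'
#' Predictions are clipped to the instrument range \[0, 40\] dB at
#' [reconstruct()] time only; fitting uses unclipped values.
#'
#' @slot subset ordered integer indices of the measured locations.
#' @slot d integer, full field dimension.
#' @slot trainMSE mean squared training error over the whole field (dB^2).
#' @name VFReconstructor-class
#' @export
setClass("VFReconstructor",
  representation("VIRTUAL",
    subset = "integer",
    d = "integer",
    trainMSE = "numeric"
  )
)

#' @rdname VFReconstructor-class
#' @slot hill per-location training mean (dB).
#' @export
setClass("MeanReconstructor", contains = "VFReconstructor",
  slots = c(hill = "numeric"))

#' @rdname VFReconstructor-class
#' @slot D weight matrix.
#' @slot beta bias vector.
#' @export
setClass("LRReconstructor", contains = "VFReconstructor",
  slots = c(D = "matrix", beta = "numeric"))

#' @rdname VFReconstructor-class
#' @slot basis frozen [PCABasis-class] shared across subsets.
#' @export
setClass("TTPCRReconstructor", contains = "VFReconstructor",
  slots = c(D = "matrix", beta = "numeric", basis = "PCABasis"))

#' @rdname VFReconstructor-class
#' @slot W d x n left factor.
#' @slot n embedding dimension.
#' @slot converged FALSE when any NIPALS component hit the iteration cap.
#' @export
setClass("PLSReconstructor", contains = "VFReconstructor",
  slots = c(W = "matrix", D = "matrix", beta = "numeric",
            n = "integer", converged = "logical"))

setValidity("VFReconstructor", function(object) {
  if (anyDuplicated(object@subset)) return("subset indices must be unique")
  if (length(object@subset) &&
      (min(object@subset) < 1L || max(object@subset) > object@d)) {
    return("subset indices out of range")
  }
  TRUE
})

#' @describeIn VFReconstructor-class model kind as a string
#' @param x,object a reconstructor.
#' @export
setGeneric("reconstructorKind", function(x) standardGeneric("reconstructorKind"))
setMethod("reconstructorKind", "MeanReconstructor", function(x) "mean")
setMethod("reconstructorKind", "LRReconstructor", function(x) "lr")
setMethod("reconstructorKind", "TTPCRReconstructor", function(x) "ttpcr")
setMethod("reconstructorKind", "PLSReconstructor", function(x) "pls")

#' @describeIn VFReconstructor-class measured-location indices
#' @export
setGeneric("measuredSubset", function(x) standardGeneric("measuredSubset"))
setMethod("measuredSubset", "VFReconstructor", function(x) x@subset)

#' @describeIn VFReconstructor-class training mean squared error (dB^2)
#' @export
setGeneric("trainingMSE", function(x) standardGeneric("trainingMSE"))
setMethod("trainingMSE", "VFReconstructor", function(x) x@trainMSE)

setMethod("show", "VFReconstructor", function(object) {
  cat(sprintf("<%s reconstructor> subset size %d of %d, training MSE %.4g dB^2\n",
              reconstructorKind(object), length(object@subset), object@d,
              object@trainMSE))
})

.asMatrixX <- function(x) {
  if (methods::is(x, "VFDataset")) dbValues(x) else as.matrix(x)
}

.trainMSE <- function(pred, X) mean((pred - X)^2)

#' Fit the hill-of-vision baseline reconstructor
#'
#' @param x training [VFDataset-class] or matrix.
#' @return a `MeanReconstructor`.
#' @export
fitMean <- function(x) {
  X <- .asMatrixX(x)
  hill <- rowMeans(X)
  methods::new("MeanReconstructor", subset = integer(0), d = nrow(X),
               hill = hill, trainMSE = .trainMSE(hill, X))
}

# augmented design: measured rows plus an intercept row
.designS <- function(X, subset) {
  rbind(X[subset, , drop = FALSE], rep(1, ncol(X)))
}

#' Fit the ordinary linear regression reconstructor
#'
#' Minimizes mean squared training error of `x = D s + beta` over the
#' training fields; minimum-norm least squares handles rank deficiency
#' (e.g. fewer training fields than measured locations).
#'
#' @param x training [VFDataset-class] or matrix (>= 2 fields).
#' @param subset ordered integer indices of the measured locations.
#' @return an `LRReconstructor`.
#' @export
fitLR <- function(x, subset) {
  X <- .asMatrixX(x)
  subset <- as.integer(subset)
  if (length(subset) < 1L) stop("subset must contain at least one location")
  if (ncol(X) < 2L) stop("need at least two training fields")
  coef <- .lsMinNorm(.designS(X, subset), X)
  k <- length(subset)
  D <- coef[, seq_len(k), drop = FALSE]
  beta <- coef[, k + 1L]
  pred <- D %*% X[subset, , drop = FALSE] + beta
  methods::new("LRReconstructor", subset = subset, d = nrow(X),
               D = D, beta = beta, trainMSE = .trainMSE(pred, X))
}

#' Fit the transformed-target principal component regressor
#'
#' Regresses the PCA embeddings of the full training fields on the measured
#' subset (`t = D s + beta`, least squares), then reconstructs through the
#' frozen basis: `x = W (D s + beta) + mu`. The basis is fitted once on the
#' training targets and shared across all subsets.
#'
#' @param x training [VFDataset-class] or matrix.
#' @param subset ordered integer indices of the measured locations.
#' @param basis a [PCABasis-class] fitted on the same training targets.
#' @return a `TTPCRReconstructor`.
#' @export
fitTTPCR <- function(x, subset, basis) {
  X <- .asMatrixX(x)
  subset <- as.integer(subset)
  if (length(subset) < 1L) stop("subset must contain at least one location")
  if (length(basis@mu) != nrow(X)) stop("basis/target dimension mismatch")
  T <- pcaEmbed(basis, X)
  if (is.null(dim(T))) T <- matrix(T, nrow = 1)
  coef <- .lsMinNorm(.designS(X, subset), T)
  k <- length(subset)
  D <- coef[, seq_len(k), drop = FALSE]
  beta <- coef[, k + 1L]
  pred <- pcaExpand(basis, D %*% X[subset, , drop = FALSE] + beta)
  methods::new("TTPCRReconstructor", subset = subset, d = nrow(X),
               D = D, beta = beta, basis = basis,
               trainMSE = .trainMSE(pred, X))
}

# NIPALS PLS2 with both-block deflation.
# Xb: N x k predictor block (centered), Yb: N x d response block (centered).
# Returns weights R (k x n) and loadings C (d x n) such that the fitted
# centered response is (Xb %*% R) %*% t(C).
.nipals <- function(Xb, Yb, n, tol = 1e-6, maxit = 500) {
  k <- ncol(Xb)
  d <- ncol(Yb)
  Wmat <- matrix(0, k, n)
  Pmat <- matrix(0, k, n)
  Cmat <- matrix(0, d, n)
  converged <- TRUE
  ncomp <- 0L
  for (h in seq_len(n)) {
    # start from the response column with the largest variance
    u <- Yb[, which.max(colSums(Yb^2))]
    if (sum(u^2) < 1e-12 || sum(Xb^2) < 1e-12) break
    w <- rep(0, k)
    for (it in seq_len(maxit)) {
      w_new <- crossprod(Xb, u)
      nw <- sqrt(sum(w_new^2))
      if (nw < 1e-12) break
      w_new <- w_new / nw
      tt <- Xb %*% w_new
      cc <- crossprod(Yb, tt) / sum(tt^2)
      u <- Yb %*% cc / sum(cc^2)
      if (sqrt(sum((w_new - w)^2)) < tol) {
        w <- w_new
        break
      }
      w <- w_new
      if (it == maxit) converged <- FALSE
    }
    if (sqrt(sum(w^2)) < 1e-12) break
    tt <- Xb %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    p <- crossprod(Xb, tt) / tt2
    cc <- crossprod(Yb, tt) / tt2
    Xb <- Xb - tt %*% t(p)
    Yb <- Yb - tt %*% t(cc)
    Wmat[, h] <- w
    Pmat[, h] <- p
    Cmat[, h] <- cc
    ncomp <- h
  }
  if (ncomp == 0L) {
    return(list(R = matrix(0, k, 0), C = matrix(0, d, 0),
                converged = converged, ncomp = 0L))
  }
  Wh <- Wmat[, seq_len(ncomp), drop = FALSE]
  Ph <- Pmat[, seq_len(ncomp), drop = FALSE]
  Ch <- Cmat[, seq_len(ncomp), drop = FALSE]
  R <- Wh %*% solve(crossprod(Ph, Wh))
  list(R = R, C = Ch, converged = converged, ncomp = ncomp)
}

#' Fit the partial least squares reconstructor
#'
#' Rank-`n` linear predictor `x = W D s + beta` fitted iteratively by
#' NIPALS PLS2 with both-block deflation (convergence tolerance `1e-6` on
#' the weight vectors, at most 500 iterations per component; on
#' non-convergence the best iterate is kept and a warning raised). With
#' `n = min(d, |subset|)` (full rank) the predictions coincide with
#' ordinary linear regression.
#'
#' @param x training [VFDataset-class] or matrix.
#' @param subset ordered integer indices of the measured locations.
#' @param n embedding dimension, `1 <= n <= min(d, |subset|, N - 1)`.
#' @param tol,maxit NIPALS convergence controls.
#' @return a `PLSReconstructor`.
#' @export
fitPLS <- function(x, subset, n, tol = 1e-6, maxit = 500) {
  X <- .asMatrixX(x)
  subset <- as.integer(subset)
  if (length(subset) < 1L) stop("subset must contain at least one location")
  N <- ncol(X)
  nmax <- min(nrow(X), length(subset), N - 1L)
  if (n < 1L || n > nmax) {
    stop(sprintf("embedding dimension must be in [1, %d]", nmax))
  }
  S <- t(X[subset, , drop = FALSE])   # N x k predictor block
  Y <- t(X)                           # N x d response block
  sbar <- colMeans(S)
  ybar <- colMeans(Y)
  fit <- .nipals(sweep(S, 2, sbar), sweep(Y, 2, ybar), n,
                 tol = tol, maxit = maxit)
  if (!fit$converged) {
    warning("NIPALS did not fully converge; returning best iterate")
  }
  W <- fit$C                                   # d x n
  D <- t(fit$R)                                # n x k
  beta <- ybar - as.numeric(W %*% (D %*% sbar))
  pred <- W %*% (D %*% X[subset, , drop = FALSE]) + beta
  methods::new("PLSReconstructor", subset = subset, d = nrow(X),
               W = W, D = D, beta = beta, n = as.integer(fit$ncomp),
               converged = fit$converged, trainMSE = .trainMSE(pred, X))
}

#' Reconstruct a full field from measured values
#'
#' @param model a fitted [VFReconstructor-class].
#' @param s numeric vector of measured thresholds, in the order of
#'   `measuredSubset(model)` (ignored, and may be empty, for the mean
#'   baseline).
#' @param clip clip the prediction to the instrument range \[0, 40\] dB
#'   (default TRUE).
#' @return numeric full-field estimate.
#' @export
setGeneric("reconstruct", function(model, s, clip = TRUE) {
  standardGeneric("reconstruct")
})

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "MeanReconstructor", function(model, s, clip = TRUE) {
  out <- model@hill
  if (clip) .clipDb(out) else out
})

.checkS <- function(model, s) {
  if (length(s) != length(model@subset)) {
    stop("measured vector length must equal the model's subset size")
  }
}

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "LRReconstructor", function(model, s, clip = TRUE) {
  .checkS(model, s)
  out <- as.numeric(model@D %*% s + model@beta)
  if (clip) .clipDb(out) else out
})

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "TTPCRReconstructor", function(model, s, clip = TRUE) {
  .checkS(model, s)
  t_hat <- as.numeric(model@D %*% s + model@beta)
  out <- pcaExpand(model@basis, t_hat)
  if (clip) .clipDb(out) else out
})

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "PLSReconstructor", function(model, s, clip = TRUE) {
  .checkS(model, s)
  out <- as.numeric(model@W %*% (model@D %*% s) + model@beta)
  if (clip) .clipDb(out) else out
})
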