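# Shared fixtures, all generated in code.

# rank-1 planted data: x_j = mu + c_j * v  (no noise)
rank1Data <- function(d = 54, N = 20, seed = 99) {
  set.seed(seed)
  mu <- runif(d, 20, 30)
  v <- rnorm(d)
  v <- v / sqrt(sum(v^2))
  cs <- rnorm(N, 0, 4)
  X <- mu + outer(v, cs)
  list(X = X, mu = mu, v = v, cs = cs)
}

# small mixed-severity dataset, memoized per session
.fixtureCache <- new.env()
cachedFields <- function(nEyes, seed, visitsPerEye = 1) {
  key <- sprintf("f_%d_%d_%d", nEyes, seed, visitsPerEye)
  if (is.null(.fixtureCache[[key]])) {
    .fixtureCache[[key]] <- generateFields(
      generatorConfig(nEyes = nEyes, visitsPerEye = visitsPerEye),
      seed = seed)
  }
  .fixtureCache[[key]]
}

# a toy 6-location grid (2 x 3 block, one per quadrant-ish), for greedy
# oracle tests at enumerable scale
toyGrid6 <- function() {
  VFGrid(cbind(x = c(-9, -3, 3, -9, -3, 3),
               y = c(3, 3, 3, -3, -3, -3)))
}

# correlated toy data on d locations
toyData <- function(d = 6, N = 30, seed = 5) {
  set.seed(seed)
  F <- matrix(rnorm(d * 2), d, 2)
  Z <- matrix(rnorm(2 * N), 2, N)
  25 + F %*% Z + matrix(rnorm(d * N, 0, 0.3), d, N)
}

# independent reduced-rank-regression oracle (Eckart-Young on OLS fit)
rrrMSE <- function(X, subset, n) {
  S <- X[subset, , drop = FALSE]
  Y <- X
  Sc <- S - rowMeans(S)
  Yc <- Y - rowMeans(Y)
  G <- Sc %*% t(Sc)
  Bols <- Yc %*% t(Sc) %*% solve(G + 1e-10 * diag(nrow(G)))
  Fhat <- Bols %*% Sc
  sv <- svd(Fhat)
  U <- sv$u[, seq_len(n), drop = FALSE]
  mean((Yc - U %*% crossprod(U, Fhat))^2)
}

# independent re-implementation of one greedy step: brute force over all
# remaining candidates with a direct least-squares fit
bruteNext <- function(X, chosen, kind = "lr", basis = NULL) {
  cand <- setdiff(seq_len(nrow(X)), chosen)
  mses <- vapply(cand, function(j) {
    sub <- c(chosen, j)
    A <- rbind(X[sub, , drop = FALSE], 1)
    Y <- if (kind == "ttpcr") {
      crossprod(basis@components, X - basis@mu)
    } else {
      X
    }
    coef <- Y %*% MASS::ginv(A)
    pred <- coef %*% A
    if (kind == "ttpcr") pred <- basis@components %*% pred + basis@mu
    mean((pred - X)^2)
  }, numeric(1))
  cand[which.min(mses)]
}

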