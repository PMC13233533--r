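# Independent reference solver for the SLIM problem: proximal gradient
# (ISTA) on the full weight matrix with a small fixed step. Deliberately
# naive and slow — it shares no code with the coordinate-descent fit it
# checks.
pg_slim_reference <- function(A, beta, lam, iters = 1e5) {
  A <- as.matrix(A)
  G <- crossprod(A)
  n <- ncol(A)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) + beta
  step <- 1 / L
  W <- matrix(0, n, n)
  for (it in seq_len(iters)) {
    grad <- G %*% W - G + beta * W
    W <- pmax(W - step * grad - step * lam, 0)
    diag(W) <- 0
  }
  W
}

# Worst KKT residual of a candidate W for the column-separable SLIM problem:
# for active coefficients |grad + lam| must vanish, for zero coefficients
# grad + lam must be nonnegative.
slim_kkt_residual <- function(A, W, beta, lam) {
  A <- as.matrix(A)
  G <- crossprod(A)
  grad <- G %*% W - G + beta * W
  worst <- 0
  for (u in seq_len(ncol(A))) {
    g <- grad[, u] + lam
    w <- W[, u]
    free <- setdiff(which(w > 0), u)
    zero <- setdiff(which(w == 0), u)
    if (length(free)) worst <- max(worst, max(abs(g[free])))
    if (length(zero)) worst <- max(worst, max(0, -min(g[zero])))
  }
  worst
}

# Random small SLIM instance on the normalized scale.
random_slim_instance <- function(seed) {
  set.seed(seed)
  m <- sample(6:12, 1)
  n <- sample(3:6, 1)
  A <- matrix(rnorm(m * n), m, n)
  A <- scale(A) * sqrt(m / (m - 1))   # population-SD z-scores per column
  attr(A, "scaled:center") <- NULL
  attr(A, "scaled:scale") <- NULL
  list(A = A, m = m, n = n)
}
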