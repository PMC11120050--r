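# Shared helpers: independent brute-force oracles and small random inputs.

# Central finite difference of a scalar function at selected coordinates.
numeric_grad <- function(f, x, idx = seq_along(x), h = 1e-5) {
  vapply(idx, function(i) {
    up <- x
    up[i] <- up[i] + h
    dn <- x
    dn[i] <- dn[i] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

rand_matrix <- function(m, n, seed) {
  set.seed(seed)
  matrix(runif(m * n), m, n)
}

rand_mask <- function(m, n, p_obs = 0.7, seed = 1) {
  set.seed(seed)
  M <- matrix(rbinom(m * n, 1, p_obs), m, n)
  if (all(M == 1)) M[1, 1] <- 0
  if (all(M == 0)) M[1, 1] <- 1
  M
}

# Textbook pairwise Pearson correlation, written independently of the
# implementation under test.
brute_correlation <- function(X) {
  n <- ncol(X)
  r <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xi <- X[, i] - mean(X[, i])
    xj <- X[, j] - mean(X[, j])
    r[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  r
}

# Element-by-element loss summations used as oracles in the loss tests.
brute_adv_loss <- function(M, M_hat) {
  tot <- 0
  cnt <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (M[i, j] == 0) {
      tot <- tot - log(min(max(M_hat[i, j], 1e-8), 1 - 1e-8))
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

brute_rec_loss <- function(X, X_hat, M) {
  tot <- 0
  cnt <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (M[i, j] == 1) {
      tot <- tot + (X[i, j] - X_hat[i, j])^2
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

brute_rmse_missing <- function(X, X_hat, M) {
  errs <- c()
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (M[i, j] == 0) errs <- c(errs, (X[i, j] - X_hat[i, j])^2)
  }
  sqrt(mean(errs))
}
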