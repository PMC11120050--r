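# Classical comparator imputers: column mean and iterative truncated SVD.

#' Column-mean imputation
#'
#' Replaces every missing cell with the mean of its column's observed
#' values. Observed entries are preserved bit-exactly; the operation is
#' idempotent.
#'
#' @param X_tilde matrix with `NaN` at missing cells; every column must
#'   have at least one observed value.
#' @return imputed matrix.
#' @export
mean_impute <- function(X_tilde) {
  X_tilde <- as_num_matrix(X_tilde, "X_tilde")
  out <- X_tilde
  for (j in seq_len(ncol(out))) {
    v <- out[, j]
    miss <- !is.finite(v)
    if (!any(miss)) next
    if (all(miss)) stop(sprintf("column %d is entirely missing", j))
    out[miss, j] <- mean(v[!miss])
  }
  out
}

#' Iterative truncated-SVD imputation
#'
#' Initialises missing cells with column means, then alternates rank-`k`
#' truncated SVD reconstruction with overwriting of the missing block
#' until the relative Frobenius change of the imputed entries drops below
#' `tol` or `max_iter` is reached. Observed entries are never altered.
#'
#' @param X_tilde matrix with `NaN` at missing cells.
#' @param rank truncation rank; default `min(ncol - 1, 5)`.
#' @param max_iter iteration cap (default 100).
#' @param tol relative-change convergence tolerance (default 1e-4).
#' @return imputed matrix with attributes `converged` (logical) and
#'   `iterations`.
#' @export
svd_impute <- function(X_tilde, rank = NULL, max_iter = 100L, tol = 1e-4) {
  X_tilde <- as_num_matrix(X_tilde, "X_tilde")
  m <- nrow(X_tilde)
  n <- ncol(X_tilde)
  if (is.null(rank)) rank <- min(n - 1L, 5L)
  if (rank < 1L || rank > min(m, n) - 1L) {
    stop("rank must satisfy 1 <= rank <= min(m, n) - 1")
  }
  miss <- !is.finite(X_tilde)
  X_cur <- mean_impute(X_tilde)
  if (!any(miss)) {
    attr(X_cur, "converged") <- TRUE
    attr(X_cur, "iterations") <- 0L
    return(X_cur)
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    sv <- svd(X_cur, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    old <- X_cur[miss]
    X_cur[miss] <- recon[miss]
    denom <- max(sqrt(sum(old^2)), .Machine$double.eps)
    if (sqrt(sum((X_cur[miss] - old)^2)) / denom < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("svd_impute did not converge in %d iterations", max_iter))
  }
  attr(X_cur, "converged") <- converged
  attr(X_cur, "iterations") <- it
  X_cur
}
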