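# The four training losses and the combined generator objective.
#
# All losses are means over their entry counts (not raw sums) so the
# weights alpha and beta transfer across dataset sizes; probabilities are
# eps-clipped before any log.

#' Loss weights for the adversarial objective
#'
#' @param alpha reconstruction weight (default 200).
#' @param beta correlation weight (default 1.5).
#' @param lam discriminator L2 weight: 0.3 for large tables, 0.6 for
#'   small ones (default 0.6).
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 200, beta = 1.5, lam = 0.6) {
  if (alpha < 0 || beta < 0 || lam < 0) stop("loss weights must be >= 0")
  structure(list(alpha = alpha, beta = beta, lam = lam), class = "loss_weights")
}

#' Generator adversarial loss
#'
#' Mean of `-log(M_hat)` over missing positions: small when the
#' discriminator is fooled into rating generated cells as real.
#' (The minimised form of the deception objective; driving `M_hat -> 1`
#' at `M = 0` drives the loss to 0.)
#'
#' @param M binary mask (1 = observed).
#' @param M_hat discriminator probabilities in (0, 1).
#' @return scalar >= 0; returns 0 with a warning when nothing is missing.
#' @export
generator_adv_loss <- function(M, M_hat) {
  M <- check_binary_mask(M)
  check_same_shape(M, M_hat, c("M", "M_hat"))
  n_miss <- sum(M == 0)
  if (n_miss == 0L) {
    warning("no missing entries; adversarial loss is 0")
    return(0)
  }
  -sum((1 - M) * log(clip_prob(M_hat))) / n_miss
}

#' Reconstruction loss on observed entries
#'
#' Mean squared error (continuous columns) plus binary cross-entropy
#' (binary columns) between the generator's raw reconstruction and the
#' data, restricted to observed entries (`M = 1`), averaged over the
#' total observed count.
#'
#' @param X data matrix (only its observed entries are read).
#' @param X_hat generator reconstruction, same shape, finite.
#' @param M binary mask.
#' @param feature_kinds character vector, `"continuous"` or `"binary"`
#'   per column; default all continuous.
#' @return scalar >= 0.
#' @export
reconstruction_loss <- function(X, X_hat, M, feature_kinds = NULL) {
  X <- as_num_matrix(X, "X")
  X_hat <- as_num_matrix(X_hat, "X_hat")
  M <- check_binary_mask(M)
  check_same_shape(X, X_hat, c("X", "X_hat"))
  check_same_shape(X, M, c("X", "M"))
  n <- ncol(X)
  if (is.null(feature_kinds)) feature_kinds <- rep("continuous", n)
  feature_kinds <- match.arg(feature_kinds, c("continuous", "binary"),
                             several.ok = TRUE)
  feature_kinds <- rep_len(feature_kinds, n)
  n_obs <- sum(M == 1)
  if (n_obs == 0L) return(0)
  total <- 0
  for (j in seq_len(n)) {
    obs <- M[, j] == 1
    if (!any(obs)) next
    x <- X[obs, j]
    xh <- X_hat[obs, j]
    if (feature_kinds[j] == "continuous") {
      total <- total + sum((x - xh)^2)
    } else {
      if (!all(x %in% c(0, 1))) {
        stop(sprintf("binary column %d has observed values outside {0, 1}", j))
      }
      p <- clip_prob(xh)
      total <- total - sum(x * log(p) + (1 - x) * log(1 - p))
    }
  }
  total / n_obs
}

#' Pearson correlation matrix with zero-variance guard
#'
#' Symmetric n x n matrix of pairwise Pearson correlations between
#' columns; the diagonal is 1 and any column with zero variance gets 0
#' off-diagonal (its correlation is undefined).
#'
#' @param X complete numeric matrix with at least 2 rows.
#' @return n x n correlation matrix.
#' @export
correlation_matrix <- function(X) {
  X <- as_num_matrix(X, "X")
  if (nrow(X) < 2L) stop("correlation needs at least 2 rows")
  if (any(!is.finite(X))) stop("X must be complete")
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  zero <- sds == 0
  r[zero, ] <- 0
  r[, zero] <- 0
  diag(r) <- 1
  r
}

#' Correlation-structure loss
#'
#' Mean squared difference between the Pearson correlation matrices of
#' two tables: penalises imputations that distort the inter-feature
#' correlation structure.
#'
#' @param X reference matrix (or a precomputed n x n correlation matrix
#'   passed via `r_target`).
#' @param X_hat comparison matrix.
#' @param r_target optional precomputed target correlation matrix,
#'   overriding `X`.
#' @return scalar >= 0; 0 iff the correlation matrices agree.
#' @export
correlation_loss <- function(X, X_hat, r_target = NULL) {
  rt <- if (is.null(r_target)) correlation_matrix(X) else r_target
  rh <- correlation_matrix(X_hat)
  mean((rt - rh)^2)
}

# Gradient of correlation_loss w.r.t. X_hat (analytic; finite-difference
# checked in the tests). Uses d r_ij / d x_j = (z_i - r_ij z_j) / ||u_j||
# with z_j the centred unit-norm column.
correlation_loss_grad <- function(X_hat, r_target) {
  m <- nrow(X_hat)
  n <- ncol(X_hat)
  U <- sweep(X_hat, 2, colMeans(X_hat))
  nrm <- sqrt(colSums(U^2))
  ok <- nrm > 0
  Z <- U
  Z[, ok] <- sweep(U[, ok, drop = FALSE], 2, nrm[ok], `/`)
  Z[, !ok] <- 0
  R <- correlation_matrix(X_hat)
  Dr <- 2 * (R - r_target) / (n * n)    # dL/dr_ij, ordered pairs
  G <- matrix(0, m, n)
  for (j in which(ok)) {
    # both (i,j) and (j,i) terms contribute; diagonal is constant
    w <- 2 * Dr[, j]
    w[j] <- 0
    G[, j] <- (Z %*% w - sum(w * R[, j]) * Z[, j]) / nrm[j]
  }
  G
}

#' Discriminator loss
#'
#' Negative binary cross-entropy of the probability grid against the true
#' mask (minimising it trains the discriminator to rate observed cells 1
#' and generated cells 0), plus an L2 penalty `lam * mean(w^2)` on the
#' discriminator weight matrices.
#'
#' @param M binary mask.
#' @param M_hat probability grid in (0, 1).
#' @param disc_weights optional numeric vector of discriminator weights
#'   for the penalty (biases excluded).
#' @param lam regularisation strength.
#' @return scalar.
#' @export
discriminator_loss <- function(M, M_hat, disc_weights = NULL, lam = 0) {
  M <- check_binary_mask(M)
  check_same_shape(M, M_hat, c("M", "M_hat"))
  p <- clip_prob(M_hat)
  bce <- -mean(M * log(p) + (1 - M) * log(1 - p))
  reg <- if (is.null(disc_weights) || lam == 0) 0 else lam * mean(disc_weights^2)
  bce + reg
}

#' Combined generator objective
#'
#' `L_gen + alpha * L_rec + beta * L_cor`.
#'
#' @param L_gen,L_rec,L_cor the three component losses.
#' @param weights a [loss_weights()] object.
#' @return scalar.
#' @export
generator_total <- function(L_gen, L_rec, L_cor, weights = loss_weights()) {
  L_gen + weights$alpha * L_rec + weights$beta * L_cor
}
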