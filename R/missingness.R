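# Missingness mechanism simulators: MCAR, softmax-over-samples MAR/MNAR,
# column-pattern MAR and below-median MNAR.
#
# All generators return a binary mask matrix (1 = observed, 0 = missing)
# with attributes "prob" (the unclipped per-entry missing probabilities,
# whose column means equal the target rate by the softmax normalization
# identity) and "realized_rate".

check_rate <- function(rate, n) {
  rate <- rep_len(as.numeric(rate), n)
  if (any(!is.finite(rate)) || any(rate <= 0) || any(rate >= 1)) {
    stop("missing rate(s) must lie strictly in (0, 1)")
  }
  rate
}

finish_mask <- function(P_unclipped, seed, rate_attr = TRUE) {
  m <- nrow(P_unclipped)
  n <- ncol(P_unclipped)
  P <- pmin(pmax(P_unclipped, 0), 1)
  M <- with_seed(seed, {
    U <- matrix(stats::runif(m * n), m, n)
    ifelse(U < P, 0, 1)
  })
  attr(M, "prob") <- P_unclipped
  attr(M, "realized_rate") <- mean(M == 0)
  M
}

#' MCAR mask: missing completely at random
#'
#' Every cell of column `j` is missing independently with probability
#' `rate[j]`, irrespective of any data value.
#'
#' @param m,n mask dimensions (samples x features).
#' @param rate target missing rate, scalar or length-`n`, strictly in
#'   (0, 1).
#' @param seed integer seed.
#' @return binary mask matrix (1 = observed) with attributes `prob`
#'   (per-entry missing probabilities) and `realized_rate`.
#' @export
mcar_mask <- function(m, n, rate, seed = 1L) {
  rate <- check_rate(rate, n)
  P <- matrix(rate, m, n, byrow = TRUE)
  finish_mask(P, seed)
}

# Shared kernel: per-column missing probabilities proportional to
# exp(-score_i), rescaled by m / sum(exp(-score)) so the column mean of
# the unclipped probabilities is exactly the target rate.
softmax_column_prob <- function(score, rate_j) {
  e <- exp(-(score - min(score)))   # shift-invariant, avoids underflow
  rate_j * length(score) * e / sum(e)
}

#' MAR mask: missingness driven by preceding observed columns
#'
#' Column `j`'s missing probability for row `i` is
#' `rate[j] * m * exp(-sum_{l<j} (w_l * x_il + k_l * (1 - x_il))) /
#' sum_s exp(-...)` - a softmax over samples of a weighted score of the
#' columns to the left, so missingness depends on observed values only.
#' Column 1 has no preceding columns and reduces to MCAR. Weight vectors
#' `W` and `K` are drawn once per call from Uniform(0,1) under `seed`
#' (or supplied). Probabilities above 1 are clipped before drawing;
#' the unclipped matrix is kept in the `prob` attribute.
#'
#' @param X_norm complete data matrix on the normalized `[0, 1]` scale.
#' @param rate target missing rate, scalar or per-column, in (0, 1).
#' @param seed integer seed (weights and Bernoulli draws).
#' @param W,K optional length-`n` weight vectors in (0, 1).
#' @return binary mask with `prob` and `realized_rate` attributes.
#' @export
mar_softmax_mask <- function(X_norm, rate, seed = 1L, W = NULL, K = NULL) {
  X_norm <- as_num_matrix(X_norm, "X_norm")
  if (anyNA(X_norm) || any(!is.finite(X_norm))) stop("X_norm must be complete")
  m <- nrow(X_norm)
  n <- ncol(X_norm)
  if (n == 0L) stop("X_norm must have at least one column")
  rate <- check_rate(rate, n)
  if (is.null(W)) W <- with_seed(derive_seed(seed, 1L), stats::runif(n))
  if (is.null(K)) K <- with_seed(derive_seed(seed, 2L), stats::runif(n))
  P <- matrix(0, m, n)
  score <- numeric(m)   # running sum over columns l < j
  for (j in seq_len(n)) {
    P[, j] <- if (j == 1L) rate[1L] else softmax_column_prob(score, rate[j])
    score <- score + W[j] * X_norm[, j] + K[j] * (1 - X_norm[, j])
  }
  finish_mask(P, seed)
}

#' MNAR mask: missingness driven by the unobserved value itself
#'
#' Column `j`'s missing probability is a softmax over samples of
#' `exp(-w_j * x_ij)`: with `w_j > 0`, larger values are less likely to
#' be removed, so missingness depends on the value that goes missing.
#' A constant column reduces to MCAR (uniform softmax).
#'
#' @inheritParams mar_softmax_mask
#' @param W optional length-`n` weight vector in (0, 1).
#' @return binary mask with `prob` and `realized_rate` attributes.
#' @export
mnar_softmax_mask <- function(X_norm, rate, seed = 1L, W = NULL) {
  X_norm <- as_num_matrix(X_norm, "X_norm")
  if (anyNA(X_norm) || any(!is.finite(X_norm))) stop("X_norm must be complete")
  n <- ncol(X_norm)
  rate <- check_rate(rate, n)
  if (is.null(W)) W <- with_seed(derive_seed(seed, 1L), stats::runif(n))
  P <- vapply(seq_len(n),
              function(j) softmax_column_prob(W[j] * X_norm[, j], rate[j]),
              numeric(nrow(X_norm)))
  finish_mask(P, seed)
}

#' Patterned MAR mask: missingness confined to column blocks
#'
#' The `one_third` pattern allows missing values only in the middle third
#' of the feature columns (columns `floor(n/3) .. ceiling(2n/3) - 1`,
#' 0-based); the `two_thirds` pattern allows them only in the complement
#' (first and last thirds). Within the eligible block cells are removed
#' MCAR at the stated rate; all other columns stay fully observed.
#'
#' @param m,n mask dimensions; `n >= 3`.
#' @param rate missing rate applied within the eligible columns.
#' @param pattern `"one_third"` or `"two_thirds"`.
#' @param seed integer seed.
#' @return binary mask with `prob` and `realized_rate` attributes, plus
#'   `eligible_cols` (1-based indices).
#' @export
mar_pattern_mask <- function(m, n, rate, pattern = c("one_third", "two_thirds"),
                             seed = 1L) {
  pattern <- match.arg(pattern)
  if (n < 3L) stop("patterned masks need n >= 3 columns")
  rate <- check_rate(rate, 1L)
  middle <- seq.int(floor(n / 3) + 1L, ceiling(2 * n / 3))
  cols <- if (pattern == "one_third") middle else setdiff(seq_len(n), middle)
  P <- matrix(0, m, n)
  P[, cols] <- rate
  M <- finish_mask(P, seed)
  attr(M, "eligible_cols") <- cols
  M
}

#' Below-median MNAR mask
#'
#' Only cells strictly below their column median (lower median for even
#' `m`) are eligible for removal; eligible cells are removed independently
#' with a probability chosen so the column's expected missing fraction
#' equals `rate`. If `rate` exceeds the eligible fraction, every eligible
#' cell is removed and a warning is raised.
#'
#' @param X_norm complete numeric matrix.
#' @param rate target per-column missing rate in (0, 1).
#' @param seed integer seed.
#' @return binary mask with `prob` and `realized_rate` attributes.
#' @export
mnar_median_mask <- function(X_norm, rate, seed = 1L) {
  X_norm <- as_num_matrix(X_norm, "X_norm")
  if (anyNA(X_norm) || any(!is.finite(X_norm))) stop("X_norm must be complete")
  m <- nrow(X_norm)
  n <- ncol(X_norm)
  rate <- check_rate(rate, n)
  P <- matrix(0, m, n)
  capped <- FALSE
  for (j in seq_len(n)) {
    med <- sort(X_norm[, j])[floor((m + 1) / 2)]   # lower median
    eligible <- X_norm[, j] < med
    frac <- mean(eligible)
    if (frac == 0) next
    p <- rate[j] / frac
    if (p > 1) {
      capped <- TRUE
      p <- 1
    }
    P[eligible, j] <- p
  }
  if (capped) {
    warning("target rate exceeds the below-median fraction in some column(s); ",
            "all eligible cells removed there")
  }
  finish_mask(P, seed)
}

#' Generate a mask under a named mechanism
#'
#' Dispatcher over the five mechanism simulators, convenient for
#' protocol sweeps and the command-line interface.
#'
#' @param X_norm complete normalized data matrix (used by the value-
#'   dependent mechanisms; only its shape is used for MCAR).
#' @param mechanism one of `"mcar"`, `"mar_softmax"`, `"mnar_softmax"`,
#'   `"mar_one_third"`, `"mar_two_thirds"`, `"mnar_median"`.
#' @param rate target missing rate in (0, 1).
#' @param seed integer seed.
#' @return binary mask matrix.
#' @export
mechanism_mask <- function(X_norm, mechanism, rate, seed = 1L) {
  X_norm <- as_num_matrix(X_norm, "X_norm")
  m <- nrow(X_norm)
  n <- ncol(X_norm)
  switch(match.arg(mechanism, c("mcar", "mar_softmax", "mnar_softmax",
                                "mar_one_third", "mar_two_thirds",
                                "mnar_median")),
         mcar = mcar_mask(m, n, rate, seed),
         mar_softmax = mar_softmax_mask(X_norm, rate, seed),
         mnar_softmax = mnar_softmax_mask(X_norm, rate, seed),
         mar_one_third = mar_pattern_mask(m, n, rate, "one_third", seed),
         mar_two_thirds = mar_pattern_mask(m, n, rate, "two_thirds", seed),
         mnar_median = mnar_median_mask(X_norm, rate, seed))
}
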