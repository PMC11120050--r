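# Generator and discriminator forward/backward passes.
#
# The generator is a dense autoencoder over the channel-concatenated input
# [X', M, (1-M)*Z, y]; its defining "detracking" property -- output feature
# j has no computational path from input feature j -- is enforced by running
# the shared backbone once per output column with that column of the data
# channel zeroed and assembling column j of the output from pass j.
#
# The discriminator applies three 1-d convolutional reductions over the
# feature axis, additive attention over the resulting per-position states,
# and a final affine+sigmoid map back to an m x n probability grid.
#
# All gradients are hand-derived; the test suite verifies every path
# against central finite differences.

# ---- parameter-tree helpers -------------------------------------------------

nn_flatten <- function(params) unlist(params, use.names = FALSE)

nn_unflatten <- function(flat, skeleton) {
  i <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    len <- length(s)
    v <- flat[(i + 1L):(i + len)]
    i <<- i + len
    if (!is.null(dim(s))) dim(v) <- dim(s)
    v
  }
  rec(skeleton)
}

nn_zeros_like <- function(params) {
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    z <- s
    z[] <- 0
    z
  }
  rec(params)
}

# ---- generator --------------------------------------------------------------

#' Initialise generator parameters
#'
#' The generator is a dense detracking autoencoder: three encoder stages
#' compress the `3n + C` input channels (`X'`, mask, masked noise, one-hot
#' label) to a low-dimensional code, three decoder stages map the code
#' back to `n` outputs through a final sigmoid so imputations stay on the
#' normalized `[0, 1]` scale.
#'
#' @param n number of features (>= 2 when detracking is used).
#' @param C one-hot label width (0 for unlabelled data).
#' @param enc_widths encoder stage widths (compression); default 32, 16, 8.
#' @param dec_widths decoder hidden widths before the `n`-unit output;
#'   default 16, 32.
#' @param seed integer seed for He-scaled Gaussian initialisation.
#' @return object of class `generator_params`.
#' @export
init_generator <- function(n, C, enc_widths = c(32L, 16L, 8L),
                           dec_widths = c(16L, 32L), seed = 1L) {
  if (enc_widths[length(enc_widths)] >= 3L * n + C) {
    enc_widths <- pmax(2L, pmin(enc_widths, 3L * n + C - 1L))
  }
  widths <- c(3L * n + C, enc_widths, dec_widths, n)
  L <- length(widths) - 1L
  params <- with_seed(seed, {
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- widths[l]
      sc <- if (l < L) sqrt(2 / fan_in) else sqrt(1 / fan_in)
      W[[l]] <- matrix(stats::rnorm(fan_in * widths[l + 1L], sd = sc),
                       fan_in, widths[l + 1L])
      b[[l]] <- numeric(widths[l + 1L])
    }
    list(W = W, b = b)
  })
  structure(list(W = params$W, b = params$b, n = as.integer(n),
                 C = as.integer(C), widths = widths, n_layers = L),
            class = "generator_params")
}

mlp_forward <- function(params, U) {
  L <- params$n_layers
  A <- vector("list", L + 1L)
  A[[1L]] <- U
  for (l in seq_len(L)) {
    Zl <- A[[l]] %*% params$W[[l]]
    Zl <- sweep(Zl, 2, params$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) relu(Zl) else sigmoid(Zl)
  }
  A
}

# dOut is the loss gradient at the (sigmoid) output of one pass.
mlp_backward <- function(params, A, dOut, grads = NULL) {
  L <- params$n_layers
  if (is.null(grads)) grads <- nn_zeros_like(params[c("W", "b")])
  out <- A[[L + 1L]]
  dZ <- dOut * out * (1 - out)             # sigmoid derivative
  for (l in rev(seq_len(L))) {
    grads$W[[l]] <- grads$W[[l]] + crossprod(A[[l]], dZ)
    grads$b[[l]] <- grads$b[[l]] + colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(params$W[[l]])
      dZ <- dA * (A[[l]] > 0)              # ReLU derivative
    }
  }
  grads
}

check_onehot <- function(Y, m, C) {
  if (C == 0L) return(matrix(0, m, 0L))
  Y <- as_num_matrix(Y, "y_onehot")
  if (nrow(Y) != m || ncol(Y) != C) stop("y_onehot must be m x C")
  rs <- rowSums(Y)
  if (!all(abs(rs - 1) < 1e-9 | abs(rs) < 1e-9)) {
    stop("each one-hot label row must sum to 1 (or be all zero when labels are disabled)")
  }
  Y
}

#' One-hot encode integer class labels
#'
#' @param y integer labels `0..C-1`.
#' @param C number of classes.
#' @return `length(y) x C` binary matrix.
#' @export
onehot <- function(y, C) {
  Y <- matrix(0, length(y), C)
  Y[cbind(seq_along(y), as.integer(y) + 1L)] <- 1
  Y
}

#' Generator forward pass
#'
#' Computes the generator output `G([X', M, (1-M)*Z, y])` for a batch.
#' With `detracking = TRUE` (the default) the shared backbone is run once
#' per feature with that feature's data channel zeroed, and column `j` of
#' the output is taken from pass `j`, so output `j` provably has no
#' computational path from input `j`. Deterministic given inputs and
#' parameters; outputs lie in `(0, 1)` via the final sigmoid.
#'
#' @param params `generator_params` from [init_generator()].
#' @param X_prime noise-filled data matrix (no missing cells), m x n.
#' @param M binary mask, m x n.
#' @param Y one-hot label matrix m x C (all-zero rows allowed when labels
#'   are disabled); ignored when `C = 0`.
#' @param Z noise matrix m x n (zero at observed cells).
#' @param detracking logical; disable only for ablation.
#' @param cache logical; keep activations for [generator_backward()].
#' @return m x n output matrix, with attribute `cache` when requested.
#' @export
generator_forward <- function(params, X_prime, M, Y = NULL, Z = NULL,
                              detracking = TRUE, cache = FALSE) {
  X_prime <- as_num_matrix(X_prime, "X_prime")
  if (any(!is.finite(X_prime))) stop("X_prime must not contain NaN; run noise_fill() first")
  M <- check_binary_mask(M)
  check_same_shape(X_prime, M, c("X_prime", "M"))
  m <- nrow(X_prime)
  n <- ncol(X_prime)
  if (n != params$n) stop("feature count does not match generator parameters")
  if (detracking && n < 2L) stop("detracking is undefined for n < 2")
  if (is.null(Z)) Z <- matrix(0, m, n)
  check_same_shape(X_prime, Z, c("X_prime", "Z"))
  Y <- check_onehot(if (is.null(Y)) matrix(0, m, params$C) else Y, m, params$C)
  U <- cbind(X_prime, M, (1 - M) * Z, Y)
  if (!detracking) {
    A <- mlp_forward(params, U)
    out <- A[[length(A)]]
    caches <- if (cache) list(A) else NULL
  } else {
    out <- matrix(0, m, n)
    caches <- if (cache) vector("list", n) else NULL
    for (j in seq_len(n)) {
      Uj <- U
      Uj[, j] <- 0                      # zero the data channel of feature j
      A <- mlp_forward(params, Uj)
      out[, j] <- A[[length(A)]][, j]
      if (cache) caches[[j]] <- A
    }
  }
  if (cache) {
    attr(out, "cache") <- list(passes = caches, detracking = detracking,
                               m = m, n = n)
  }
  out
}

#' Generator backward pass
#'
#' Accumulates parameter gradients of a scalar loss given its gradient
#' with respect to the generator output.
#'
#' @param params `generator_params`.
#' @param fwd the output of [generator_forward()] called with
#'   `cache = TRUE`.
#' @param dG_out m x n gradient of the loss w.r.t. the generator output.
#' @return list with gradient trees `W` and `b` matching `params`.
#' @export
generator_backward <- function(params, fwd, dG_out) {
  info <- attr(fwd, "cache")
  if (is.null(info)) stop("forward pass must be run with cache = TRUE")
  grads <- nn_zeros_like(params[c("W", "b")])
  if (!info$detracking) {
    return(mlp_backward(params, info$passes[[1L]], dG_out, grads))
  }
  for (j in seq_len(info$n)) {
    dOut <- matrix(0, info$m, info$n)
    dOut[, j] <- dG_out[, j]            # only column j of pass j is used
    grads <- mlp_backward(params, info$passes[[j]], dOut, grads)
  }
  grads
}

# ---- discriminator ----------------------------------------------------------

#' Initialise discriminator parameters
#'
#' Three 1-d convolutional reductions (kernel 3, stride 1, same padding)
#' over the feature axis map the `1 + C` input channels (imputed value
#' plus broadcast one-hot label) to per-position states; additive
#' attention summarises them into a context vector; a final affine stage
#' maps `[state_s ; context]` to a logit per position.
#'
#' @param n number of features.
#' @param C one-hot label width.
#' @param conv_channels channel widths of the three conv stages.
#' @param att_dim dimension of the additive-attention hidden space.
#' @param seed integer seed.
#' @return object of class `discriminator_params`.
#' @export
init_discriminator <- function(n, C, conv_channels = c(16L, 16L, 8L),
                               att_dim = 8L, seed = 1L) {
  ch <- c(1L + C, conv_channels)
  d <- ch[length(ch)]
  a <- att_dim
  params <- with_seed(seed, {
    Wconv <- vector("list", length(conv_channels))
    bconv <- vector("list", length(conv_channels))
    for (l in seq_along(conv_channels)) {
      fan_in <- 3L * ch[l]
      Wconv[[l]] <- array(stats::rnorm(3L * ch[l] * ch[l + 1L],
                                       sd = sqrt(2 / fan_in)),
                          dim = c(3L, ch[l], ch[l + 1L]))
      bconv[[l]] <- numeric(ch[l + 1L])
    }
    list(Wconv = Wconv, bconv = bconv,
         W1 = matrix(stats::rnorm(a * d, sd = sqrt(1 / d)), a, d),
         W2 = matrix(stats::rnorm(a * d, sd = sqrt(1 / d)), a, d),
         v = stats::rnorm(a, sd = sqrt(1 / a)),
         Wc = matrix(stats::rnorm(d * 2L * d, sd = sqrt(1 / (2 * d))), d, 2L * d),
         u = stats::rnorm(2L * d, sd = sqrt(1 / (2 * d))),
         b0 = 0)
  })
  structure(c(params, list(n = as.integer(n), C = as.integer(C),
                           channels = ch, att_dim = a, state_dim = d)),
            class = "discriminator_params")
}

# 1-d convolution over the position axis; A is (m, n, ch_in).
conv1d_forward <- function(A, W, b) {
  m <- dim(A)[1L]
  n <- dim(A)[2L]
  ch_in <- dim(A)[3L]
  ch_out <- dim(W)[3L]
  Apad <- array(0, dim = c(m, n + 2L, ch_in))
  Apad[, 2L:(n + 1L), ] <- A
  out <- array(rep(b, each = m * n), dim = c(m, n, ch_out))
  for (t in seq_len(n)) {
    acc <- matrix(out[, t, ], m, ch_out)
    for (o in 1:3) {
      acc <- acc + matrix(Apad[, t + o - 1L, ], m, ch_in) %*%
        matrix(W[o, , ], ch_in, ch_out)
    }
    out[, t, ] <- acc
  }
  out
}

conv1d_backward <- function(A, W, dOut) {
  m <- dim(A)[1L]
  n <- dim(A)[2L]
  ch_in <- dim(A)[3L]
  ch_out <- dim(W)[3L]
  Apad <- array(0, dim = c(m, n + 2L, ch_in))
  Apad[, 2L:(n + 1L), ] <- A
  dW <- array(0, dim = dim(W))
  db <- numeric(ch_out)
  dApad <- array(0, dim = dim(Apad))
  for (t in seq_len(n)) {
    dz <- matrix(dOut[, t, ], m, ch_out)
    db <- db + colSums(dz)
    for (o in 1:3) {
      Ain <- matrix(Apad[, t + o - 1L, ], m, ch_in)
      dW[o, , ] <- matrix(dW[o, , ], ch_in, ch_out) + crossprod(Ain, dz)
      dApad[, t + o - 1L, ] <- matrix(dApad[, t + o - 1L, ], m, ch_in) +
        dz %*% t(matrix(W[o, , ], ch_in, ch_out))
    }
  }
  list(dW = dW, db = db, dA = dApad[, 2L:(n + 1L), , drop = FALSE])
}

#' Discriminator forward pass
#'
#' Maps an imputed matrix (and its labels) to a probability grid of the
#' same shape: `M_hat[i, j]` is the estimated probability that cell
#' `(i, j)` holds an observed (real) rather than generated value.
#'
#' @param params `discriminator_params` from [init_discriminator()].
#' @param X_hat imputed matrix m x n, finite.
#' @param Y one-hot label matrix m x C (or `NULL` / all-zero when labels
#'   are disabled).
#' @param use_attention logical; when `FALSE` the attention weights are
#'   frozen at uniform `1/n` (mean pooling), the ablation variant.
#' @param cache logical; keep intermediates for [discriminator_backward()].
#' @return m x n matrix of probabilities strictly inside (0, 1), with
#'   attribute `cache` when requested.
#' @export
discriminator_forward <- function(params, X_hat, Y = NULL, use_attention = TRUE,
                                  cache = FALSE) {
  X_hat <- as_num_matrix(X_hat, "X_hat")
  if (any(!is.finite(X_hat))) stop("X_hat must be finite")
  m <- nrow(X_hat)
  n <- ncol(X_hat)
  if (n != params$n) stop("feature count does not match discriminator parameters")
  C <- params$C
  Y <- check_onehot(if (is.null(Y)) matrix(0, m, C) else Y, m, C)
  d <- params$state_dim
  a <- params$att_dim

  A0 <- array(0, dim = c(m, n, 1L + C))
  A0[, , 1L] <- X_hat
  if (C > 0L) for (k in seq_len(C)) A0[, , 1L + k] <- Y[, k]

  n_conv <- length(params$Wconv)
  As <- vector("list", n_conv + 1L)
  Zs <- vector("list", n_conv)
  As[[1L]] <- A0
  for (l in seq_len(n_conv)) {
    Zs[[l]] <- conv1d_forward(As[[l]], params$Wconv[[l]], params$bconv[[l]])
    As[[l + 1L]] <- array(relu(Zs[[l]]), dim = dim(Zs[[l]]))
  }
  Hbar <- As[[n_conv + 1L]]                       # (m, n, d)

  Ht <- matrix(0, m, d)
  for (s in seq_len(n)) Ht <- Ht + matrix(Hbar[, s, ], m, d)
  Ht <- Ht / n

  Tarr <- NULL
  if (use_attention) {
    Tarr <- array(0, dim = c(m, n, a))
    score <- matrix(0, m, n)
    HtW1 <- Ht %*% t(params$W1)
    for (s in seq_len(n)) {
      Ts <- tanh(HtW1 + matrix(Hbar[, s, ], m, d) %*% t(params$W2))
      Tarr[, s, ] <- Ts
      score[, s] <- Ts %*% params$v
    }
    alpha <- softmax_rows(score)
  } else {
    alpha <- matrix(1 / n, m, n)
  }

  Ct <- matrix(0, m, d)
  for (s in seq_len(n)) Ct <- Ct + alpha[, s] * matrix(Hbar[, s, ], m, d)
  At <- tanh(cbind(Ct, Ht) %*% t(params$Wc))      # (m, d)

  logits <- matrix(params$b0, m, n)
  u_state <- params$u[seq_len(d)]
  u_ctx <- params$u[(d + 1L):(2L * d)]
  At_u <- drop(At %*% u_ctx)
  for (s in seq_len(n)) {
    logits[, s] <- logits[, s] + drop(matrix(Hbar[, s, ], m, d) %*% u_state) + At_u
  }
  M_hat <- pmin(pmax(sigmoid(logits), 1e-12), 1 - 1e-12)
  dim(M_hat) <- c(m, n)
  if (cache) {
    attr(M_hat, "cache") <- list(As = As, Zs = Zs, Hbar = Hbar, Ht = Ht,
                                 Tarr = Tarr, alpha = alpha, Ct = Ct, At = At,
                                 sig = sigmoid(logits), use_attention = use_attention,
                                 m = m, n = n)
  }
  M_hat
}

#' Discriminator backward pass
#'
#' Given the gradient of a scalar loss with respect to `M_hat`, returns
#' parameter gradients and (optionally) the gradient with respect to the
#' input matrix -- the path through which the generator receives its
#' adversarial signal.
#'
#' @param params `discriminator_params`.
#' @param fwd output of [discriminator_forward()] with `cache = TRUE`.
#' @param dM_hat m x n loss gradient w.r.t. the output probabilities.
#' @param input_grad logical; also compute `dX_hat`.
#' @return list with `grads` (tree matching the parameter list) and
#'   `dX_hat` (m x n matrix or `NULL`).
#' @export
discriminator_backward <- function(params, fwd, dM_hat, input_grad = TRUE) {
  cc <- attr(fwd, "cache")
  if (is.null(cc)) stop("forward pass must be run with cache = TRUE")
  m <- cc$m
  n <- cc$n
  d <- params$state_dim
  a <- params$att_dim
  Hbar <- cc$Hbar
  grads <- nn_zeros_like(params[c("Wconv", "bconv", "W1", "W2", "v", "Wc", "u", "b0")])

  dlogit <- dM_hat * cc$sig * (1 - cc$sig)
  u_state <- params$u[seq_len(d)]
  u_ctx <- params$u[(d + 1L):(2L * d)]

  dHbar <- array(0, dim = c(m, n, d))
  dAt <- matrix(0, m, d)
  for (s in seq_len(n)) {
    dl <- dlogit[, s]
    Hs <- matrix(Hbar[, s, ], m, d)
    grads$u[seq_len(d)] <- grads$u[seq_len(d)] + drop(crossprod(Hs, dl))
    grads$u[(d + 1L):(2L * d)] <- grads$u[(d + 1L):(2L * d)] +
      drop(crossprod(cc$At, dl))
    dHbar[, s, ] <- matrix(dHbar[, s, ], m, d) + outer(dl, u_state)
    dAt <- dAt + dl * matrix(u_ctx, m, d, byrow = TRUE)
  }
  grads$b0 <- sum(dlogit)

  # At = tanh([Ct ; Ht] %*% t(Wc))
  dP <- dAt * (1 - cc$At^2)
  grads$Wc <- crossprod(dP, cbind(cc$Ct, cc$Ht))
  dCt <- dP %*% params$Wc[, seq_len(d), drop = FALSE]
  dHt <- dP %*% params$Wc[, (d + 1L):(2L * d), drop = FALSE]

  # Ct = sum_s alpha_s * Hbar_s
  dalpha <- matrix(0, m, n)
  for (s in seq_len(n)) {
    Hs <- matrix(Hbar[, s, ], m, d)
    dalpha[, s] <- rowSums(dCt * Hs)
    dHbar[, s, ] <- matrix(dHbar[, s, ], m, d) + cc$alpha[, s] * dCt
  }

  if (cc$use_attention) {
    # softmax over positions
    dscore <- cc$alpha * (dalpha - rowSums(dalpha * cc$alpha))
    for (s in seq_len(n)) {
      Ts <- matrix(cc$Tarr[, s, ], m, a)
      dT <- outer(dscore[, s], params$v)
      grads$v <- grads$v + drop(crossprod(Ts, dscore[, s]))
      dQ <- dT * (1 - Ts^2)
      grads$W1 <- grads$W1 + crossprod(dQ, cc$Ht)
      grads$W2 <- grads$W2 + crossprod(dQ, matrix(Hbar[, s, ], m, d))
      dHt <- dHt + dQ %*% params$W1
      dHbar[, s, ] <- matrix(dHbar[, s, ], m, d) + dQ %*% params$W2
    }
  }

  # Ht = mean_s Hbar_s
  for (s in seq_len(n)) {
    dHbar[, s, ] <- matrix(dHbar[, s, ], m, d) + dHt / n
  }

  dA <- dHbar
  n_conv <- length(params$Wconv)
  for (l in rev(seq_len(n_conv))) {
    dZ <- dA * (cc$Zs[[l]] > 0)
    bk <- conv1d_backward(cc$As[[l]], params$Wconv[[l]], dZ)
    grads$Wconv[[l]] <- bk$dW
    grads$bconv[[l]] <- bk$db
    dA <- bk$dA
  }
  dX_hat <- if (input_grad) matrix(dA[, , 1L], m, n) else NULL
  list(grads = grads, dX_hat = dX_hat)
}

#' Additive attention over a set of states
#'
#' The scoring and pooling primitive used inside the discriminator,
#' exposed for a single query: `score_s = v' tanh(w1 h_t + w2 hbar_s)`,
#' `alpha = softmax_s(score)`, `c_t = sum_s alpha_s hbar_s`, and (when
#' `Wc` is supplied) `alpha_t = tanh(Wc [c_t ; h_t])`.
#'
#' @param h_bar S x d matrix of states (one row per position).
#' @param h_t length-d query vector.
#' @param v length-a scoring vector.
#' @param w1,w2 a x d scoring matrices.
#' @param Wc optional d_out x 2d output matrix.
#' @return list with `alpha_ts` (length S, sums to 1), `c_t` (length d),
#'   and `alpha_t` (or `NULL`).
#' @export
attention <- function(h_bar, h_t, v, w1, w2, Wc = NULL) {
  h_bar <- as_num_matrix(h_bar, "h_bar")
  S <- nrow(h_bar)
  if (S == 0L) stop("attention needs at least one state")
  score <- vapply(seq_len(S),
                  function(s) sum(v * tanh(w1 %*% h_t + w2 %*% h_bar[s, ])),
                  numeric(1))
  alpha <- drop(softmax_rows(matrix(score, 1L)))
  c_t <- drop(crossprod(h_bar, alpha))
  alpha_t <- if (is.null(Wc)) NULL else drop(tanh(Wc %*% c(c_t, h_t)))
  list(alpha_ts = alpha, c_t = c_t, alpha_t = alpha_t)
}

#' Numerical self-dependence of generator outputs
#'
#' Central finite difference of output column `j` with respect to input
#' column `j`, maximised over columns -- the detracking property states
#' this is numerically zero.
#'
#' @param params `generator_params`.
#' @param X_prime,M,Y,Z forward-pass inputs (see [generator_forward()]).
#' @param detracking forwarded to [generator_forward()].
#' @param delta finite-difference step.
#' @return largest absolute change of any output `[, j]` under a `delta`
#'   perturbation of input `[, j]`, scaled by `1/(2*delta)`.
#' @export
self_dependence <- function(params, X_prime, M, Y = NULL, Z = NULL,
                            detracking = TRUE, delta = 1e-3) {
  worst <- 0
  for (j in seq_len(ncol(X_prime))) {
    up <- X_prime
    up[, j] <- up[, j] + delta
    dn <- X_prime
    dn[, j] <- dn[, j] - delta
    g_up <- generator_forward(params, up, M, Y, Z, detracking = detracking)
    g_dn <- generator_forward(params, dn, M, Y, Z, detracking = detracking)
    worst <- max(worst, max(abs(g_up[, j] - g_dn[, j]) / (2 * delta)))
  }
  worst
}
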