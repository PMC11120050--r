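# Alternating adversarial training with best-model selection, ablation
# toggles, and inference-time imputation.

#' Training configuration
#'
#' Defaults follow the reference protocol: 1000 alternations of one
#' discriminator and one generator Adam step at learning rate 0.001,
#' loss weights `alpha = 200`, `beta = 1.5`, and `lam = 0.6` (small-table
#' regularisation; use 0.3 for large tables).
#'
#' @param epochs number of alternating training rounds.
#' @param learning_rate Adam step size for both networks.
#' @param batch_size minibatch rows per round; the full training set is
#'   used when it has fewer than 256 rows.
#' @param weights a [loss_weights()] object.
#' @param z_sigma standard deviation of the zero-mean Gaussian noise used
#'   to fill missing cells each round.
#' @param seed integer seed governing initialisation, batching and noise.
#' @param use_attention,use_detracking,use_labels ablation toggles.
#' @param enc_widths,dec_widths generator stage widths
#'   (see [init_generator()]).
#' @param conv_channels,att_dim discriminator widths
#'   (see [init_discriminator()]).
#' @param patience optional early-stopping patience in rounds without a
#'   checkpoint improvement; `Inf` (default) trains the full schedule.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, learning_rate = 0.001,
                         batch_size = 128L, weights = loss_weights(),
                         z_sigma = 0.01, seed = 1L,
                         use_attention = TRUE, use_detracking = TRUE,
                         use_labels = TRUE,
                         enc_widths = c(32L, 16L, 8L), dec_widths = c(16L, 32L),
                         conv_channels = c(16L, 16L, 8L), att_dim = 8L,
                         patience = Inf) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), weights = weights,
                 z_sigma = z_sigma, seed = as.integer(seed),
                 use_attention = isTRUE(use_attention),
                 use_detracking = isTRUE(use_detracking),
                 use_labels = isTRUE(use_labels),
                 enc_widths = enc_widths, dec_widths = dec_widths,
                 conv_channels = conv_channels, att_dim = att_dim,
                 patience = patience),
            class = "train_config")
}

#' Derive an ablation configuration
#'
#' Maps the named ablation variants onto the three toggles: removing
#' attention freezes the discriminator's attention weights at uniform
#' pooling; removing the detracking autoencoder lets each output see its
#' own input; removing labels replaces the one-hot channel with zeros.
#'
#' @param cfg a [train_config()].
#' @param variant one of `"full"`, `"wo_attention"`, `"wo_dtae"`,
#'   `"wo_dtae_attention"`, `"wo_dtae_attention_labels"`.
#' @return the modified `train_config`.
#' @export
ablate_config <- function(cfg, variant = c("full", "wo_attention", "wo_dtae",
                                           "wo_dtae_attention",
                                           "wo_dtae_attention_labels")) {
  variant <- match.arg(variant)
  cfg$use_attention <- !(variant %in% c("wo_attention", "wo_dtae_attention",
                                        "wo_dtae_attention_labels"))
  cfg$use_detracking <- !(variant %in% c("wo_dtae", "wo_dtae_attention",
                                         "wo_dtae_attention_labels"))
  cfg$use_labels <- variant != "wo_dtae_attention_labels"
  cfg
}

# ---- Adam on a flattened parameter vector ----------------------------------

adam_init <- function(flat) list(m = numeric(length(flat)),
                                 v = numeric(length(flat)), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

disc_weight_vector <- function(dp) {
  c(unlist(dp$Wconv, use.names = FALSE), dp$W1, dp$W2, dp$v, dp$Wc, dp$u)
}

# Pairwise-complete correlation target from incomplete data: the
# observable stand-in for the complete-data correlation structure.
observed_correlation <- function(X_tilde) {
  r <- suppressWarnings(stats::cor(X_tilde, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

#' Train the adversarial imputer
#'
#' Alternating training: each round samples a minibatch, draws fresh fill
#' noise, takes one discriminator Adam step (binary cross-entropy of the
#' probability grid against the mask, plus L2 weight decay) and one
#' generator Adam step (adversarial + `alpha` x reconstruction + `beta` x
#' correlation loss). The generator is checkpointed whenever both the
#' training-batch objective and the held-out criterion improve; the
#' checkpointed model is returned. Fully reproducible from `cfg$seed`.
#'
#' The held-out criterion is the masked-entry RMSE on the validation rows
#' against `X_true` when complete ground truth is available (simulation
#' mode), otherwise the generator objective on the validation rows; with
#' no validation rows it falls back to the training criterion.
#'
#' @param bundle a [data_bundle()] on the normalized scale (its `X` may
#'   already contain `NaN` at missing cells).
#' @param M binary mask aligned with `bundle$X`.
#' @param cfg a [train_config()].
#' @param X_true optional complete ground-truth matrix (simulation mode).
#' @param val_idx optional integer row indices held out for checkpoint
#'   selection; excluded from gradient updates.
#' @return object of class `trained_model` with elements `generator`,
#'   `discriminator`, `cfg`, `selection` (best train value, best held-out
#'   value, epoch), and `history` (per-epoch loss data frame).
#' @export
dtae_train <- function(bundle, M, cfg = train_config(), X_true = NULL,
                       val_idx = NULL) {
  stopifnot(inherits(bundle, "data_bundle"))
  M <- check_binary_mask(M)
  check_same_shape(bundle$X, M, c("X", "M"))
  m <- nrow(bundle$X)
  n <- ncol(bundle$X)
  C <- n_classes(bundle)
  use_labels <- cfg$use_labels && C > 0L
  Yfull <- if (use_labels) onehot(bundle$y, C) else matrix(0, m, max(C, 0L))

  X_tilde <- apply_mask(ifelse(is.finite(bundle$X), bundle$X, 0), M)
  train_idx <- setdiff(seq_len(m), val_idx)
  if (!length(train_idx)) stop("no training rows left after holding out val_idx")
  r_target <- observed_correlation(X_tilde[train_idx, , drop = FALSE])

  gen <- init_generator(n, max(C, 0L), cfg$enc_widths, cfg$dec_widths,
                        seed = derive_seed(cfg$seed, 11L))
  dis <- init_discriminator(n, max(C, 0L), cfg$conv_channels, cfg$att_dim,
                            seed = derive_seed(cfg$seed, 12L))
  g_theta <- nn_flatten(gen[c("W", "b")])
  d_theta <- nn_flatten(dis[c("Wconv", "bconv", "W1", "W2", "v", "Wc", "u", "b0")])
  g_skel <- gen[c("W", "b")]
  d_skel <- dis[c("Wconv", "bconv", "W1", "W2", "v", "Wc", "u", "b0")]
  g_adam <- adam_init(g_theta)
  d_adam <- adam_init(d_theta)
  set_gen <- function(p, theta) {
    p[c("W", "b")] <- nn_unflatten(theta, g_skel)
    p
  }
  set_dis <- function(p, theta) {
    p[names(d_skel)] <- nn_unflatten(theta, d_skel)
    p
  }

  batch_size <- if (length(train_idx) < 256L) length(train_idx) else
    min(cfg$batch_size, length(train_idx))
  lam <- cfg$weights$lam
  n_dw <- length(disc_weight_vector(dis))
  hist <- matrix(NA_real_, cfg$epochs, 6L,
                 dimnames = list(NULL, c("epoch", "L_gen", "L_rec", "L_cor",
                                         "L_D", "gen_total")))
  val_hist <- rep(NA_real_, cfg$epochs)

  best_train <- Inf
  best_val <- Inf
  best_epoch <- NA_integer_
  best_theta <- g_theta
  best_d_theta <- d_theta
  since_improve <- 0L

  val_criterion <- function(gen_now) {
    if (!length(val_idx)) return(NULL)
    vi <- val_idx
    nf <- noise_fill(X_tilde[vi, , drop = FALSE], cfg$z_sigma,
                     seed = derive_seed(cfg$seed, 999L))
    G_out <- generator_forward(gen_now, nf$X_prime, M[vi, , drop = FALSE],
                               Yfull[vi, , drop = FALSE], nf$Z,
                               detracking = cfg$use_detracking)
    if (!is.null(X_true) && any(M[vi, ] == 0)) {
      rmse_missing(X_true[vi, , drop = FALSE],
                   compose_imputed(X_tilde[vi, , drop = FALSE],
                                   M[vi, , drop = FALSE], G_out),
                   M[vi, , drop = FALSE])
    } else {
      Mh <- discriminator_forward(set_dis(dis, d_theta),
                                  compose_imputed(X_tilde[vi, , drop = FALSE],
                                                  M[vi, , drop = FALSE], G_out),
                                  Yfull[vi, , drop = FALSE],
                                  use_attention = cfg$use_attention)
      lg <- if (any(M[vi, ] == 0)) generator_adv_loss(M[vi, , drop = FALSE], Mh) else 0
      lr_ <- reconstruction_loss(X_tilde[vi, , drop = FALSE], G_out,
                                 M[vi, , drop = FALSE])
      generator_total(lg, lr_, 0, cfg$weights)
    }
  }

  for (epoch in seq_len(cfg$epochs)) {
    ep_seed <- derive_seed(cfg$seed, epoch)
    batch <- with_seed(ep_seed,
                       train_idx[sample.int(length(train_idx), batch_size)])
    Xb_t <- X_tilde[batch, , drop = FALSE]
    Mb <- M[batch, , drop = FALSE]
    Yb <- Yfull[batch, , drop = FALSE]
    nf <- noise_fill(Xb_t, cfg$z_sigma, seed = derive_seed(ep_seed, 7L))
    Xb_obs <- ifelse(Mb == 1, Xb_t, 0)

    gen <- set_gen(gen, g_theta)
    dis <- set_dis(dis, d_theta)

    # --- discriminator step (generator pass reused for the G step below,
    # since G's parameters do not change in between) ---
    G_out <- generator_forward(gen, nf$X_prime, Mb, Yb, nf$Z,
                               detracking = cfg$use_detracking, cache = TRUE)
    X_hat <- compose_imputed(Xb_t, Mb, G_out)
    Mh <- discriminator_forward(dis, X_hat, Yb,
                                use_attention = cfg$use_attention, cache = TRUE)
    p <- clip_prob(Mh)
    N <- length(Mh)
    L_D <- discriminator_loss(Mb, Mh, disc_weight_vector(dis), lam)
    dMh <- -(Mb / p - (1 - Mb) / (1 - p)) / N
    bk <- discriminator_backward(dis, Mh, dMh, input_grad = FALSE)
    d_grad <- nn_flatten(bk$grads)
    if (lam > 0) {
      reg <- nn_zeros_like(d_skel)
      for (nm in c("Wconv", "W1", "W2", "v", "Wc", "u")) {
        reg[[nm]] <- if (is.list(dis[[nm]])) lapply(dis[[nm]], function(w) 2 * lam * w / n_dw)
        else 2 * lam * dis[[nm]] / n_dw
      }
      d_grad <- d_grad + nn_flatten(reg)
    }
    upd <- adam_step(d_theta, d_grad, d_adam, cfg$learning_rate)
    d_theta <- upd$theta
    d_adam <- upd$state
    dis <- set_dis(dis, d_theta)

    # --- generator step ---
    Mh <- discriminator_forward(dis, X_hat, Yb,
                                use_attention = cfg$use_attention, cache = TRUE)
    n_miss <- sum(Mb == 0)
    n_obs <- sum(Mb == 1)
    L_gen <- if (n_miss > 0) -sum((1 - Mb) * log(clip_prob(Mh))) / n_miss else 0
    L_rec <- if (n_obs > 0) sum(Mb * (Xb_obs - G_out)^2) / n_obs else 0
    L_cor <- correlation_loss(NULL, X_hat, r_target = r_target)
    total <- generator_total(L_gen, L_rec, L_cor, cfg$weights)

    dX_hat <- matrix(0, batch_size, n)
    if (n_miss > 0) {
      dMh_g <- -(1 - Mb) / (clip_prob(Mh) * n_miss)
      adv <- discriminator_backward(dis, Mh, dMh_g, input_grad = TRUE)
      dX_hat <- dX_hat + adv$dX_hat
    }
    dX_hat <- dX_hat + cfg$weights$beta * correlation_loss_grad(X_hat, r_target)
    dG <- (1 - Mb) * dX_hat
    if (n_obs > 0) {
      dG <- dG + cfg$weights$alpha * 2 * Mb * (G_out - Xb_obs) / n_obs
    }
    g_grads <- generator_backward(gen, G_out, dG)
    upd <- adam_step(g_theta, nn_flatten(g_grads), g_adam, cfg$learning_rate)
    g_theta <- upd$theta
    g_adam <- upd$state

    hist[epoch, ] <- c(epoch, L_gen, L_rec, L_cor, L_D, total)
    if (!all(is.finite(hist[epoch, ]))) {
      bad <- colnames(hist)[which(!is.finite(hist[epoch, ]))[1L]]
      stop(sprintf("non-finite loss '%s' at epoch %d; reduce the learning rate",
                   bad, epoch))
    }

    # The held-out criterion only matters when the training criterion
    # improved (the checkpoint test is a conjunction), so it is evaluated
    # lazily; val_criterion entries stay NA on epochs where it was not
    # needed.
    val_now <- total
    if (total < best_train) {
      vc <- val_criterion(set_gen(gen, g_theta))
      if (!is.null(vc)) val_now <- vc
      val_hist[epoch] <- val_now
    }
    if (total < best_train && val_now < best_val) {
      best_train <- total
      best_val <- val_now
      best_epoch <- epoch
      best_theta <- g_theta
      best_d_theta <- d_theta
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= cfg$patience) break
    }
  }

  done <- !is.na(hist[, "epoch"])
  history <- as.data.frame(hist[done, , drop = FALSE])
  history$val_criterion <- val_hist[done]
  structure(list(generator = set_gen(gen, best_theta),
                 discriminator = set_dis(dis, best_d_theta),
                 cfg = cfg, col_names = bundle$col_names, C = max(C, 0L),
                 selection = list(best_value = best_train,
                                  best_test_value = best_val,
                                  epoch = best_epoch),
                 history = history),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: %d features, %d classes, %d epochs run\n",
              x$generator$n, x$C, nrow(x$history)))
  cat(sprintf("  checkpoint: epoch %d (train %.4g, held-out %.4g)\n",
              x$selection$epoch, x$selection$best_value,
              x$selection$best_test_value))
  invisible(x)
}

#' Impute missing cells with a trained generator
#'
#' Runs the checkpointed generator in inference mode on the masked table
#' and composes the result: observed values verbatim, generated values at
#' missing positions. Deterministic given `seed`.
#'
#' @param model a `trained_model` from [dtae_train()].
#' @param bundle a [data_bundle()] with the same column schema.
#' @param M binary mask aligned with `bundle$X`.
#' @param seed seed for the noise fill.
#' @return imputed matrix on the normalized scale (no missing cells).
#' @export
dtae_impute <- function(model, bundle, M, seed = 1L) {
  stopifnot(inherits(model, "trained_model"), inherits(bundle, "data_bundle"))
  M <- check_binary_mask(M)
  check_same_shape(bundle$X, M, c("X", "M"))
  if (ncol(bundle$X) != model$generator$n) {
    stop("column schema does not match the trained model")
  }
  cfg <- model$cfg
  C <- model$C
  use_labels <- cfg$use_labels && C > 0L && !is.null(bundle$y)
  Y <- if (use_labels) onehot(bundle$y, C) else matrix(0, nrow(bundle$X), C)
  X_tilde <- apply_mask(ifelse(is.finite(bundle$X), bundle$X, 0), M)
  nf <- noise_fill(X_tilde, cfg$z_sigma, seed = seed)
  G_out <- generator_forward(model$generator, nf$X_prime, M, Y, nf$Z,
                             detracking = cfg$use_detracking)
  compose_imputed(X_tilde, M, G_out)
}
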