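# Evaluation metrics (masked RMSE, random-forest classification score)
# and the cross-validated, repeated experimental protocol.

#' Root mean square error over missing entries
#'
#' `sqrt(sum_(M=0) (x - x_hat)^2 / #(M=0))`: imputation error measured
#' only where values were actually missing, on whatever common scale the
#' inputs share (the protocol uses the normalized `[0, 1]` scale).
#'
#' @param X ground-truth matrix.
#' @param X_hat imputed matrix.
#' @param M binary mask (1 = observed); at least one entry must be 0.
#' @return scalar RMSE.
#' @export
rmse_missing <- function(X, X_hat, M) {
  X <- as_num_matrix(X, "X")
  X_hat <- as_num_matrix(X_hat, "X_hat")
  M <- check_binary_mask(M)
  check_same_shape(X, X_hat, c("X", "X_hat"))
  check_same_shape(X, M, c("X", "M"))
  n_miss <- sum(M == 0)
  if (n_miss == 0L) stop("no missing entries to evaluate")
  sqrt(sum(((1 - M) * (X - X_hat))^2) / n_miss)
}

#' Classification accuracy from a confusion matrix
#'
#' Trace divided by total: the fraction of correctly classified samples.
#' The binary `(TP + TN) / (TP + TN + FP + FN)` form is the `C = 2`
#' special case.
#'
#' @param conf C x C confusion matrix, `conf[i, j]` = count of samples of
#'   true class `i` predicted as class `j`.
#' @return scalar in `[0, 1]`.
#' @export
rfc_score <- function(conf) {
  conf <- as_num_matrix(conf, "conf")
  if (nrow(conf) != ncol(conf)) stop("confusion matrix must be square")
  total <- sum(conf)
  if (total <= 0) stop("confusion matrix is empty")
  sum(diag(conf)) / total
}

#' Downstream random-forest classification of imputed data
#'
#' Fits a fixed random-forest classifier (100 trees, default depth,
#' seeded) on the imputed training table and evaluates it on the imputed
#' test table, returning the confusion matrix over all classes present in
#' either label vector.
#'
#' @param X_train,y_train imputed training matrix and labels (`0..C-1`).
#' @param X_test,y_test imputed test matrix and labels.
#' @param seed integer seed for the forest.
#' @param ntree number of trees (default 100).
#' @return C x C integer confusion matrix (true class in rows).
#' @export
downstream_classify <- function(X_train, y_train, X_test, y_test,
                                seed = 1L, ntree = 100L) {
  X_train <- as_num_matrix(X_train, "X_train")
  X_test <- as_num_matrix(X_test, "X_test")
  if (length(unique(y_train)) < 2L) {
    stop("training labels contain a single class; nothing to classify")
  }
  levs <- sort(unique(c(y_train, y_test)))
  ytr <- factor(y_train, levels = levs)
  colnames(X_train) <- colnames(X_test) <- paste0("f", seq_len(ncol(X_train)))
  fit <- with_seed(seed,
                   randomForest::randomForest(x = X_train, y = ytr,
                                              ntree = ntree))
  pred <- stats::predict(fit, X_test)
  conf <- table(factor(y_test, levels = levs), factor(pred, levels = levs))
  mat <- matrix(as.integer(conf), length(levs), length(levs),
                dimnames = list(true = levs, predicted = levs))
  mat
}

#' Run the cross-validated imputation protocol
#'
#' For every condition (mechanism x rate x method x variant): generate a
#' mask on the complete table, split the rows into `k_folds` folds (4:1
#' train:test at the default 5), fit each imputer, impute the test fold,
#' and score masked RMSE plus downstream random-forest accuracy; then
#' aggregate mean and standard deviation over folds x repeats. Masks are
#' regenerated with a fresh derived seed every repeat so the spread
#' reflects both mask and training randomness. A failure in one condition
#' is recorded and does not abort the sweep.
#'
#' @param bundle complete, labelled [data_bundle()] on the normalized
#'   scale.
#' @param mechanisms character vector of mechanism names (see
#'   [mechanism_mask()]).
#' @param rates numeric vector of target missing rates.
#' @param methods subset of `"dtae_cgan"`, `"mean"`, `"svd"`.
#' @param variants ablation variants applied to `"dtae_cgan"` (see
#'   [ablate_config()]); other methods ignore them.
#' @param k_folds folds per repeat (default 5).
#' @param n_repeats repeats (default 10).
#' @param cfg base [train_config()] for the adversarial imputer.
#' @param seed master seed for masks, splits, training and classifiers.
#' @param svd_rank rank for the SVD baseline (default `min(n - 1, 5)`).
#' @return list of class `eval_report`: `report` (aggregated data frame
#'   with mean/sd per condition), `runs` (per-run values), `failures`
#'   (data frame of recorded errors, possibly empty).
#' @export
run_protocol <- function(bundle, mechanisms = "mcar", rates = 0.2,
                         methods = c("dtae_cgan", "mean", "svd"),
                         variants = "full", k_folds = 5L, n_repeats = 10L,
                         cfg = train_config(), seed = 1L, svd_rank = NULL) {
  stopifnot(inherits(bundle, "data_bundle"))
  if (any(!is.finite(bundle$X))) stop("the protocol needs a complete table")
  if (is.null(bundle$y)) stop("the protocol needs labelled data")
  methods <- match.arg(methods, c("dtae_cgan", "mean", "svd"), several.ok = TRUE)
  X <- bundle$X
  y <- bundle$y
  m <- nrow(X)
  runs <- list()
  failures <- list()
  for (mech in mechanisms) for (rate in rates) {
    for (rep_i in seq_len(n_repeats)) {
      rep_seed <- derive_seed(seed, rep_i * 1000L + round(rate * 100))
      Mk <- mechanism_mask(X, mech, rate, seed = rep_seed)
      folds <- make_splits(m, k_folds, 1L, seed = rep_seed, y = y)[[1L]]
      X_tilde <- apply_mask(X, Mk)
      for (fold_i in seq_len(k_folds)) {
        test_idx <- folds[[fold_i]]
        train_idx <- setdiff(seq_len(m), test_idx)
        for (method in methods) {
          vars <- if (method == "dtae_cgan") variants else "full"
          for (variant in vars) {
            res <- tryCatch({
              X_imp <- switch(method,
                mean = mean_impute(X_tilde),
                svd = suppressWarnings(svd_impute(X_tilde, rank = svd_rank)),
                dtae_cgan = {
                  cfg_v <- ablate_config(cfg, variant)
                  cfg_v$seed <- derive_seed(rep_seed, fold_i)
                  mdl <- dtae_train(data_bundle(X_tilde, y, bundle$col_names),
                                    Mk, cfg_v, X_true = X,
                                    val_idx = test_idx)
                  dtae_impute(mdl, data_bundle(X_tilde, y, bundle$col_names),
                              Mk, seed = derive_seed(rep_seed, 500L + fold_i))
                })
              Mtest <- Mk[test_idx, , drop = FALSE]
              rmse <- if (any(Mtest == 0)) {
                rmse_missing(X[test_idx, , drop = FALSE],
                             X_imp[test_idx, , drop = FALSE], Mtest)
              } else NA_real_
              conf <- downstream_classify(X_imp[train_idx, , drop = FALSE],
                                          y[train_idx],
                                          X_imp[test_idx, , drop = FALSE],
                                          y[test_idx],
                                          seed = derive_seed(rep_seed, 77L))
              data.frame(mechanism = mech, rate = rate, method = method,
                         variant = variant, repeat_i = rep_i, fold = fold_i,
                         rmse = rmse, rfc = rfc_score(conf))
            }, error = function(e) {
              failures[[length(failures) + 1L]] <<- data.frame(
                mechanism = mech, rate = rate, method = method,
                variant = variant, repeat_i = rep_i, fold = fold_i,
                error = conditionMessage(e))
              NULL
            })
            if (!is.null(res)) runs[[length(runs) + 1L]] <- res
          }
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  report <- NULL
  if (!is.null(runs)) {
    key <- interaction(runs$mechanism, runs$rate, runs$method, runs$variant,
                       drop = TRUE)
    agg <- lapply(split(runs, key), function(g) {
      data.frame(mechanism = g$mechanism[1], rate = g$rate[1],
                 method = g$method[1], variant = g$variant[1],
                 rmse_mean = mean(g$rmse), rmse_sd = stats::sd(g$rmse),
                 rfc_mean = mean(g$rfc), rfc_sd = stats::sd(g$rfc),
                 n_runs = nrow(g))
    })
    report <- do.call(rbind, agg)
    rownames(report) <- NULL
    report <- report[order(report$mechanism, report$rate, report$method,
                           report$variant), , drop = FALSE]
  }
  structure(list(report = report, runs = runs,
                 failures = if (length(failures)) do.call(rbind, failures)
                 else data.frame()),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:\n")
  print(x$report, digits = 4)
  if (nrow(x$failures)) {
    cat(sprintf("  (%d condition(s) failed; see $failures)\n", nrow(x$failures)))
  }
  invisible(x)
}
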