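# Training-loop behaviour on deliberately small problems so the whole file
# stays inside a few seconds.

small_setup <- function(m = 60, n = 5, C = 2, seed = 21) {
  b <- generate_fixture(m, n, C, rho = 0.6, class_sep = 3, seed = seed)
  M <- mcar_mask(m, n, 0.25, seed = seed + 1)
  list(bundle = data_bundle(apply_mask(b$X, M), b$y, b$col_names),
       truth = b$X, M = M)
}

test_that("a single epoch runs one G and one D step and returns a model", {
  s <- small_setup()
  cfg <- train_config(epochs = 1, seed = 3)
  mdl <- dtae_train(s$bundle, s$M, cfg)
  expect_s3_class(mdl, "trained_model")
  expect_equal(nrow(mdl$history), 1L)
  expect_equal(mdl$selection$epoch, 1L)             # first epoch always saves
  expect_true(all(is.finite(unlist(mdl$history[, 2:6]))))
})

test_that("training is bit-reproducible from the config seed", {
  s <- small_setup()
  cfg <- train_config(epochs = 25, seed = 9)
  m1 <- dtae_train(s$bundle, s$M, cfg, X_true = s$truth, val_idx = 1:12)
  m2 <- dtae_train(s$bundle, s$M, cfg, X_true = s$truth, val_idx = 1:12)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$generator$W, m2$generator$W)
  # a different seed gives a different run
  m3 <- dtae_train(s$bundle, s$M, train_config(epochs = 25, seed = 10),
                   X_true = s$truth, val_idx = 1:12)
  expect_false(identical(m1$history$gen_total, m3$history$gen_total))
})

test_that("the generator objective decreases over training", {
  b <- generate_fixture(200, 6, 2, rho = 0.7, class_sep = 3, seed = 31)
  M <- mcar_mask(200, 6, 0.2, seed = 32)
  bundle <- data_bundle(apply_mask(b$X, M), b$y, b$col_names)
  mdl <- dtae_train(bundle, M, train_config(epochs = 200, seed = 5))
  h <- mdl$history$gen_total
  expect_lt(mean(h[151:200]), mean(h[1:50]))
})

test_that("checkpoint selection records a jointly improving epoch", {
  s <- small_setup()
  mdl <- dtae_train(s$bundle, s$M, train_config(epochs = 40, seed = 2),
                    X_true = s$truth, val_idx = 1:12)
  sel <- mdl$selection
  expect_lte(sel$epoch, 40L)
  expect_equal(sel$best_value,
               min(mdl$history$gen_total[seq_len(sel$epoch)]))
  # the recorded held-out value matches that epoch's criterion
  expect_equal(sel$best_test_value, mdl$history$val_criterion[sel$epoch])
})

test_that("imputation preserves observed values, fills everything, and is
           deterministic", {
  s <- small_setup()
  cfg <- train_config(epochs = 15, seed = 4)
  mdl <- dtae_train(s$bundle, s$M, cfg)
  X1 <- dtae_impute(mdl, s$bundle, s$M, seed = 6)
  X2 <- dtae_impute(mdl, s$bundle, s$M, seed = 6)
  expect_identical(X1, X2)
  expect_false(anyNA(X1))
  expect_equal(X1[s$M == 1], s$bundle$X[s$M == 1])
  # an all-ones mask returns the data untouched
  M1 <- matrix(1, 60, 5)
  full_bundle <- data_bundle(s$truth, s$bundle$y, s$bundle$col_names)
  expect_equal(dtae_impute(mdl, full_bundle, M1, seed = 1), s$truth,
               ignore_attr = TRUE)
  # schema mismatch is refused
  wrong <- data_bundle(matrix(0.5, 60, 4))
  expect_error(dtae_impute(mdl, wrong, matrix(1, 60, 4)), "schema")
})

test_that("ablation variants map onto the three toggles", {
  cfg <- train_config()
  expect_true(all(unlist(cfg[c("use_attention", "use_detracking",
                               "use_labels")])))
  off <- ablate_config(cfg, "wo_dtae_attention_labels")
  expect_false(off$use_attention || off$use_detracking || off$use_labels)
  wa <- ablate_config(cfg, "wo_attention")
  expect_false(wa$use_attention)
  expect_true(wa$use_detracking && wa$use_labels)
  wd <- ablate_config(cfg, "wo_dtae")
  expect_false(wd$use_detracking)
  expect_true(wd$use_attention && wd$use_labels)
  expect_error(ablate_config(cfg, "wo_everything"))
})

test_that("disabling labels changes the generator output on labelled data", {
  s <- small_setup(seed = 41)
  cfg_on <- train_config(epochs = 10, seed = 8)
  cfg_off <- ablate_config(cfg_on, "wo_dtae_attention_labels")
  cfg_off$use_attention <- TRUE
  cfg_off$use_detracking <- TRUE                    # isolate the label toggle
  m_on <- dtae_train(s$bundle, s$M, cfg_on)
  m_off <- dtae_train(s$bundle, s$M, cfg_off)
  X_on <- dtae_impute(m_on, s$bundle, s$M, seed = 1)
  X_off <- dtae_impute(m_off, s$bundle, s$M, seed = 1)
  expect_gt(max(abs(X_on[s$M == 0] - X_off[s$M == 0])), 1e-6)
})
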