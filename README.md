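# dtaecgan

Conditional adversarial imputation of missing values in numeric tables,
built around two architectural ideas:

* a **detracking autoencoder generator** — output feature *j* has *no
  computational path* from input feature *j*, so every fill must be
  inferred from the other features (plus the mask, fill noise, and the
  class label as a conditioning channel), never copied;
* a **convolution + additive-attention discriminator** that returns a
  probability grid `M_hat` of the same shape as the data — its per-cell
  estimate that a value is observed rather than generated — with no
  hint matrix.

With mask `M` (1 = observed), incomplete data `X_tilde = X ⊙ M`, and
noise-filled input `X'`, the imputation is the composition

```
X_hat = M ⊙ X_tilde + (1 − M) ⊙ G(X', M, (1−M)⊙z | y)
```

trained by alternating Adam steps on

```
generator:      L_gen + α·L_rec + β·L_cor        (α = 200, β = 1.5)
discriminator:  −BCE(M_hat, M) + λ·mean(w_D²)    (λ = 0.6 small / 0.3 large tables)
```

where `L_gen = −mean log M_hat` over missing cells, `L_rec` is the
observed-entry reconstruction error, and `L_cor` penalises distortion of
the Pearson correlation matrix. The package also provides the
missingness-mechanism simulators (MCAR, softmax-over-samples MAR/MNAR,
column-pattern MAR, below-median MNAR), column-mean and iterative
truncated-SVD baselines, masked-RMSE / downstream random-forest
evaluation, and a repeated cross-validated protocol harness. The
networks and all their gradients are implemented in base R and verified
against finite differences in the test suite.

For whom: statisticians and data engineers who need a reproducible,
dependency-light adversarial imputer for numeric tables with class
labels, or a calibrated testbed for missingness mechanisms.

## Worked example

```r
library(dtaecgan)

# hand-checkable 6 x 3 table with 4 missing cells
we <- worked_example()
mean_impute(we$X_tilde)[we$M == 0]
#> 0.55 0.52 0.52 0.55
rmse_missing(we$X, mean_impute(we$X_tilde), we$M)
#> 0.2518928

# study fixture: 600 x 10, 3 classes, equicorrelation 0.7, 20% MCAR
b <- generate_fixture(600, 10, 3, rho = 0.7, class_sep = 3, seed = 101)
M <- mcar_mask(600, 10, 0.2, seed = 202)
test_idx <- make_splits(600, 5, 1, seed = 303, y = b$y)[[1]][[1]]
bundle <- data_bundle(apply_mask(b$X, M), b$y, b$col_names)

model <- dtae_train(bundle, M, train_config(epochs = 1000, seed = 7),
                    X_true = b$X, val_idx = test_idx)   # ~1 min CPU
model
#> trained_model: 10 features, 3 classes, 1000 epochs run
#>   checkpoint: epoch 788 (train 1.246, held-out 0.09847)

X_hat <- dtae_impute(model, bundle, M, seed = 9)
rmse_missing(b$X[test_idx, ], X_hat[test_idx, ], M[test_idx, ])
#> 0.09859133   # adversarial imputer
rmse_missing(b$X[test_idx, ], mean_impute(bundle$X)[test_idx, ], M[test_idx, ])
#> 0.1753952    # column-mean baseline
```

The held-out masked RMSE (here ~0.099 on the normalized `[0, 1]` scale,
vs ~0.175 for mean imputation) is the fraction-of-range error at the
cells that were actually missing; the checkpoint line shows which epoch
Algorithm-style dual-improvement selection kept.

`run_protocol()` wraps the full experimental design — mechanisms x
rates x methods x ablation variants, masks regenerated per repeat,
stratified 5-fold splits, RMSE plus downstream random-forest accuracy,
aggregated mean ± sd — and returns both per-run values and the
aggregated report.

A thin CLI wrapper ships in `inst/exec/dtaecgan`
(`simulate-missing`, `impute`) over the same functions.

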