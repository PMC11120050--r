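test_that("min-max normalization maps endpoints, handles constants, and inverts", {
  out <- minmax_normalize(cbind(a = c(0, 5, 10)))
  expect_equal(unname(out$X[, 1]), c(0, 0.5, 1))

  const <- minmax_normalize(cbind(k = c(7, 7, 7)))
  expect_equal(unname(const$X[, 1]), c(0, 0, 0))
  expect_equal(unname(const$norm[, 1]), c(7, 7))
  expect_equal(unname(minmax_denormalize(const$X, const$norm)[, 1]), c(7, 7, 7))

  set.seed(11)
  A <- matrix(rnorm(60, sd = 13) + 5, 12, 5)
  nz <- minmax_normalize(A)
  expect_true(all(nz$X >= 0 & nz$X <= 1))
  expect_equal(minmax_denormalize(nz$X, nz$norm), A, tolerance = 1e-12)

  withNA <- A
  withNA[3, 2] <- NaN
  nz2 <- minmax_normalize(withNA)
  expect_true(is.nan(nz2$X[3, 2]))

  allNA <- A
  allNA[, 4] <- NaN
  expect_error(minmax_normalize(allNA), "V4")
})

test_that("masking marks missing cells as NaN and composition restores them", {
  X <- matrix(c(1, 3, 2, 4), 2, 2)
  M <- matrix(c(1, 1, 0, 1), 2, 2)
  Xt <- apply_mask(X, M)
  expect_equal(Xt[1, 2], NaN)
  expect_equal(Xt[c(1, 2, 4)], X[c(1, 2, 4)])

  expect_equal(apply_mask(X, matrix(1, 2, 2)), X)
  expect_true(all(is.nan(apply_mask(X, matrix(0, 2, 2)))))
  expect_error(apply_mask(X, matrix(1, 3, 2)), "shape")
  expect_error(apply_mask(X, matrix(0.5, 2, 2)), "0 or 1")

  G <- matrix(c(9, 9, 5, 9), 2, 2)
  expect_equal(compose_imputed(Xt, M, G), matrix(c(1, 3, 5, 4), 2, 2))
  expect_equal(compose_imputed(Xt, matrix(1, 2, 2) * M, X), X) # observed kept
  expect_error(compose_imputed(Xt, M, Xt), "NaN")

  # mask/compose consistency for random binary masks
  for (s in 1:5) {
    Xr <- rand_matrix(6, 4, s)
    Mr <- rand_mask(6, 4, 0.5, s)
    expect_equal(compose_imputed(apply_mask(Xr, Mr), Mr, Xr), Xr)
  }
})

test_that("noise fill is seeded, clipped, and exact at observed cells", {
  Xt <- apply_mask(rand_matrix(8, 5, 1), rand_mask(8, 5, 0.6, 2))
  nf1 <- noise_fill(Xt, 0.05, seed = 9)
  nf2 <- noise_fill(Xt, 0.05, seed = 9)
  expect_identical(nf1$X_prime, nf2$X_prime)
  expect_false(anyNA(nf1$X_prime))
  obs <- is.finite(Xt)
  expect_identical(nf1$X_prime[obs], Xt[obs])
  expect_true(all(nf1$X_prime >= 0 & nf1$X_prime <= 1))

  zero <- noise_fill(Xt, 0, seed = 1)
  expect_true(all(zero$X_prime[!obs] == 0))

  # CLT bound on the mean of ~1e4 clipped fills at sigma = 0.01: clipping
  # at 0 halves the mass, so compare the mean of the nonzero draws' signed
  # pre-clip distribution via the raw Z matrix instead.
  big <- apply_mask(matrix(0.5, 100, 100), matrix(0, 100, 100))
  nf <- noise_fill(big, 0.01, seed = 3)
  fills <- nf$X_prime
  # half the draws clip to exactly 0; the rest are half-normal with mean
  # sigma*sqrt(2/pi), so overall mean ~ sigma/sqrt(2*pi) ~ 0.004
  expect_lt(abs(mean(fills) - 0.01 / sqrt(2 * pi)), 3 * 0.01 / 100)
})

test_that("splits partition indices, stratify by class, and are reproducible", {
  sp <- make_splits(10, k_folds = 5, n_repeats = 2, seed = 4)
  for (r in 1:2) {
    folds <- sp[[r]]
    expect_equal(sort(unlist(folds)), 1:10)
    expect_true(all(lengths(folds) == 2))
  }
  expect_identical(make_splits(10, 5, 2, seed = 4), sp)
  expect_error(make_splits(3, 5), "smaller")

  y <- rep(0:2, c(30, 30, 40))
  st <- make_splits(100, 5, 1, seed = 1, y = y)[[1]]
  for (f in st) {
    tab <- table(factor(y[f], levels = 0:2))
    expect_true(all(abs(tab - c(6, 6, 8)) <= 1))
  }
})

test_that("CSV round-trip preserves values, missing cells, and labels", {
  path <- tempfile(fileext = ".csv")
  X <- rand_matrix(7, 3, 5) * 100
  X[2, 1] <- NaN
  X[5, 3] <- NaN
  y <- c(0L, 1L, 0L, 2L, 1L, 0L, 2L)
  write_table_csv(X, path, y = y, col_names = c("aa", "bb", "cc"))
  back <- read_table_csv(path, label_col = "label")
  expect_equal(back$col_names, c("aa", "bb", "cc"))
  expect_equal(back$y, y)
  expect_true(is.nan(back$X[2, 1]) && is.nan(back$X[5, 3]))
  fin <- is.finite(X)
  expect_equal(back$X[fin], X[fin], tolerance = 1e-12)
})

test_that("data_bundle validates scale, labels, and norm shape", {
  X <- rand_matrix(5, 3, 1)
  b <- data_bundle(X, y = c(0L, 1L, 0L, 1L, 1L))
  expect_s3_class(b, "data_bundle")
  expect_error(data_bundle(X * 10), "normalized")
  expect_error(data_bundle(X, y = 1:3), "label")
  expect_error(data_bundle(X, norm = matrix(0, 3, 3)), "2 x n")
})
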