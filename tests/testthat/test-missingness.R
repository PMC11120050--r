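test_that("MCAR masks are calibrated, seeded, and exchangeable across rows", {
  M <- mcar_mask(2000, 10, 0.2, seed = 1)
  expect_true(all(M %in% c(0, 1)))
  expect_lt(abs(mean(M == 0) - 0.2), 0.01)        # binomial 3-sigma ~ 0.0085
  expect_identical(mcar_mask(2000, 10, 0.2, seed = 1), M)

  for (rate in c(0.1, 0.4, 0.7)) {
    Mr <- mcar_mask(2000, 10, rate, seed = 2)
    expect_lt(abs(mean(Mr == 0) - rate), 0.015)
  }
  expect_error(mcar_mask(10, 3, 1.2), "strictly in")
  expect_error(mcar_mask(10, 3, 0), "strictly in")

  # exchangeability: row totals look binomial, no row structure
  tot <- rowSums(mcar_mask(500, 20, 0.3, seed = 3) == 0)
  expect_lt(abs(mean(tot) - 6), 0.5)
})

test_that("softmax MAR: column 1 is MCAR, column means hit the target rate, and
           later columns depend on preceding ones", {
  X <- rand_matrix(2000, 6, 7)
  M <- mar_softmax_mask(X, 0.2, seed = 3)
  P <- attr(M, "prob")
  expect_true(all(P[, 1] == 0.2))                  # empty sum => uniform
  expect_equal(colMeans(P), rep(0.2, 6), tolerance = 1e-12)
  expect_lt(abs(mean(M == 0) - 0.2), 0.015)

  # dependence oracle: logistic regression of missingness in column j on
  # the preceding columns, with a permutation null on the deviance drop
  set.seed(42)
  Xbig <- matrix(runif(5000 * 4), 5000, 4)
  Mbig <- mar_softmax_mask(Xbig, 0.25, seed = 9)
  miss <- as.integer(Mbig[, 3] == 0)
  dev_obs <- deviance(glm(miss ~ Xbig[, 1] + Xbig[, 2], family = binomial))
  dev_null <- replicate(200, {
    sh <- sample(miss)
    deviance(glm(sh ~ Xbig[, 1] + Xbig[, 2], family = binomial))
  })
  # permutation p-value < 0.01: observed deviance lower than every null
  expect_lt((1 + sum(dev_null <= dev_obs)) / 201, 0.01)
})

test_that("softmax MNAR prefers removing large-weight-small-value cells and is
           calibrated", {
  X <- rand_matrix(2000, 5, 8)
  M <- mnar_softmax_mask(X, 0.2, seed = 4)
  expect_equal(colMeans(attr(M, "prob")), rep(0.2, 5), tolerance = 1e-12)
  expect_lt(abs(mean(M == 0) - 0.2), 0.015)

  # constant column: uniform softmax => exactly MCAR probabilities
  Xc <- cbind(rep(0.5, 400), rand_matrix(400, 1, 1))
  Pc <- attr(mnar_softmax_mask(Xc, 0.3, seed = 2), "prob")
  expect_true(all(abs(Pc[, 1] - 0.3) < 1e-12))

  # with w_j > 0 larger values survive: value/missingness correlation < 0
  set.seed(5)
  Xb <- matrix(runif(5000), 5000, 1)
  Mb <- mnar_softmax_mask(Xb, 0.3, seed = 5, W = 0.9)
  expect_lt(cor(Xb[, 1], as.integer(Mb[, 1] == 0)), -0.05)
})

test_that("patterned MAR masks confine missingness to the stated column blocks", {
  M1 <- mar_pattern_mask(200, 9, 0.5, "one_third", seed = 1)
  M2 <- mar_pattern_mask(200, 9, 0.5, "two_thirds", seed = 1)
  expect_equal(attr(M1, "eligible_cols"), 4:6)     # 0-based 3,4,5
  expect_true(all(M1[, c(1:3, 7:9)] == 1))
  expect_true(any(M1[, 4:6] == 0))
  expect_true(all(M2[, 4:6] == 1))
  expect_true(any(M2[, c(1:3, 7:9)] == 0))
  # eligible sets partition the columns
  expect_equal(sort(c(attr(M1, "eligible_cols"), attr(M2, "eligible_cols"))), 1:9)
  expect_error(mar_pattern_mask(10, 2, 0.2, "one_third"), "n >= 3")
  expect_error(mar_pattern_mask(10, 9, 0.2, "diagonal"))
})

test_that("median MNAR removes only strictly-below-median cells at the target
           rate", {
  Xs <- cbind(c(1, 2, 3, 4, 5) / 5)
  Ms <- mnar_median_mask(Xs, 0.3, seed = 1)
  expect_true(all(Ms[3:5, 1] == 1))                # median 3/5 and above survive

  X <- matrix(runif(2000 * 4), 2000, 4)
  M <- mnar_median_mask(X, 0.2, seed = 6)
  for (j in 1:4) {
    med <- sort(X[, j])[1000]                      # lower median
    expect_true(all(X[M[, j] == 0, j] < med))
    expect_lt(abs(mean(M[, j] == 0) - 0.2), 0.02)
  }
  expect_warning(mnar_median_mask(X, 0.6, seed = 1), "eligible")
})

test_that("mechanism dispatcher reproduces the dedicated generators", {
  X <- rand_matrix(100, 6, 3)
  expect_identical(mechanism_mask(X, "mcar", 0.2, seed = 5),
                   mcar_mask(100, 6, 0.2, seed = 5))
  expect_identical(mechanism_mask(X, "mnar_median", 0.2, seed = 5),
                   mnar_median_mask(X, 0.2, seed = 5))
  expect_error(mechanism_mask(X, "adversarial", 0.2))
})
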