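# The networks' defining properties: detracking zero-self-dependence,
# attention normalization, and hand-derived gradients agreeing with
# central finite differences.

gen_inputs <- function(m, n, C, seed) {
  set.seed(seed)
  list(Xp = matrix(runif(m * n), m, n),
       M = rand_mask(m, n, 0.7, seed + 1),
       Y = onehot(sample(0:(C - 1), m, replace = TRUE), C),
       Z = matrix(rnorm(m * n, 0, 0.01), m, n))
}

test_that("detracking severs every output column from its own input", {
  for (s in 1:4) {
    inp <- gen_inputs(5, 6, 2, s)
    gp <- init_generator(6, 2, seed = s * 13)
    expect_lt(self_dependence(gp, inp$Xp, inp$M, inp$Y, inp$Z, TRUE), 1e-6)
    # negative control: without detracking the dependence is material
    expect_gt(self_dependence(gp, inp$Xp, inp$M, inp$Y, inp$Z, FALSE), 1e-3)
  }
  # n = 2 limit: output column 1 depends only on input column 2
  inp <- gen_inputs(4, 2, 2, 9)
  gp2 <- init_generator(2, 2, enc_widths = c(4, 3), dec_widths = c(3), seed = 1)
  expect_lt(self_dependence(gp2, inp$Xp, inp$M, inp$Y, inp$Z, TRUE), 1e-6)
  expect_error(generator_forward(init_generator(1, 0, seed = 1),
                                 matrix(0.5, 3, 1), matrix(1, 3, 1)),
               "n < 2")
})

test_that("generator forward obeys its shape, range, and determinism contracts", {
  inp <- gen_inputs(7, 5, 3, 2)
  gp <- init_generator(5, 3, seed = 4)
  G1 <- generator_forward(gp, inp$Xp, inp$M, inp$Y, inp$Z)
  G2 <- generator_forward(gp, inp$Xp, inp$M, inp$Y, inp$Z)
  expect_identical(G1, G2)
  expect_equal(dim(G1), c(7L, 5L))
  expect_true(all(G1 > 0 & G1 < 1))
  bad_Y <- inp$Y
  bad_Y[1, ] <- 0.5
  expect_error(generator_forward(gp, inp$Xp, inp$M, bad_Y, inp$Z), "sum to 1")
  expect_error(generator_forward(gp, apply_mask(inp$Xp, inp$M), inp$M, inp$Y),
               "NaN")
})

test_that("generator parameter gradients match finite differences", {
  inp <- gen_inputs(4, 4, 2, 3)
  for (detrack in c(TRUE, FALSE)) {
    gp <- init_generator(4, 2, enc_widths = c(6, 4), dec_widths = c(5),
                         seed = 21)
    fwd <- generator_forward(gp, inp$Xp, inp$M, inp$Y, inp$Z,
                             detracking = detrack, cache = TRUE)
    # arbitrary smooth scalar loss sum(sin(G)) with dL/dG = cos(G)
    grads <- nn_flat <- dtaecgan:::nn_flatten(
      generator_backward(gp, fwd, cos(fwd)))
    theta <- dtaecgan:::nn_flatten(gp[c("W", "b")])
    f <- function(th) {
      p <- gp
      p[c("W", "b")] <- dtaecgan:::nn_unflatten(th, gp[c("W", "b")])
      sum(sin(generator_forward(p, inp$Xp, inp$M, inp$Y, inp$Z,
                                detracking = detrack)))
    }
    set.seed(7)
    idx <- sample(length(theta), 30)
    expect_equal(numeric_grad(f, theta, idx), grads[idx], tolerance = 1e-6)
  }
})

test_that("attention weights normalise to one and match the closed form", {
  set.seed(8)
  d <- 4
  a <- 3
  v <- rnorm(a)
  w1 <- matrix(rnorm(a * d), a, d)
  w2 <- matrix(rnorm(a * d), a, d)
  for (s in 1:10) {
    h_bar <- matrix(rnorm(6 * d), 6, d)
    h_t <- rnorm(d)
    att <- attention(h_bar, h_t, v, w1, w2)
    expect_equal(sum(att$alpha_ts), 1, tolerance = 1e-6)
    expect_equal(att$c_t, drop(crossprod(h_bar, att$alpha_ts)))
  }
  # v = 0: all scores 0, uniform weights, context = mean state
  att0 <- attention(matrix(rnorm(5 * d), 5, d), rnorm(d), rep(0, a), w1, w2)
  expect_equal(att0$alpha_ts, rep(0.2, 5))

  # hand-set closed form: scores (0, tanh(10)), softmax ~ (0.269, 0.731)
  h_bar <- rbind(c(0, 0), c(10, 0))
  att2 <- attention(h_bar, c(0, 0), v = c(1, 0), w1 = diag(2), w2 = diag(2))
  expected <- exp(c(0, tanh(10))) / sum(exp(c(0, tanh(10))))
  expect_equal(att2$alpha_ts, expected, tolerance = 1e-12)
  expect_equal(att2$alpha_ts, c(0.2689, 0.7311), tolerance = 1e-3)
  expect_error(attention(matrix(0, 0, 2), c(0, 0), c(1, 0), diag(2), diag(2)),
               "at least one")
})

test_that("discriminator output is a probability grid and is deterministic", {
  inp <- gen_inputs(6, 5, 2, 4)
  dp <- init_discriminator(5, 2, seed = 3)
  Mh <- discriminator_forward(dp, inp$Xp, inp$Y)
  expect_equal(dim(Mh), c(6L, 5L))
  expect_true(all(Mh > 0 & Mh < 1))
  expect_identical(discriminator_forward(dp, inp$Xp, inp$Y), Mh)
  expect_error(discriminator_forward(dp, apply_mask(inp$Xp, inp$M), inp$Y),
               "finite")
})

test_that("discriminator gradients (parameters and input) match finite
           differences, with and without attention", {
  m <- 4
  n <- 4
  C <- 2
  inp <- gen_inputs(m, n, C, 5)
  nms <- c("Wconv", "bconv", "W1", "W2", "v", "Wc", "u", "b0")
  for (use_att in c(TRUE, FALSE)) {
    dp <- init_discriminator(n, C, conv_channels = c(5, 4, 3), att_dim = 3,
                             seed = 17)
    fwd <- discriminator_forward(dp, inp$Xp, inp$Y, use_attention = use_att,
                                 cache = TRUE)
    bk <- discriminator_backward(dp, fwd, 3 * cos(3 * fwd), input_grad = TRUE)
    theta <- dtaecgan:::nn_flatten(dp[nms])
    f <- function(th) {
      p <- dp
      p[nms] <- dtaecgan:::nn_unflatten(th, dp[nms])
      sum(sin(3 * discriminator_forward(p, inp$Xp, inp$Y,
                                        use_attention = use_att)))
    }
    set.seed(use_att + 1)
    idx <- sample(length(theta), 35)
    expect_equal(numeric_grad(f, theta, idx),
                 dtaecgan:::nn_flatten(bk$grads)[idx], tolerance = 1e-6)

    fx <- function(xv) {
      sum(sin(3 * discriminator_forward(dp, matrix(xv, m, n), inp$Y,
                                        use_attention = use_att)))
    }
    expect_equal(numeric_grad(fx, c(inp$Xp)), c(bk$dX_hat), tolerance = 1e-6)
    # the adversarial signal path is alive: input gradient nonzero somewhere
    expect_gt(max(abs(bk$dX_hat)), 0)
  }
})

test_that("forward maps stay finite on [0,1] inputs at default widths", {
  inp <- gen_inputs(20, 12, 4, 6)
  gp <- init_generator(12, 4, seed = 2)
  dp <- init_discriminator(12, 4, seed = 2)
  G <- generator_forward(gp, inp$Xp, inp$M, inp$Y, inp$Z)
  Mh <- discriminator_forward(dp, inp$Xp, inp$Y)
  expect_true(all(is.finite(G)) && all(is.finite(Mh)))
})
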