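# Architecture: shape trace, attention, LSTM cell, BiLSTM, softmax head.

test_that("shape trace of the default spec reproduces the recommended stack", {
  st <- shape_trace(model_spec(512))
  expected <- data.frame(
    stage = c("Convolution-1", "Convolution-2", "Pool_1", "BN_1", "Drop_1",
              "Convolution-3", "Convolution-4", "Pool_2", "BN_2", "Drop_2",
              "Convolution-5", "Convolution-6", "Pool_3", "BN_3", "Drop_3",
              "Convolution-7", "BN_4"),
    channels = c(32, 32, 32, 32, 32, 64, 64, 64, 64, 64,
                 128, 128, 128, 128, 128, 64, 64),
    length = c(256, 126, 63, 63, 63, 30, 13, 6, 6, 6, 4, 3, 2, 2, 2, 2, 2),
    stringsAsFactors = FALSE)
  expect_equal(st, expected, ignore_attr = TRUE)
})

test_that("reduced stacks end in a length-2, 64-channel map for small inputs", {
  for (len in c(3, 8, 16, 24, 32, 128, 256)) {
    st <- shape_trace(model_spec(len))
    expect_equal(unlist(st[nrow(st), c("channels", "length")]),
                 c(channels = 64, length = 2))
  }
  expect_error(model_spec(1))
})

test_that("multiplicative residual combination", {
  f <- array(rnorm(24), c(2, 3, 4))
  expect_equal(multiplicative_residual(array(1, dim(f)), f), f)
  expect_equal(multiplicative_residual(f, array(0, dim(f))),
               array(0, dim(f)))
  expect_equal(multiplicative_residual(array(3, c(1, 1, 1)),
                                       array(5, c(1, 1, 1)))[1], 15)
  expect_error(multiplicative_residual(array(1, c(2, 2, 2)),
                                       array(1, c(2, 2, 3))), "match")
})

test_that("self-attention: single position, uniform keys, saturation limit", {
  # n = 1: weight 1, output = V
  X <- matrix(rnorm(4), 1, 4)
  W <- diag(4)
  sa <- self_attention(X, W, W, W)
  expect_equal(sa$weights, matrix(1, 1, 1))
  expect_equal(sa$output, X %*% W)
  # identical key rows -> uniform weights 1/n
  X2 <- rbind(c(1, 0), c(5, 3), c(-2, 1))
  Wk0 <- matrix(0, 2, 2)                      # K rows all zero (identical)
  sa2 <- self_attention(X2, diag(2), Wk0, diag(2))
  expect_equal(sa2$weights, matrix(1 / 3, 3, 3))
  # 2x2 saturation: Q = K = c*I with large c -> weights ~ I, output ~ V
  c_big <- 40
  X3 <- diag(2) * sqrt(c_big)
  sa3 <- self_attention(X3, diag(2) * sqrt(c_big), diag(2) * sqrt(c_big),
                        diag(2))
  expect_equal(sa3$weights, diag(2), tolerance = 1e-6)
  expect_equal(sa3$output, X3, tolerance = 1e-4)
  # weight rows always sum to one
  expect_equal(rowSums(sa2$weights), rep(1, 3))
})

test_that("lstm_step closed forms and independent transcription", {
  H <- 3; D <- 2
  zero <- list(W_f = matrix(0, H, H + D), W_i = matrix(0, H, H + D),
               W_o = matrix(0, H, H + D), W_c = matrix(0, H, H + D),
               b_f = numeric(H), b_i = numeric(H), b_o = numeric(H),
               b_c = numeric(H))
  c_prev <- c(0.4, -1, 2)
  st <- lstm_step(c(1, -1), numeric(H), c_prev, zero)
  expect_equal(st$c, 0.5 * c_prev)
  expect_equal(st$h, 0.5 * tanh(0.5 * c_prev))
  # saturated forget gate preserves the cell state
  sat <- zero; sat$b_f <- rep(50, H)
  st2 <- lstm_step(c(1, -1), numeric(H), c_prev, sat)
  expect_equal(st2$c, c_prev, tolerance = 1e-10)
  # random instances against a straight-line transcription of the gates
  set.seed(12)
  for (rep in 1:20) {
    p <- list(W_f = matrix(rnorm(H * (H + D)), H), W_i = matrix(rnorm(H * (H + D)), H),
              W_o = matrix(rnorm(H * (H + D)), H), W_c = matrix(rnorm(H * (H + D)), H),
              b_f = rnorm(H), b_i = rnorm(H), b_o = rnorm(H), b_c = rnorm(H))
    x <- rnorm(D); h0 <- rnorm(H); c0 <- rnorm(H)
    z <- c(h0, x)
    f <- 1 / (1 + exp(-(p$W_f %*% z + p$b_f)))
    i <- 1 / (1 + exp(-(p$W_i %*% z + p$b_i)))
    o <- 1 / (1 + exp(-(p$W_o %*% z + p$b_o)))
    ct <- drop(f) * c0 + drop(i) * tanh(drop(p$W_c %*% z) + p$b_c)
    ht <- drop(o) * tanh(ct)
    st3 <- lstm_step(x, h0, c0, p)
    expect_equal(st3$c, ct, tolerance = 1e-10)
    expect_equal(st3$h, ht, tolerance = 1e-10)
  }
})

test_that("softmax head: uniform, stability, normalization, equivariance", {
  expect_equal(softmax_head(rnorm(5), matrix(0, 2, 5), c(0, 0)), c(0.5, 0.5))
  p <- softmax_head(1, matrix(c(1000, 0), 2, 1), c(0, 0))
  expect_equal(p, c(1, 0))
  expect_false(any(is.nan(p)))
  set.seed(2)
  H <- matrix(rnorm(30), 10, 3)
  W <- matrix(rnorm(6), 2, 3)
  P <- softmax_head(H, W, c(0.3, -0.2))
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12)
  # permuting class order permutes outputs
  P2 <- softmax_head(H, W[2:1, ], c(-0.2, 0.3))
  expect_equal(P2, P[, 2:1])
})

test_that("build_model variants: head contract, ablation, determinism", {
  sp <- model_spec(512)
  m <- build_model(sp, seed = 4)
  set.seed(1)
  fw <- model_forward(m, matrix(rnorm(2 * 512), 2))
  expect_equal(rowSums(fw$probs), c(1, 1), tolerance = 1e-12)
  # BiLSTM final feature has length 2 x last hidden size = 128
  expect_equal(m$d_head, 128)
  # ablation without attention has no attention parameters
  m2 <- build_model(model_spec(512, variant = "CNN-BiLSTM"), seed = 4)
  expect_false(any(grepl("^att_", names(m2$params))))
  expect_true(any(grepl("^att_", names(m$params))))
  # same spec + seed reproduce parameters exactly
  m3 <- build_model(sp, seed = 4)
  expect_identical(m$params, m3$params)
  expect_error(model_spec(512, variant = "resnet"), "arg")
})

test_that("bidirectional symmetry: reversing the input swaps direction roles", {
  set.seed(6)
  H <- 4; D <- 3; n <- 5; B <- 2
  W <- matrix(rnorm(4 * H * (H + D), sd = 0.3), 4 * H)
  b <- rnorm(4 * H, sd = 0.1)
  S <- array(rnorm(B * n * D), c(B, n, D))
  Sr <- S[, n:1, , drop = FALSE]
  fw <- csbn:::lstm_dir_forward(S, W, b, reverse = FALSE)
  bw <- csbn:::lstm_dir_forward(S, W, b, reverse = TRUE)
  fw_r <- csbn:::lstm_dir_forward(Sr, W, b, reverse = FALSE)
  bw_r <- csbn:::lstm_dir_forward(Sr, W, b, reverse = TRUE)
  expect_equal(fw_r$h_final, bw$h_final, tolerance = 1e-12)
  expect_equal(bw_r$h_final, fw$h_final, tolerance = 1e-12)
  # degenerate length-1 sequence: both directions see identical input
  S1 <- S[, 1, , drop = FALSE]
  f1 <- csbn:::lstm_dir_forward(S1, W, b, reverse = FALSE)
  b1 <- csbn:::lstm_dir_forward(S1, W, b, reverse = TRUE)
  expect_identical(f1$h_final, b1$h_final)
})

test_that("attention weight rows sum to one on random batches", {
  set.seed(33)
  worst <- 0
  for (r in 1:100) {
    X <- array(rnorm(5 * 2 * 8), c(5, 2, 8))
    fa <- csbn:::attention_forward(X, matrix(rnorm(64), 8),
                                   matrix(rnorm(64), 8), matrix(rnorm(64), 8))
    worst <- max(worst, abs(apply(fa$weights, c(1, 2), sum) - 1))
  }
  expect_lt(worst, 1e-6)
})
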