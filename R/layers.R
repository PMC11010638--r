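# Differentiable layer primitives. Batches are 3-D arrays laid out
# [batch, length, channels] — column-major R arrays then reshape to
# (batch*length) x channels matrices with no permutation, which keeps the
# interpreter overhead of the hand-rolled training loop low. Sequence
# layers read the same layout as [batch, time, dim]. Every forward returns
# the cache its backward needs; backwards are verified against finite
# differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- 1-D convolution -------------------------------------------------

# X: [B, L, C_in]; W: array [C_in, kernel, C_out]; b: numeric C_out.
conv1d_forward <- function(X, W, b, stride, padding = 0) {
  d <- dim(X); B <- d[1]; L <- d[2]; C_in <- d[3]
  k <- dim(W)[2]; C_out <- dim(W)[3]
  if (padding > 0) {
    Xp <- array(0, c(B, L + 2 * padding, C_in))
    Xp[, (padding + 1):(padding + L), ] <- X
  } else Xp <- X
  Lp <- dim(Xp)[2]
  L_out <- floor((Lp - k) / stride) + 1
  if (L_out < 1) stop("conv output length < 1")
  acc <- matrix(0, B * L_out, C_out)
  mats <- vector("list", k)
  for (j in seq_len(k)) {
    pos <- seq(j, by = stride, length.out = L_out)
    Mj <- matrix(Xp[, pos, , drop = FALSE], B * L_out, C_in)
    mats[[j]] <- Mj
    acc <- acc + Mj %*% matrix(W[, j, ], C_in, C_out)
  }
  acc <- acc + matrix(b, B * L_out, C_out, byrow = TRUE)
  list(out = array(acc, c(B, L_out, C_out)),
       cache = list(mats = mats, dimX = d, stride = stride, padding = padding,
                    k = k, L_out = L_out, W = W))
}

conv1d_backward <- function(dOut, cache) {
  W <- cache$W
  d <- cache$dimX; B <- d[1]; L <- d[2]; C_in <- d[3]
  k <- cache$k; L_out <- cache$L_out
  stride <- cache$stride; padding <- cache$padding
  C_out <- dim(W)[3]
  dM <- matrix(dOut, B * L_out, C_out)
  db <- colSums(dM)
  dW <- array(0, dim(W))
  dXp <- array(0, c(B, L + 2 * padding, C_in))
  for (j in seq_len(k)) {
    pos <- seq(j, by = stride, length.out = L_out)
    dW[, j, ] <- crossprod(cache$mats[[j]], dM)
    dXj <- array(tcrossprod(dM, matrix(W[, j, ], C_in, C_out)),
                 c(B, L_out, C_in))
    dXp[, pos, ] <- dXp[, pos, , drop = FALSE] + dXj
  }
  dX <- if (padding > 0) dXp[, (padding + 1):(padding + L), , drop = FALSE]
        else dXp
  list(dX = dX, dW = dW, db = db)
}

relu_forward <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_backward <- function(dOut, cache) dOut * cache

## ---- pooling (size 2, stride 1 or 2) ---------------------------------

pool2_forward <- function(X, kind, stride) {
  d <- dim(X); L <- d[2]
  L_out <- floor((L - 2) / stride) + 1
  p1 <- seq(1, by = stride, length.out = L_out)
  A <- X[, p1, , drop = FALSE]
  Bm <- X[, p1 + 1, , drop = FALSE]
  if (kind == "avg") {
    list(out = (A + Bm) / 2,
         cache = list(kind = kind, p1 = p1, dimX = d, stride = stride))
  } else {
    mask <- A >= Bm            # ties go to the first element
    list(out = ifelse(mask, A, Bm),
         cache = list(kind = kind, p1 = p1, dimX = d, stride = stride,
                      mask = mask))
  }
}

pool2_backward <- function(dOut, cache) {
  dX <- array(0, cache$dimX)
  p1 <- cache$p1
  if (cache$kind == "avg") {
    dX[, p1, ] <- dX[, p1, , drop = FALSE] + dOut / 2
    dX[, p1 + 1, ] <- dX[, p1 + 1, , drop = FALSE] + dOut / 2
  } else {
    dX[, p1, ] <- dX[, p1, , drop = FALSE] + dOut * cache$mask
    dX[, p1 + 1, ] <- dX[, p1 + 1, , drop = FALSE] + dOut * (!cache$mask)
  }
  dX
}

## ---- batch normalization (per channel over batch x length) -----------

bn_forward <- function(X, gamma, beta, state, training, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  Xm <- matrix(X, B * L, C)
  if (training) {
    mu <- colMeans(Xm)
    va <- colMeans(sweep(Xm, 2, mu)^2)               # biased, standard for BN
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  inv <- 1 / sqrt(va + eps)
  m <- B * L
  xhat <- (Xm - matrix(mu, m, C, byrow = TRUE)) *
    matrix(inv, m, C, byrow = TRUE)
  Ym <- xhat * matrix(gamma, m, C, byrow = TRUE) +
    matrix(beta, m, C, byrow = TRUE)
  list(out = array(Ym, d), state = state,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, dims = d,
                    training = training))
}

bn_backward <- function(dOut, cache) {
  d <- cache$dims; B <- d[1]; L <- d[2]; C <- d[3]
  m <- B * L
  dYm <- matrix(dOut, m, C)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * matrix(cache$gamma, m, C, byrow = TRUE)
  if (cache$training) {
    t1 <- dxhat - matrix(colMeans(dxhat), m, C, byrow = TRUE)
    t2 <- cache$xhat * matrix(colMeans(dxhat * cache$xhat), m, C, byrow = TRUE)
    dXm <- (t1 - t2) * matrix(cache$inv, m, C, byrow = TRUE)
  } else {
    dXm <- dxhat * matrix(cache$inv, m, C, byrow = TRUE)
  }
  list(dX = array(dXm, d), dgamma = dgamma, dbeta = dbeta)
}

## ---- spatial dropout (whole channels zeroed) -------------------------

spatial_dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = X, cache = NULL))
  }
  d <- dim(X)
  keep <- matrix(stats::rbinom(d[1] * d[3], 1, 1 - rate), d[1], d[3]) /
    (1 - rate)
  mask <- aperm(array(keep, c(d[1], d[3], d[2])), c(1, 3, 2))
  list(out = X * mask, cache = mask)
}

spatial_dropout_backward <- function(dOut, cache) {
  if (is.null(cache)) dOut else dOut * cache
}

## ---- scaled dot-product self-attention -------------------------------

# X: [B, n, d_model]; Wq/Wk: d_model x d_k; Wv: d_model x d_v.
attention_forward <- function(X, Wq, Wk, Wv) {
  d <- dim(X); B <- d[1]; n <- d[2]; dm <- d[3]
  dk <- ncol(Wq); dv <- ncol(Wv)
  Xm <- matrix(X, B * n, dm)
  Q <- array(Xm %*% Wq, c(B, n, dk))
  K <- array(Xm %*% Wk, c(B, n, dk))
  V <- array(Xm %*% Wv, c(B, n, dv))
  S <- array(0, c(B, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    S[, i, j] <- rowSums(matrix(Q[, i, ], B, dk) * matrix(K[, j, ], B, dk)) /
      sqrt(dk)
  }
  A <- array(0, c(B, n, n))
  for (i in seq_len(n)) {
    Si <- matrix(S[, i, ], B, n)
    Si <- Si - apply(Si, 1, max)
    E <- exp(Si)
    A[, i, ] <- E / rowSums(E)
  }
  out <- array(0, c(B, n, dv))
  for (i in seq_len(n)) {
    acc <- matrix(0, B, dv)
    for (j in seq_len(n)) acc <- acc + A[, i, j] * matrix(V[, j, ], B, dv)
    out[, i, ] <- acc
  }
  list(out = out, weights = A,
       cache = list(X = X, Q = Q, K = K, V = V, A = A,
                    Wq = Wq, Wk = Wk, Wv = Wv, dims = d))
}

attention_backward <- function(dOut, cache) {
  d <- cache$dims; B <- d[1]; n <- d[2]; dm <- d[3]
  Wq <- cache$Wq; Wk <- cache$Wk; Wv <- cache$Wv
  dk <- ncol(Wq); dv <- ncol(Wv)
  A <- cache$A; Q <- cache$Q; K <- cache$K; V <- cache$V
  dA <- array(0, c(B, n, n))
  dV <- array(0, c(B, n, dv))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dA[, i, j] <- rowSums(matrix(dOut[, i, ], B, dv) * matrix(V[, j, ], B, dv))
    dV[, j, ] <- matrix(dV[, j, ], B, dv) + A[, i, j] * matrix(dOut[, i, ], B, dv)
  }
  dS <- array(0, c(B, n, n))
  for (i in seq_len(n)) {
    Ai <- matrix(A[, i, ], B, n)
    dAi <- matrix(dA[, i, ], B, n)
    dS[, i, ] <- Ai * (dAi - rowSums(Ai * dAi))
  }
  dQ <- array(0, c(B, n, dk))
  dK <- array(0, c(B, n, dk))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dQ[, i, ] <- matrix(dQ[, i, ], B, dk) +
      dS[, i, j] * matrix(K[, j, ], B, dk) / sqrt(dk)
    dK[, j, ] <- matrix(dK[, j, ], B, dk) +
      dS[, i, j] * matrix(Q[, i, ], B, dk) / sqrt(dk)
  }
  Xm <- matrix(cache$X, B * n, dm)
  dQm <- matrix(dQ, B * n, dk)
  dKm <- matrix(dK, B * n, dk)
  dVm <- matrix(dV, B * n, dv)
  dX <- array(tcrossprod(dQm, Wq) + tcrossprod(dKm, Wk) + tcrossprod(dVm, Wv),
              c(B, n, dm))
  list(dX = dX,
       dWq = crossprod(Xm, dQm), dWk = crossprod(Xm, dKm),
       dWv = crossprod(Xm, dVm))
}

#' Scaled dot-product self-attention over one sequence
#'
#' Computes `A = softmax(Q K' / sqrt(d_k)) V` with `Q = X Wq`, `K = X Wk`,
#' `V = X Wv`, returning both the attended output and the attention-weight
#' matrix for inspection.
#'
#' @param X Sequence matrix, n x d_model.
#' @param Wq,Wk Projections d_model x d_k.
#' @param Wv Projection d_model x d_v.
#' @return List with `output` (n x d_v) and `weights` (n x n, rows sum
#'   to 1).
#' @export
self_attention <- function(X, Wq, Wk, Wv) {
  X <- as.matrix(X)
  fa <- attention_forward(array(X, c(1, nrow(X), ncol(X))), Wq, Wk, Wv)
  list(output = matrix(fa$out[1, , ], nrow(X), ncol(Wv)),
       weights = matrix(fa$weights[1, , ], nrow(X), nrow(X)))
}

#' Multiplicative residual combination
#'
#' Elementwise product `h(x) * F(x)` of a shape-adjusted skip path `h`
#' (a 1x1 convolution in the network) and the two-convolution main path
#' `F`; both arguments must already share one shape.
#'
#' @param h_out Skip-path output.
#' @param f_out Main-path output.
#' @return Elementwise product, same shape.
#' @export
multiplicative_residual <- function(h_out, f_out) {
  if (!identical(dim(h_out), dim(f_out)) || length(h_out) != length(f_out)) {
    stop("skip and main path shapes must match after the 1x1 adjustment")
  }
  h_out * f_out
}

## ---- LSTM ------------------------------------------------------------

#' Single LSTM cell step
#'
#' One time step of the standard LSTM cell: forget/input/output gates are
#' logistic sigmoids of `W . [h_prev, x] + b`, the candidate is a tanh, the
#' cell state is `f * c_prev + i * g` and the output is `o * tanh(c)`.
#'
#' @param x Input vector at this step.
#' @param h_prev,c_prev Previous hidden and cell state vectors (length H).
#' @param params List with gate weights `W_f`, `W_i`, `W_o`, `W_c` (each
#'   H x (H + length(x)), acting on `c(h_prev, x)`) and biases `b_f`,
#'   `b_i`, `b_o`, `b_c`.
#' @return List with `h` and `c`, each length H.
#' @export
lstm_step <- function(x, h_prev, c_prev, params) {
  z <- c(h_prev, x)
  f <- sigmoid(drop(params$W_f %*% z) + params$b_f)
  i <- sigmoid(drop(params$W_i %*% z) + params$b_i)
  o <- sigmoid(drop(params$W_o %*% z) + params$b_o)
  g <- tanh(drop(params$W_c %*% z) + params$b_c)
  cc <- f * c_prev + i * g
  list(h = o * tanh(cc), c = cc)
}

# Batched one-direction LSTM over a [B, n, D] sequence with stacked gate
# weights W [4H x (H+D)] (row blocks f, i, o, g) and bias b [4H].
lstm_dir_forward <- function(X, W, b, reverse = FALSE) {
  d <- dim(X); B <- d[1]; n <- d[2]; D <- d[3]
  H <- nrow(W) / 4
  ts <- if (reverse) rev(seq_len(n)) else seq_len(n)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hs <- array(0, c(B, n, H))
  steps <- vector("list", n)
  bmat <- matrix(b, B, 4 * H, byrow = TRUE)
  for (si in seq_len(n)) {
    t <- ts[si]
    xt <- matrix(X[, t, ], B, D)
    Z <- cbind(h, xt)
    G <- tcrossprod(Z, W) + bmat
    f <- sigmoid(G[, 1:H, drop = FALSE])
    i <- sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(G[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(G[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    Hs[, t, ] <- h
    steps[[si]] <- list(Z = Z, f = f, i = i, o = o, g = g,
                        c_prev = c_prev, c = cc, tc = tc)
  }
  list(H_seq = Hs, h_final = h,
       cache = list(steps = steps, ts = ts, W = W, dims = d, H = H))
}

# dH_seq: [B, n, H] per-step gradients; dh_final: extra gradient on the
# final hidden state (or NULL).
lstm_dir_backward <- function(dH_seq, dh_final, cache) {
  d <- cache$dims; B <- d[1]; n <- d[2]; D <- d[3]
  H <- cache$H; W <- cache$W; ts <- cache$ts
  dW <- matrix(0, 4 * H, H + D)
  db <- numeric(4 * H)
  dX <- array(0, c(B, n, D))
  dh_carry <- matrix(0, B, H)
  dc_carry <- matrix(0, B, H)
  if (!is.null(dh_final)) dh_carry <- dh_carry + dh_final
  for (si in rev(seq_len(n))) {
    t <- ts[si]
    st <- cache$steps[[si]]
    dh <- matrix(dH_seq[, t, ], B, H) + dh_carry
    do <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_carry
    df <- dc * st$c_prev
    di <- dc * st$g
    dg <- dc * st$i
    dG <- cbind(df * st$f * (1 - st$f),
                di * st$i * (1 - st$i),
                do * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dW <- dW + crossprod(dG, st$Z)
    db <- db + colSums(dG)
    dZ <- dG %*% W
    dh_carry <- dZ[, 1:H, drop = FALSE]
    dX[, t, ] <- dZ[, (H + 1):(H + D), drop = FALSE]
    dc_carry <- dc * st$f
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- softmax head ----------------------------------------------------

#' Softmax classification head
#'
#' Numerically stable softmax of `W h + b`.
#'
#' @param H Feature vector (length D) or matrix of row vectors (B x D).
#' @param W Weight matrix, n_classes x D.
#' @param b Bias, length n_classes.
#' @return Probability vector (or B x n_classes matrix); rows sum to 1.
#' @export
softmax_head <- function(H, W, b) {
  one <- is.null(dim(H))
  Hm <- if (one) matrix(H, 1) else as.matrix(H)
  logits <- tcrossprod(Hm, W) + matrix(b, nrow(Hm), length(b), byrow = TRUE)
  logits <- logits - apply(logits, 1, max)
  E <- exp(logits)
  P <- E / rowSums(E)
  if (one) drop(P) else P
}
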