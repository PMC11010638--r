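# CSBN network assembly: executable plan from a model_spec, seeded Glorot
# initialization, full forward pass (train/eval modes) and hand-derived
# backward pass returning gradients named like the parameters.

# Walk the stage list into an executable plan; consecutive convs form a
# multiplicative-residual pair (skip path = 1x1 conv at the pair's
# cumulative stride, truncated to the main path's length).
build_plan <- function(spec) {
  plan <- list()
  C <- 1L; L <- spec$input_len
  stages <- spec$stages
  i <- 1L
  nid <- 0L
  while (i <= length(stages)) {
    st <- stages[[i]]
    nid <- nid + 1L
    if (st$type == "conv" && i < length(stages) &&
        stages[[i + 1L]]$type == "conv" && spec$residual_pairs) {
      st2 <- stages[[i + 1L]]
      La <- conv_out_len(L, st$kernel, st$stride, st$padding)
      Lb <- conv_out_len(La, st2$kernel, st2$stride, st2$padding)
      s_total <- st$stride * st2$stride
      Lh <- conv_out_len(L, 1, s_total)
      if (Lh < Lb) stop("skip path shorter than main path")
      plan[[length(plan) + 1L]] <- list(
        kind = "respair", id = sprintf("n%02d", nid),
        C_in = C, L_in = L,
        a = st, b = st2, f = st2$filters, La = La, Lb = Lb,
        h_stride = s_total, Lh = Lh)
      C <- st2$filters; L <- Lb
      i <- i + 2L
    } else if (st$type == "conv") {
      Lo <- conv_out_len(L, st$kernel, st$stride, st$padding)
      plan[[length(plan) + 1L]] <- list(kind = "conv", id = sprintf("n%02d", nid),
                                        C_in = C, L_in = L, st = st, Lo = Lo)
      C <- st$filters; L <- Lo
      i <- i + 1L
    } else if (st$type == "pool") {
      Lo <- conv_out_len(L, st$size, st$stride)
      plan[[length(plan) + 1L]] <- list(kind = "pool", id = sprintf("n%02d", nid),
                                        st = st, Lo = Lo)
      L <- Lo
      i <- i + 1L
    } else if (st$type == "bn") {
      plan[[length(plan) + 1L]] <- list(kind = "bn", id = sprintf("n%02d", nid),
                                        C = C)
      i <- i + 1L
    } else {                                   # drop
      plan[[length(plan) + 1L]] <- list(kind = "drop", id = sprintf("n%02d", nid),
                                        rate = st$rate)
      i <- i + 1L
    }
  }
  attr(plan, "out_channels") <- C
  attr(plan, "out_len") <- L
  plan
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Build a trainable CSBN model
#'
#' Instantiates the parameters of a [model_spec()] with seeded Glorot
#' uniform initialization. Depending on the variant the model comprises the
#' convolutional stack with multiplicative residual pairs, the
#' self-attention stage, the three-layer bidirectional LSTM and the softmax
#' head.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the initializer.
#' @return A `csbn_model`: list with `spec`, `plan`, `params` (named list
#'   of arrays), and `bn` (running batch-norm statistics).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list()
  bn <- list()
  use_cnn <- spec$variant %in% c("CSBN", "CNN", "CNN-BiLSTM")
  plan <- if (use_cnn) build_plan(spec) else list()
  if (use_cnn) {
    for (nd in plan) {
      if (nd$kind == "respair") {
        f <- nd$f
        params[[paste0(nd$id, "_convA_W")]] <-
          glorot(nd$C_in * nd$a$kernel, f * nd$a$kernel, c(nd$C_in, nd$a$kernel, f))
        params[[paste0(nd$id, "_convA_b")]] <- numeric(f)
        params[[paste0(nd$id, "_convB_W")]] <-
          glorot(f * nd$b$kernel, f * nd$b$kernel, c(f, nd$b$kernel, f))
        params[[paste0(nd$id, "_convB_b")]] <- numeric(f)
        params[[paste0(nd$id, "_h_W")]] <- glorot(nd$C_in, f, c(nd$C_in, 1, f))
        params[[paste0(nd$id, "_h_b")]] <- numeric(f)
      } else if (nd$kind == "conv") {
        f <- nd$st$filters
        params[[paste0(nd$id, "_conv_W")]] <-
          glorot(nd$C_in * nd$st$kernel, f * nd$st$kernel,
                 c(nd$C_in, nd$st$kernel, f))
        params[[paste0(nd$id, "_conv_b")]] <- numeric(f)
      } else if (nd$kind == "bn") {
        params[[paste0(nd$id, "_gamma")]] <- rep(1, nd$C)
        params[[paste0(nd$id, "_beta")]] <- numeric(nd$C)
        bn[[nd$id]] <- list(mean = numeric(nd$C), var = rep(1, nd$C))
      }
    }
  }
  d_model <- if (use_cnn) attr(plan, "out_channels") else NULL
  if (spec$variant == "CSBN") {
    params$att_Wq <- glorot(d_model, spec$d_k, c(d_model, spec$d_k))
    params$att_Wk <- glorot(d_model, spec$d_k, c(d_model, spec$d_k))
    params$att_Wv <- glorot(d_model, spec$d_v, c(d_model, spec$d_v))
  }
  if (spec$variant %in% c("CSBN", "CNN-BiLSTM", "BiLSTM")) {
    D <- switch(spec$variant,
                CSBN = spec$d_v,
                `CNN-BiLSTM` = d_model,
                BiLSTM = spec$bilstm_only_step_dim)
    for (l in seq_along(spec$bilstm_sizes)) {
      H <- spec$bilstm_sizes[l]
      for (dir in c("fw", "bw")) {
        params[[sprintf("bl%d_%s_W", l, dir)]] <-
          glorot(H + D, H, c(4 * H, H + D))
        params[[sprintf("bl%d_%s_b", l, dir)]] <- numeric(4 * H)
      }
      D <- 2 * H
    }
    d_head <- 2 * spec$bilstm_sizes[length(spec$bilstm_sizes)]
  } else {
    d_head <- d_model * attr(plan, "out_len")
  }
  params$head_W <- glorot(d_head, spec$n_classes, c(spec$n_classes, d_head))
  params$head_b <- numeric(spec$n_classes)
  structure(list(spec = spec, plan = plan, params = params, bn = bn,
                 d_head = d_head), class = "csbn_model")
}

#' @export
print.csbn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<csbn_model> variant=%s input_len=%d params=%d tensors (%d values)\n",
              x$spec$variant, x$spec$input_len, length(x$params), np))
  invisible(x)
}

# Forward through the conv plan. X: [B, 1, L]. Returns map, caches, bn.
cnn_forward <- function(model, X, training) {
  p <- model$params
  caches <- list()
  bn <- model$bn
  cur <- X
  for (nd in model$plan) {
    if (nd$kind == "respair") {
      fa <- conv1d_forward(cur, p[[paste0(nd$id, "_convA_W")]],
                           p[[paste0(nd$id, "_convA_b")]],
                           nd$a$stride, nd$a$padding)
      ra <- relu_forward(fa$out)
      fb <- conv1d_forward(ra$out, p[[paste0(nd$id, "_convB_W")]],
                           p[[paste0(nd$id, "_convB_b")]],
                           nd$b$stride, nd$b$padding)
      rb <- relu_forward(fb$out)
      fh <- conv1d_forward(cur, p[[paste0(nd$id, "_h_W")]],
                           p[[paste0(nd$id, "_h_b")]], nd$h_stride, 0)
      hcrop <- fh$out[, seq_len(nd$Lb), , drop = FALSE]
      out <- multiplicative_residual(hcrop, rb$out)
      caches[[nd$id]] <- list(fa = fa$cache, ra = ra$cache, fb = fb$cache,
                              rb = rb$cache, fh = fh$cache, hcrop = hcrop,
                              f_out = rb$out, Lh = nd$Lh, Lb = nd$Lb)
      cur <- out
    } else if (nd$kind == "conv") {
      fc <- conv1d_forward(cur, p[[paste0(nd$id, "_conv_W")]],
                           p[[paste0(nd$id, "_conv_b")]],
                           nd$st$stride, nd$st$padding)
      rc <- relu_forward(fc$out)
      caches[[nd$id]] <- list(fc = fc$cache, rc = rc$cache)
      cur <- rc$out
    } else if (nd$kind == "pool") {
      fp <- pool2_forward(cur, nd$st$kind, nd$st$stride)
      caches[[nd$id]] <- fp$cache
      cur <- fp$out
    } else if (nd$kind == "bn") {
      fb <- bn_forward(cur, p[[paste0(nd$id, "_gamma")]],
                       p[[paste0(nd$id, "_beta")]], bn[[nd$id]], training)
      bn[[nd$id]] <- fb$state
      caches[[nd$id]] <- fb$cache
      cur <- fb$out
    } else {
      fd <- spatial_dropout_forward(cur, nd$rate, training)
      caches[[nd$id]] <- fd$cache
      cur <- fd$out
    }
  }
  list(map = cur, caches = caches, bn = bn)
}

cnn_backward <- function(model, dMap, caches) {
  p <- model$params
  grads <- list()
  dcur <- dMap
  for (nd in rev(model$plan)) {
    ca <- caches[[nd$id]]
    if (nd$kind == "respair") {
      dF <- dcur * ca$hcrop
      dHc <- dcur * ca$f_out
      dHfull <- array(0, c(dim(dHc)[1], ca$Lh, dim(dHc)[3]))
      dHfull[, seq_len(ca$Lb), ] <- dHc
      bh <- conv1d_backward(dHfull, ca$fh)
      grads[[paste0(nd$id, "_h_W")]] <- bh$dW
      grads[[paste0(nd$id, "_h_b")]] <- bh$db
      dfb <- relu_backward(dF, ca$rb)
      bb <- conv1d_backward(dfb, ca$fb)
      grads[[paste0(nd$id, "_convB_W")]] <- bb$dW
      grads[[paste0(nd$id, "_convB_b")]] <- bb$db
      dfa <- relu_backward(bb$dX, ca$ra)
      ba <- conv1d_backward(dfa, ca$fa)
      grads[[paste0(nd$id, "_convA_W")]] <- ba$dW
      grads[[paste0(nd$id, "_convA_b")]] <- ba$db
      dcur <- ba$dX + bh$dX
    } else if (nd$kind == "conv") {
      dfc <- relu_backward(dcur, ca$rc)
      bc <- conv1d_backward(dfc, ca$fc)
      grads[[paste0(nd$id, "_conv_W")]] <- bc$dW
      grads[[paste0(nd$id, "_conv_b")]] <- bc$db
      dcur <- bc$dX
    } else if (nd$kind == "pool") {
      dcur <- pool2_backward(dcur, ca)
    } else if (nd$kind == "bn") {
      bb <- bn_backward(dcur, ca)
      grads[[paste0(nd$id, "_gamma")]] <- bb$dgamma
      grads[[paste0(nd$id, "_beta")]] <- bb$dbeta
      dcur <- bb$dX
    } else {
      dcur <- spatial_dropout_backward(dcur, ca)
    }
  }
  list(dX = dcur, grads = grads)
}

bilstm_forward <- function(model, S) {
  p <- model$params
  caches <- list()
  for (l in seq_along(model$spec$bilstm_sizes)) {
    fw <- lstm_dir_forward(S, p[[sprintf("bl%d_fw_W", l)]],
                           p[[sprintf("bl%d_fw_b", l)]], reverse = FALSE)
    bw <- lstm_dir_forward(S, p[[sprintf("bl%d_bw_W", l)]],
                           p[[sprintf("bl%d_bw_b", l)]], reverse = TRUE)
    d <- dim(fw$H_seq)
    S <- array(0, c(d[1], d[2], 2 * d[3]))
    S[, , 1:d[3]] <- fw$H_seq
    S[, , (d[3] + 1):(2 * d[3])] <- bw$H_seq
    caches[[l]] <- list(fw = fw$cache, bw = bw$cache, H = d[3])
    if (l == length(model$spec$bilstm_sizes)) {
      feat <- cbind(fw$h_final, bw$h_final)
    }
  }
  list(feat = feat, caches = caches)
}

bilstm_backward <- function(model, dFeat, caches) {
  grads <- list()
  n_layers <- length(model$spec$bilstm_sizes)
  dS_above <- NULL
  for (l in rev(seq_len(n_layers))) {
    ca <- caches[[l]]
    H <- ca$H
    dims <- ca$fw$dims                     # [B, n, D] of this layer's input
    if (l == n_layers) {
      zero <- array(0, c(dims[1], dims[2], H))
      bfw <- lstm_dir_backward(zero, dFeat[, 1:H, drop = FALSE], ca$fw)
      bbw <- lstm_dir_backward(zero, dFeat[, (H + 1):(2 * H), drop = FALSE],
                               ca$bw)
    } else {
      bfw <- lstm_dir_backward(dS_above[, , 1:H, drop = FALSE], NULL, ca$fw)
      bbw <- lstm_dir_backward(dS_above[, , (H + 1):(2 * H), drop = FALSE],
                               NULL, ca$bw)
    }
    grads[[sprintf("bl%d_fw_W", l)]] <- bfw$dW
    grads[[sprintf("bl%d_fw_b", l)]] <- bfw$db
    grads[[sprintf("bl%d_bw_W", l)]] <- bbw$dW
    grads[[sprintf("bl%d_bw_b", l)]] <- bbw$db
    dS_above <- bfw$dX + bbw$dX
  }
  list(dS = dS_above, grads = grads)
}

#' Forward pass of a CSBN model
#'
#' @param model A [build_model()] result.
#' @param X Feature matrix, B x input_len (a `de_matrix` works).
#' @param training Logical: batch-norm in batch mode and dropout active.
#' @return List with `probs` (B x n_classes), `cache` (for the backward
#'   pass) and `bn` (updated running statistics when training).
#' @export
model_forward <- function(model, X, training = FALSE) {
  X <- unclass(as.matrix(X))
  spec <- model$spec
  B <- nrow(X)
  stopifnot(ncol(X) == spec$input_len)
  cache <- list()
  bn <- model$bn
  if (spec$variant %in% c("CSBN", "CNN", "CNN-BiLSTM")) {
    Xin <- array(X, c(B, spec$input_len, 1))
    cf <- cnn_forward(model, Xin, training)
    bn <- cf$bn
    cache$cnn <- cf$caches
    map <- cf$map                          # [B, L, C]
    if (spec$variant == "CNN") {
      feat <- matrix(map, B, dim(map)[2] * dim(map)[3])
      cache$map_dim <- dim(map)
    } else {
      S <- map                             # [B, n, d_model] directly
      cache$map_dim <- dim(map)
      if (spec$variant == "CSBN") {
        fa <- attention_forward(S, model$params$att_Wq, model$params$att_Wk,
                                model$params$att_Wv)
        cache$att <- fa$cache
        S <- fa$out
      }
      fb <- bilstm_forward(model, S)
      cache$bilstm <- fb$caches
      feat <- fb$feat
    }
  } else {                                 # BiLSTM-only ablation
    d <- spec$bilstm_only_step_dim
    n <- spec$input_len / d
    S <- aperm(array(X, c(B, d, n)), c(1, 3, 2))
    cache$seq_dim <- c(B, n, d)
    fb <- bilstm_forward(model, S)
    cache$bilstm <- fb$caches
    feat <- fb$feat
  }
  cache$feat <- feat
  probs <- softmax_head(feat, model$params$head_W, model$params$head_b)
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  list(probs = probs, cache = cache, bn = bn)
}

# Backward from dLogits (B x n_classes; typically (P - Y)/B for CE loss).
model_backward <- function(model, dLogits, cache) {
  spec <- model$spec
  grads <- list()
  feat <- cache$feat
  grads$head_W <- crossprod(dLogits, feat)
  grads$head_b <- colSums(dLogits)
  dFeat <- dLogits %*% model$params$head_W
  if (spec$variant == "BiLSTM") {
    bb <- bilstm_backward(model, dFeat, cache$bilstm)
    grads <- c(grads, bb$grads)
    return(grads)
  }
  if (spec$variant == "CNN") {
    md <- cache$map_dim
    dMap <- array(dFeat, md)
    cb <- cnn_backward(model, dMap, cache$cnn)
    grads <- c(grads, cb$grads)
    return(grads)
  }
  bb <- bilstm_backward(model, dFeat, cache$bilstm)
  grads <- c(grads, bb$grads)
  dS <- bb$dS
  if (spec$variant == "CSBN") {
    ab <- attention_backward(dS, cache$att)
    grads$att_Wq <- ab$dWq
    grads$att_Wk <- ab$dWk
    grads$att_Wv <- ab$dWv
    dS <- ab$dX
  }
  cb <- cnn_backward(model, dS, cache$cnn)
  grads <- c(grads, cb$grads)
  grads
}
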