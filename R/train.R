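# Mini-batch Adam training on the cross-entropy loss, fully seeded.

#' Training configuration
#'
#' @param task `"valence"` or `"arousal"`; named explicitly in every result
#'   record.
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2 Adam moment decays (defaults 0.9, 0.999).
#' @param eps Adam epsilon (default 1e-8).
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(task = c("valence", "arousal"), epochs = 100,
                         batch_size = 64, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, seed = 1L) {
  task <- match.arg(task)
  if (epochs < 1) stop("epochs must be >= 1")
  stopifnot(batch_size >= 1, lr > 0)
  structure(list(task = task, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a CSBN model
#'
#' Adam on the categorical cross-entropy, mini-batches reshuffled each
#' epoch. Deterministic for a given config seed (single-threaded BLAS
#' assumed).
#'
#' @param spec A [model_spec()].
#' @param X Feature matrix, N x input_len (a `de_matrix` works).
#' @param y Integer 0/1 labels, length N; both classes must be present.
#' @param cfg A [train_config()].
#' @return A `csbn_fit`: list with `model`, `history` (per-epoch loss and
#'   training accuracy) and `cfg`.
#' @export
train_model <- function(spec, X, y, cfg) {
  X <- unclass(as.matrix(X))
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  if (!inherits(cfg, "train_config")) stop("cfg must be a train_config")
  N <- nrow(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  model <- build_model(spec, seed = cfg$seed)
  m_state <- lapply(model$params, function(p) array(0, dim(p) %||% length(p)))
  v_state <- lapply(model$params, function(p) array(0, dim(p) %||% length(p)))
  t_step <- 0L
  hist_loss <- numeric(cfg$epochs)
  hist_acc <- numeric(cfg$epochs)
  Y_full <- cbind(1 - y, y)                    # class order: 0 then 1
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(N)
    ep_loss <- 0
    ep_correct <- 0L
    for (start in seq(1, N, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, N)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y_full[idx, , drop = FALSE]
      fw <- model_forward(model, Xb, training = TRUE)
      model$bn <- fw$bn
      P <- fw$probs
      ep_loss <- ep_loss - sum(log(pmax(P[cbind(seq_along(idx), y[idx] + 1L)],
                                        1e-12)))
      ep_correct <- ep_correct + sum(max.col(P, ties.method = "first") - 1L == y[idx])
      dLogits <- (P - Yb) / length(idx)
      grads <- model_backward(model, dLogits, fw$cache)
      t_step <- t_step + 1L
      corr1 <- 1 - cfg$beta1^t_step
      corr2 <- 1 - cfg$beta2^t_step
      for (nm in names(grads)) {
        g <- grads[[nm]]
        m_state[[nm]] <- cfg$beta1 * m_state[[nm]] + (1 - cfg$beta1) * g
        v_state[[nm]] <- cfg$beta2 * v_state[[nm]] + (1 - cfg$beta2) * g^2
        model$params[[nm]] <- model$params[[nm]] -
          cfg$lr * (m_state[[nm]] / corr1) /
            (sqrt(v_state[[nm]] / corr2) + cfg$eps)
      }
    }
    hist_loss[ep] <- ep_loss / N
    hist_acc[ep] <- ep_correct / N
  }
  structure(list(model = model,
                 history = data.frame(epoch = seq_len(cfg$epochs),
                                      loss = hist_loss, accuracy = hist_acc),
                 cfg = cfg),
            class = "csbn_fit")
}

#' Positive-class probabilities
#'
#' @param fit A `csbn_fit` (or bare `csbn_model`).
#' @param X Feature matrix.
#' @return Numeric vector, probability of class 1 per row.
#' @export
predict_proba <- function(fit, X) {
  model <- if (inherits(fit, "csbn_fit")) fit$model else fit
  model_forward(model, X, training = FALSE)$probs[, 2]
}
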