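# Declarative CSBN architecture. The canonical 512-input convolutional
# stack reproduces the recommended stage table exactly (kernel sizes are
# derived from the printed output lengths under no padding, except the
# final conv which uses padding 1); shorter feature vectors (fewer channels
# or a band subset) get a reduced stack built by the same pattern so the
# attention/BiLSTM stages always see a length-2 sequence of 64-dim features.

conv_stage <- function(name, filters, kernel, stride, padding = 0,
                       activation = "relu") {
  list(type = "conv", name = name, filters = filters, kernel = kernel,
       stride = stride, padding = padding, activation = activation)
}
pool_stage <- function(name, kind, size = 2, stride = 2) {
  list(type = "pool", name = name, kind = kind, size = size, stride = stride)
}
bn_stage <- function(name) list(type = "bn", name = name)
drop_stage <- function(name, rate) list(type = "drop", name = name, rate = rate)

# The canonical stack for a 512-length DE vector (128 channels x 4 bands).
canonical_stages <- function(dropout_rate) {
  list(
    conv_stage("Convolution-1", 32, 2, 2),
    conv_stage("Convolution-2", 32, 6, 2),
    pool_stage("Pool_1", "max"),
    bn_stage("BN_1"),
    drop_stage("Drop_1", dropout_rate),
    conv_stage("Convolution-3", 64, 5, 2),
    conv_stage("Convolution-4", 64, 6, 2),
    pool_stage("Pool_2", "avg"),
    bn_stage("BN_2"),
    drop_stage("Drop_2", dropout_rate),
    conv_stage("Convolution-5", 128, 3, 1),
    conv_stage("Convolution-6", 128, 2, 1),
    pool_stage("Pool_3", "avg", size = 2, stride = 1),
    bn_stage("BN_3"),
    drop_stage("Drop_3", dropout_rate),
    conv_stage("Convolution-7", 64, 3, 1, padding = 1),
    bn_stage("BN_4")
  )
}

conv_out_len <- function(L, kernel, stride, padding = 0) {
  floor((L + 2 * padding - kernel) / stride) + 1
}

# Reduced stack for input lengths where the canonical kernels do not fit:
# conv pairs + pool blocks with the canonical filter progression, stopping
# when the length budget is exhausted, then a 64-filter conv to length 2.
reduced_stages <- function(input_len, dropout_rate) {
  stages <- list()
  L <- input_len
  filters <- c(32, 64, 128)
  kinds <- c("max", "avg", "avg")
  ci <- 1L
  for (blk in 1:3) {
    if (L < 6) break
    f <- filters[blk]
    s1 <- if (L >= 16) 2 else 1
    stages[[length(stages) + 1L]] <- conv_stage(sprintf("Convolution-%d", ci), f, 2, s1)
    L <- conv_out_len(L, 2, s1); ci <- ci + 1L
    stages[[length(stages) + 1L]] <- conv_stage(sprintf("Convolution-%d", ci), f, 2, 1)
    L <- conv_out_len(L, 2, 1); ci <- ci + 1L
    ps <- if (L >= 4) 2 else 1
    stages[[length(stages) + 1L]] <- pool_stage(sprintf("Pool_%d", blk), kinds[blk],
                                                size = 2, stride = ps)
    L <- conv_out_len(L, 2, ps)
    stages[[length(stages) + 1L]] <- bn_stage(sprintf("BN_%d", blk))
    stages[[length(stages) + 1L]] <- drop_stage(sprintf("Drop_%d", blk), dropout_rate)
  }
  if (L == 2) {
    stages[[length(stages) + 1L]] <- conv_stage(sprintf("Convolution-%d", ci), 64, 3, 1,
                                                padding = 1)
  } else if (L >= 3) {
    stages[[length(stages) + 1L]] <- conv_stage(sprintf("Convolution-%d", ci), 64, L - 1, 1)
  } else {
    stop(sprintf("input length %d too short for the convolutional stack", input_len))
  }
  stages[[length(stages) + 1L]] <- bn_stage("BN_final")
  stages
}

#' CSBN model specification
#'
#' Builds the declarative layer stack for a DE feature vector of length
#' `input_len` (channels x bands). For `input_len = 512` the stack is the
#' canonical recommended architecture; other lengths get a reduced stack
#' built by the same conv-pair/pool pattern. Every variant ends in a
#' 2-class softmax head.
#'
#' @param input_len Feature vector length (default 512 = 128 channels x 4
#'   bands).
#' @param variant `"CSBN"` (full model), `"CNN"` (conv stack + softmax),
#'   `"BiLSTM"` (reshaped input + BiLSTM + softmax), or `"CNN-BiLSTM"`
#'   (full model without self-attention).
#' @param n_classes Output classes (default 2).
#' @param dropout_rate Spatial dropout probability (default 0.3).
#' @param bilstm_sizes Hidden sizes of the three bidirectional layers
#'   (default `c(128, 64, 64)`).
#' @param d_k,d_v Attention key/value dimensions (default 64, matching the
#'   64-channel CNN output).
#' @return A `model_spec` object.
#' @export
model_spec <- function(input_len = 512, variant = c("CSBN", "CNN", "BiLSTM",
                                                    "CNN-BiLSTM"),
                       n_classes = 2, dropout_rate = 0.3,
                       bilstm_sizes = c(128, 64, 64), d_k = 64, d_v = 64) {
  variant <- match.arg(variant)
  stopifnot(input_len >= 2, n_classes >= 2, dropout_rate >= 0, dropout_rate < 1)
  stages <- if (input_len == 512) canonical_stages(dropout_rate)
            else reduced_stages(input_len, dropout_rate)
  # BiLSTM-only ablation input layout: 64-dim steps when divisible, else the
  # widest step count <= 8 that divides the input length.
  bl_d <- if (input_len %% 64 == 0) 64 else {
    divs <- which(input_len %% seq_len(min(8, input_len)) == 0)
    input_len / max(divs)
  }
  spec <- structure(list(input_len = as.integer(input_len), variant = variant,
                         stages = stages, n_classes = as.integer(n_classes),
                         dropout_rate = dropout_rate,
                         bilstm_sizes = as.integer(bilstm_sizes),
                         d_k = as.integer(d_k), d_v = as.integer(d_v),
                         bilstm_only_step_dim = as.integer(bl_d),
                         residual_pairs = TRUE),
                    class = "model_spec")
  st <- shape_trace(spec)        # validates every stage length >= 1
  final <- st[nrow(st), ]
  if (variant %in% c("CSBN", "CNN-BiLSTM") && final$length < 2) {
    stop("conv stack output too short for a sequence stage")
  }
  spec
}

#' Symbolic forward-shape computation
#'
#' Runs the spec's stage list on the input length without any weights,
#' returning (channels, length) after every stage. Conv and pool lengths
#' follow `floor((L + 2*pad - kernel)/stride) + 1`.
#'
#' @param spec A [model_spec()].
#' @return Data frame with columns `stage`, `channels`, `length`.
#' @export
shape_trace <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  C <- 1L
  L <- spec$input_len
  rows <- list()
  for (st in spec$stages) {
    if (st$type == "conv") {
      L <- conv_out_len(L, st$kernel, st$stride, st$padding)
      C <- st$filters
    } else if (st$type == "pool") {
      L <- conv_out_len(L, st$size, st$stride)
    }
    if (L < 1) stop(sprintf("stage %s produces length %d < 1", st$name, L))
    rows[[length(rows) + 1L]] <- data.frame(stage = st$name, channels = C,
                                            length = L,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> variant=%s input_len=%d n_classes=%d\n",
              x$variant, x$input_len, x$n_classes))
  print(shape_trace(x))
  invisible(x)
}
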