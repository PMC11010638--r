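# 10-fold cross-validation and the ablation / single-band / band-combination
# experiment suites.

#' k-fold cross-validation indices
#'
#' Disjoint test folds covering all `n` samples. With `stratify = TRUE`
#' (and labels supplied) each class is shuffled and dealt round-robin, so
#' per-fold class counts differ from proportionality by at most one
#' sample.
#'
#' @param n Sample count.
#' @param k Fold count (default 10); `2 <= k <= n`.
#' @param labels Optional label vector (length n) for stratification.
#' @param stratify Stratify on `labels` (default TRUE when labels given).
#' @param groups Optional grouping vector (length n), e.g. trial ids: all
#'   samples of a group are assigned to the same fold. Segment-level
#'   (ungrouped) splitting matches the reported experimental setup but lets
#'   windows of one trial appear on both sides of a split; grouped
#'   splitting avoids that leakage at the cost of coarser folds.
#' @param seed Integer seed; identical seeds give identical folds.
#' @return List of k elements, each `list(train = ..., test = ...)` of
#'   1-based row indices.
#' @export
kfold_indices <- function(n, k = 10, labels = NULL,
                          stratify = !is.null(labels), groups = NULL,
                          seed = 1L) {
  if (k > n) stop("k must not exceed n")
  if (k < 2) stop("k must be at least 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_of <- integer(n)
  if (!is.null(groups)) {
    if (length(groups) != n) stop("groups must have length n")
    ug <- sample(unique(groups))
    if (k > length(ug)) stop("k exceeds the number of groups")
    gf <- rep_len(seq_len(k), length(ug))
    fold_of <- gf[match(groups, ug)]
  } else if (stratify) {
    if (is.null(labels) || length(labels) != n) {
      stop("stratification requires labels of length n")
    }
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold_of[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

de_labels <- function(features, task) {
  meta <- attr(features, "row_meta")
  if (is.null(meta)) stop("feature matrix carries no row metadata")
  as.integer(meta[[task]])
}

#' Cross-validated training and evaluation
#'
#' Trains one model per fold (re-initialized from a per-fold seed derived
#' from the config seed, so folds are independent yet reproducible) and
#' aggregates the per-fold metrics as mean and max.
#'
#' @param spec A [model_spec()].
#' @param features Feature matrix (N x input_len).
#' @param labels Integer 0/1 labels, length N.
#' @param cfg A [train_config()].
#' @param k Fold count (default 10).
#' @return A `cv_result`: `folds` (per-fold metric rows), `mean`, `max`
#'   (named metric vectors), `task`.
#' @export
cross_validate <- function(spec, features, labels, cfg, k = 10) {
  features <- unclass(as.matrix(features))
  labels <- as.integer(labels)
  folds <- kfold_indices(nrow(features), k, labels = labels,
                         stratify = TRUE, seed = cfg$seed)
  rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    cfg_f <- cfg
    cfg_f$seed <- substream_seed(cfg$seed, f, 0L, 7L)
    fit <- train_model(spec, features[folds[[f]]$train, , drop = FALSE],
                       labels[folds[[f]]$train], cfg_f)
    m <- evaluate_model(fit, features[folds[[f]]$test, , drop = FALSE],
                        labels[folds[[f]]$test])
    rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                            precision = m$precision, f1 = m$f1, auc = m$auc)
  }
  tab <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "precision", "f1", "auc")
  structure(list(folds = tab,
                 mean = colMeans(tab[metric_cols], na.rm = TRUE),
                 max = apply(tab[metric_cols], 2, max, na.rm = TRUE),
                 task = cfg$task, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> task=%s, %d folds\n", x$task, x$k))
  cat(sprintf("  mean: acc %.4f  pre %.4f  f1 %.4f  auc %.4f\n",
              x$mean["accuracy"], x$mean["precision"], x$mean["f1"],
              x$mean["auc"]))
  cat(sprintf("  max : acc %.4f  pre %.4f  f1 %.4f  auc %.4f\n",
              x$max["accuracy"], x$max["precision"], x$max["f1"],
              x$max["auc"]))
  invisible(x)
}

#' Ablation experiment suite
#'
#' Cross-validates the four architecture variants (conv stack only, BiLSTM
#' only, conv + BiLSTM, and the full model with self-attention) on the
#' valence and arousal tasks.
#'
#' @param features A `de_matrix` with row metadata.
#' @param cfg A [train_config()]; its `task` field is overridden per task.
#' @param variants Variant names (default all four).
#' @param tasks Tasks to run (default valence and arousal).
#' @param k Fold count (default 10).
#' @return Data frame: variant, task, mean metrics, max accuracy.
#' @export
run_ablation_suite <- function(features,
                               cfg,
                               variants = c("CNN", "BiLSTM", "CNN-BiLSTM",
                                            "CSBN"),
                               tasks = c("valence", "arousal"), k = 10) {
  rows <- list()
  for (task in tasks) {
    labels <- de_labels(features, task)
    for (v in variants) {
      spec <- model_spec(input_len = ncol(features), variant = v)
      cfg_t <- cfg
      cfg_t$task <- task
      cv <- cross_validate(spec, features, labels, cfg_t, k = k)
      rows[[length(rows) + 1L]] <-
        data.frame(variant = v, task = task,
                   accuracy = cv$mean["accuracy"],
                   precision = cv$mean["precision"],
                   f1 = cv$mean["f1"], auc = cv$mean["auc"],
                   max_accuracy = cv$max["accuracy"],
                   row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' All band subsets of sizes 1-3
#'
#' The 4 singletons, 6 pairs and 4 triples of the standard band set.
#'
#' @param band_names Band names (default the four standard bands).
#' @return List of character vectors.
#' @export
band_subsets <- function(band_names = names(default_bands())) {
  subs <- list()
  for (sz in 1:3) {
    cmb <- utils::combn(band_names, sz, simplify = FALSE)
    subs <- c(subs, cmb)
  }
  subs
}

#' Band-subset experiment suite
#'
#' For each subset: restrict the DE matrix to those bands, rebuild the
#' model spec for the reduced input length, and cross-validate.
#'
#' @param features A `de_matrix` with row metadata.
#' @param cfg A [train_config()].
#' @param subsets List of band-name vectors (default all subsets of sizes
#'   1-3).
#' @param tasks Tasks to run (default valence and arousal).
#' @param variant Architecture variant (default `"CSBN"`).
#' @param k Fold count (default 10).
#' @return Data frame: subset label, task, mean metrics, max accuracy.
#' @export
run_band_suite <- function(features, cfg, subsets = band_subsets(),
                           tasks = c("valence", "arousal"),
                           variant = "CSBN", k = 10) {
  rows <- list()
  for (task in tasks) {
    labels <- de_labels(features, task)
    for (sub in subsets) {
      fsub <- select_bands(features, sub)
      spec <- tryCatch(model_spec(input_len = ncol(fsub), variant = variant),
                       error = function(e) {
                         stop(sprintf("subset (%s): %s",
                                      paste(sub, collapse = ","),
                                      conditionMessage(e)))
                       })
      cfg_t <- cfg
      cfg_t$task <- task
      cv <- cross_validate(spec, fsub, labels, cfg_t, k = k)
      rows[[length(rows) + 1L]] <-
        data.frame(subset = paste(sub, collapse = ","), task = task,
                   accuracy = cv$mean["accuracy"],
                   precision = cv$mean["precision"],
                   f1 = cv$mean["f1"], auc = cv$mean["auc"],
                   max_accuracy = cv$max["accuracy"],
                   row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
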