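# Shared fixtures, built lazily and cached for the whole run.

.fixture_env <- new.env(parent = emptyenv())

# Reduced-scale synthetic study: 8 channels at 128 Hz, 10-s trials,
# 25 trials per class -> 4 usable 2-s windows per trial = 100 segments per
# class, alpha-dominant class signatures (the generator defaults).
fixture_features <- function() {
  if (is.null(.fixture_env$features)) {
    spec <- synth_spec(n_trials_per_class = 25, n_channels = 8,
                       trial_seconds = 10, fs = 128, seed = 101L)
    ds <- make_dataset(spec)
    segs <- preprocess_dataset(ds$recordings, ds$ratings)
    .fixture_env$dataset <- ds
    .fixture_env$features <- build_feature_matrix(segs)
  }
  .fixture_env$features
}

fixture_dataset <- function() {
  fixture_features()
  .fixture_env$dataset
}

# Tiny linearly separable two-class feature set for optimizer tests.
separable_features <- function(n_per_class = 40, p = 32, gap = 3, seed = 7) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p, mean = 0), n_per_class, p),
             matrix(rnorm(n_per_class * p, mean = gap), n_per_class, p))
  y <- rep(c(0L, 1L), each = n_per_class)
  list(X = X, y = y)
}

# Raw periodogram band-power share (independent spectral oracle).
band_power_share <- function(x, fs, low, high) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  inband <- half & freq >= low & freq <= high
  sum(P[inband]) / sum(P[half & freq > 0])
}
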