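# Raw recordings -> labeled 2-s band-decomposed segments: 1-45 Hz band-pass,
# downsample to 128 Hz, baseline correction on the first 2 s, Hann-windowed
# non-overlapping segmentation, order-3 Butterworth band split, rating
# binarization at threshold 5.

#' Multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param meta List of trial metadata (class, trial id, ...).
#' @return A `recording` object.
#' @export
recording <- function(data, fs, channel_labels = NULL, meta = list()) {
  data <- as.matrix(data)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%03d", seq_len(nrow(data)))
  }
  stopifnot(fs > 0, nrow(data) == length(channel_labels), all(is.finite(data)))
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Standard EEG band set
#'
#' Theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz, in that order.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
default_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 45))
}

#' Zero-phase Butterworth band-pass filter
#'
#' The filter is applied forward and backward (`signal::filtfilt`), so the
#' effective magnitude response is the squared Butterworth response and the
#' phase is zero — band power is not shifted across windows.
#'
#' @param rec A [recording()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param order Butterworth order (default 3).
#' @return Filtered [recording()] of the same shape and rate.
#' @export
bandpass <- function(rec, low_hz, high_hz, order = 3) {
  stopifnot(inherits(rec, "recording"))
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rec$fs / 2)) {
    stop(sprintf("invalid band (%g, %g) Hz for fs = %g", low_hz, high_hz, rec$fs))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  if (nrow(rec$data) == 1L) out <- matrix(out, nrow = 1)
  recording(out, rec$fs, rec$channel_labels, rec$meta)
}

# FFT resampling of one channel to nout samples (Fourier-domain truncation).
fft_resample <- function(x, nout) {
  n <- length(x)
  if (nout == n) return(x)
  X <- stats::fft(x)
  h <- floor(min(n, nout) / 2)
  Y <- complex(real = numeric(nout))
  Y[seq_len(h + 1)] <- X[seq_len(h + 1)]
  if (h > 0) Y[(nout - h + 1):nout] <- X[(n - h + 1):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Downsample a recording
#'
#' Fourier-domain resampling: the spectrum is truncated at the new Nyquist
#' frequency and inverse-transformed, so in-band components are preserved
#' essentially exactly. Only downsampling is supported.
#'
#' @param rec A [recording()].
#' @param target_fs New sampling rate in Hz (<= `rec$fs`).
#' @return Resampled [recording()] with `round(n * target_fs / fs)` samples.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs > rec$fs) stop("upsampling is not supported")
  if (target_fs == rec$fs) return(rec)
  nout <- round(ncol(rec$data) * target_fs / rec$fs)
  out <- t(apply(rec$data, 1, fft_resample, nout = nout))
  if (nrow(rec$data) == 1L) out <- matrix(out, nrow = 1)
  recording(out, target_fs, rec$channel_labels, rec$meta)
}

#' Baseline correction
#'
#' Subtracts each channel's mean over the first `baseline_seconds` from the
#' whole channel, then drops the baseline window from the recording (it is a
#' reference period, not stimulus data).
#'
#' @param rec A [recording()].
#' @param baseline_seconds Length of the baseline window (default 2).
#' @return Corrected, shortened [recording()].
#' @export
baseline_correct <- function(rec, baseline_seconds = 2) {
  stopifnot(inherits(rec, "recording"))
  nb <- round(baseline_seconds * rec$fs)
  if (nb >= ncol(rec$data)) stop("recording shorter than the baseline window")
  if (nb < 1) stop("baseline window must contain at least one sample")
  mu <- rowMeans(rec$data[, seq_len(nb), drop = FALSE])
  out <- rec$data - mu
  out <- out[, (nb + 1):ncol(out), drop = FALSE]
  recording(out, rec$fs, rec$channel_labels, rec$meta)
}

#' Artifact-removal hook
#'
#' Placeholder for ICA-based ocular/muscular artifact removal, which in the
#' emulated protocol is interactive (component inspection by eye) and out of
#' scope here. `method = "none"` passes the recording through unchanged.
#'
#' @param rec A [recording()].
#' @param method Only `"none"` is implemented.
#' @return The recording, unchanged.
#' @export
remove_artifacts <- function(rec, method = c("none")) {
  method <- match.arg(method)
  rec
}

#' Segment a recording into labeled windows
#'
#' Cuts non-overlapping `window_seconds` windows (trailing partial window
#' discarded). With `taper = "hann"` each window is multiplied per sample by
#' a Hann taper and rescaled by `1/sqrt(mean(w^2))` so the expected power of
#' stationary noise is preserved.
#'
#' @param rec A [recording()].
#' @param window_seconds Window length in seconds (default 2).
#' @param taper `"hann"` (default) or `"none"`.
#' @param valence_label,arousal_label Binary labels copied onto every
#'   segment (may be NA when unlabeled data is segmented).
#' @return List of `labeled_segment` objects: fields `data` (channels x T),
#'   `fs`, `class_name`, `valence_label`, `arousal_label`, `trial_id`,
#'   `window_index`.
#' @export
segment_recording <- function(rec, window_seconds = 2,
                              taper = c("hann", "none"),
                              valence_label = NA_integer_,
                              arousal_label = NA_integer_) {
  stopifnot(inherits(rec, "recording"))
  taper <- match.arg(taper)
  t_len <- window_seconds * rec$fs
  if (abs(t_len - round(t_len)) > 1e-9) {
    stop("window_seconds * fs must be an integer")
  }
  t_len <- as.integer(round(t_len))
  n_win <- ncol(rec$data) %/% t_len
  if (n_win == 0L) {
    warning("recording shorter than one window; no segments produced")
    return(list())
  }
  w <- if (taper == "hann") {
    h <- 0.5 - 0.5 * cos(2 * pi * seq(0, t_len - 1) / (t_len - 1))
    h / sqrt(mean(h^2))
  } else rep(1, t_len)
  lapply(seq_len(n_win), function(i) {
    cols <- ((i - 1L) * t_len + 1L):(i * t_len)
    seg <- rec$data[, cols, drop = FALSE] *
      matrix(w, nrow = nrow(rec$data), ncol = t_len, byrow = TRUE)
    structure(list(data = seg, fs = rec$fs,
                   class_name = rec$meta$class_name %||% NA_character_,
                   valence_label = valence_label,
                   arousal_label = arousal_label,
                   trial_id = rec$meta$trial_id %||% NA_character_,
                   window_index = i),
              class = "labeled_segment")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decompose a signal into frequency bands
#'
#' Applies an order-3 zero-phase Butterworth band-pass per band; output
#' order follows the band set's order.
#'
#' @param x A [recording()], a `labeled_segment`, or a channels x samples
#'   matrix.
#' @param bands Named list of `c(low, high)` pairs (default
#'   [default_bands()]).
#' @param fs Sampling rate; required only when `x` is a bare matrix.
#' @param order Butterworth order (default 3).
#' @return Named list, one channels x samples matrix per band.
#' @export
band_decompose <- function(x, bands = default_bands(), fs = NULL, order = 3) {
  if (inherits(x, "recording")) { dat <- x$data; fs <- x$fs }
  else if (inherits(x, "labeled_segment")) { dat <- x$data; fs <- x$fs }
  else { dat <- as.matrix(x); if (is.null(fs)) stop("fs required for a matrix") }
  out <- vector("list", length(bands))
  names(out) <- names(bands)
  for (b in seq_along(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    if (!(lo > 0 && lo < hi && hi < fs / 2)) {
      stop(sprintf("band %s = (%g, %g) Hz invalid for fs = %g",
                   names(bands)[b], lo, hi, fs))
    }
    bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
    fd <- t(apply(dat, 1, function(ch) signal::filtfilt(bf, ch)))
    if (nrow(dat) == 1L) fd <- matrix(fd, nrow = 1)
    out[[b]] <- fd
  }
  out
}

#' Binarize a 1-9 rating
#'
#' Ratings below 5 map to 0 (low), above 5 to 1 (high). A rating of exactly
#' 5 maps to 1: the rule is monotone nondecreasing and the boundary is
#' assigned to the high class (recorded in the returned attribute
#' `threshold_rule`).
#'
#' @param rating Numeric vector of ratings in `[1, 9]`.
#' @param threshold Decision threshold (default 5).
#' @return Integer vector of 0/1 labels.
#' @export
binarize_ratings <- function(rating, threshold = 5) {
  if (any(rating < 1 | rating > 9)) stop("ratings must lie in [1, 9]")
  out <- as.integer(rating >= threshold)
  attr(out, "threshold_rule") <- sprintf(">=%g -> 1", threshold)
  out
}

#' Full preprocessing pipeline
#'
#' For each trial: 1-45 Hz band-pass, downsample to `target_fs`, baseline
#' correction on the first `baseline_seconds` (window then dropped), and
#' Hann-windowed segmentation. Trial ratings are binarized at `threshold`
#' and copied onto every segment of the trial.
#'
#' @param recordings List of [recording()]s with `meta$trial_id` set.
#' @param ratings Data frame with columns trial_id, class, valence, arousal.
#' @param bandpass_hz `c(low, high)` of the broadband filter (default 1-45).
#' @param target_fs Post-downsampling rate (default 128 Hz).
#' @param baseline_seconds Baseline window (default 2 s).
#' @param window_seconds Segment length (default 2 s).
#' @param taper Segment taper, `"hann"` or `"none"`.
#' @param threshold Rating binarization threshold (default 5).
#' @return List of `labeled_segment`s across all trials.
#' @export
preprocess_dataset <- function(recordings, ratings,
                               bandpass_hz = c(1, 45), target_fs = 128,
                               baseline_seconds = 2, window_seconds = 2,
                               taper = "hann", threshold = 5) {
  segs <- list()
  for (rec in recordings) {
    tid <- rec$meta$trial_id
    row <- ratings[ratings$trial_id == tid, , drop = FALSE]
    if (nrow(row) != 1L) stop(sprintf("no unique rating row for trial %s", tid))
    v <- binarize_ratings(row$valence, threshold)
    a <- binarize_ratings(row$arousal, threshold)
    r <- bandpass(rec, bandpass_hz[1], bandpass_hz[2], order = 3)
    r <- resample_recording(r, target_fs)
    r <- baseline_correct(r, baseline_seconds)
    s <- segment_recording(r, window_seconds, taper = taper,
                           valence_label = as.integer(v),
                           arousal_label = as.integer(a))
    segs <- c(segs, s)
  }
  segs
}
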