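# Differential-entropy (DE) features. For a zero-mean Gaussian band signal
# the DE has the closed form h = 1/2 log(2*pi*e*sigma^2); one DE value per
# channel per band summarises each 2-s window, giving an N x (C*B) matrix.

#' Gaussian differential entropy
#'
#' Closed form `0.5 * log_base(2 * pi * e * sigma2)` for a Gaussian with
#' variance `sigma2`. A variance floor guards against -Inf on degenerate
#' (constant) inputs.
#'
#' @param sigma2 Variance (signal units squared).
#' @param log_base 2 (bits, default) or `exp(1)` (nats).
#' @param variance_floor Smallest admissible variance (default 1e-10).
#' @return DE in bits (base 2) or nats (base e).
#' @export
gaussian_de <- function(sigma2, log_base = 2, variance_floor = 1e-10) {
  if (any(sigma2 <= 0) && variance_floor <= 0) {
    stop("non-positive variance with no floor: degenerate signal")
  }
  s2 <- pmax(sigma2, variance_floor)
  0.5 * log(2 * pi * exp(1) * s2) / log(log_base)
}

#' Numerical differential entropy of the symmetric two-Gaussian density
#'
#' Quadrature oracle for the density
#' `p(x) = 1/(sqrt(2*pi)*sigma) * exp(-(x^2+mu^2)/(2*sigma^2)) * cosh(mu*x/sigma^2)`,
#' i.e. an equal mixture of N(mu, sigma^2) and N(-mu, sigma^2). At mu = 0 it
#' reduces to the Gaussian, so it independently checks [gaussian_de()]; for
#' mu/sigma large its entropy exceeds the Gaussian's by ln 2 (one bit: which
#' mode). The excess `L(mu/sigma) = h - 0.5*log(2*pi*e*sigma^2)` rises from
#' 0 to ln 2.
#'
#' @param mu Mixture mode location.
#' @param sigma Component standard deviation (> 0).
#' @param log_base 2 or `exp(1)`.
#' @return List with `de` (entropy in the requested base) and `L_nats` (the
#'   excess over the Gaussian entropy, in nats).
#' @export
mixture_de_numeric <- function(mu, sigma, log_base = 2) {
  stopifnot(sigma > 0)
  dens <- function(x) {
    1 / (sqrt(2 * pi) * sigma) *
      exp(-(x^2 + mu^2) / (2 * sigma^2)) * cosh(mu * x / sigma^2)
  }
  integrand <- function(x) {
    p <- dens(x)
    out <- numeric(length(x))
    ok <- p > .Machine$double.xmin
    out[ok] <- -p[ok] * log(p[ok])
    out
  }
  lim <- abs(mu) + 40 * sigma
  q <- stats::integrate(integrand, -lim, lim, rel.tol = 1e-10,
                        subdivisions = 1000L)
  if (q$message != "OK") stop("quadrature did not converge: ", q$message)
  h_nats <- q$value
  list(de = h_nats / log(log_base),
       L_nats = h_nats - 0.5 * log(2 * pi * exp(1) * sigma^2))
}

#' DE feature vector of one band-decomposed segment
#'
#' Per channel and band: unbiased sample variance of the band signal, then
#' [gaussian_de()]. Entries are assembled band-major:
#' `(band1.ch1, ..., band1.chC, band2.ch1, ...)`.
#'
#' @param banded Named list (one entry per band) of channels x T matrices,
#'   as returned by [band_decompose()].
#' @param log_base Logarithm base (default 2, bits).
#' @param variance_floor Variance floor before the log (default 1e-10);
#'   floored entries trigger a warning.
#' @return Numeric vector of length `C * B` with names `band.channel`.
#' @export
segment_de <- function(banded, log_base = 2, variance_floor = 1e-10) {
  stopifnot(is.list(banded), length(banded) >= 1)
  dims <- vapply(banded, dim, integer(2))
  if (any(dims != dims[, 1])) stop("band signals must share one shape")
  if (dims[2, 1] < 2) stop("need at least 2 samples per window")
  vals <- unlist(lapply(banded, function(m) apply(m, 1, stats::var)),
                 use.names = FALSE)
  n_floored <- sum(vals < variance_floor)
  if (n_floored > 0) {
    warning(sprintf("%d zero-variance entries floored at %g",
                    n_floored, variance_floor))
  }
  de <- gaussian_de(vals, log_base, variance_floor)
  chn <- rownames(banded[[1]])
  if (is.null(chn)) chn <- sprintf("ch%03d", seq_len(dims[1, 1]))
  names(de) <- unlist(lapply(names(banded), function(b) paste(b, chn, sep = ".")))
  de
}

#' Build the DE feature matrix
#'
#' One row per segment: the segment is band-decomposed (order-3 Butterworth)
#' and summarised by [segment_de()]. With 128 channels and 4 bands each row
#' has 512 entries.
#'
#' @param segments Non-empty list of `labeled_segment`s with a common
#'   channel count.
#' @param bands Named band list (default [default_bands()]).
#' @param log_base Logarithm base (default 2).
#' @return A `de_matrix`: numeric matrix N x (C*B) with attributes
#'   `band_names`, `channel_labels`, `log_base`, `ordering` ("band-major")
#'   and `row_meta` (data.frame: class, valence, arousal, trial_id,
#'   window_index).
#' @export
build_feature_matrix <- function(segments, bands = default_bands(),
                                 log_base = 2) {
  if (length(segments) == 0L) stop("empty segment list")
  ncs <- vapply(segments, function(s) nrow(s$data), integer(1))
  if (length(unique(ncs)) != 1L) stop("segments have heterogeneous channel counts")
  rows <- lapply(segments, function(s) {
    segment_de(band_decompose(s, bands), log_base = log_base)
  })
  m <- do.call(rbind, rows)
  meta <- data.frame(
    class = vapply(segments, function(s) s$class_name, character(1)),
    valence = vapply(segments, function(s) as.integer(s$valence_label), integer(1)),
    arousal = vapply(segments, function(s) as.integer(s$arousal_label), integer(1)),
    trial_id = vapply(segments, function(s) s$trial_id, character(1)),
    window_index = vapply(segments, function(s) as.integer(s$window_index), integer(1)),
    stringsAsFactors = FALSE)
  de_matrix(m, band_names = names(bands),
            channel_labels = sprintf("ch%03d", seq_len(ncs[1])),
            log_base = log_base, row_meta = meta)
}

#' Construct a DE matrix container
#'
#' @param values N x (C*B) numeric matrix, band-major columns.
#' @param band_names,channel_labels Column ordering metadata.
#' @param log_base Logarithm base used.
#' @param row_meta Per-row label data.frame (or NULL).
#' @return A `de_matrix` object.
#' @export
de_matrix <- function(values, band_names, channel_labels, log_base = 2,
                      row_meta = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != length(band_names) * length(channel_labels)) {
    stop("column count must equal n_bands * n_channels")
  }
  if (!all(is.finite(values))) stop("DE matrix contains non-finite values")
  structure(values,
            band_names = band_names, channel_labels = channel_labels,
            log_base = log_base, ordering = "band-major",
            row_meta = row_meta, class = c("de_matrix", "matrix"))
}

#' @export
`[.de_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (!missing(j)) {
    # arbitrary column subsets lose the band structure; return a bare matrix
    return(unclass(x)[i, j, drop = drop])
  }
  meta <- attr(x, "row_meta")
  de_matrix(unclass(x)[i, , drop = FALSE],
            band_names = attr(x, "band_names"),
            channel_labels = attr(x, "channel_labels"),
            log_base = attr(x, "log_base"),
            row_meta = if (is.null(meta)) NULL else meta[i, , drop = FALSE])
}

#' @export
print.de_matrix <- function(x, ...) {
  cat(sprintf("<de_matrix> %d segments x %d features (%d channels x %d bands: %s)\n",
              nrow(x), ncol(x), length(attr(x, "channel_labels")),
              length(attr(x, "band_names")),
              paste(attr(x, "band_names"), collapse = ", ")))
  invisible(x)
}

#' Restrict a DE matrix to a band subset
#'
#' Keeps only the columns of the chosen bands, preserving the matrix's
#' band-major order and row metadata.
#'
#' @param mat A `de_matrix`.
#' @param subset Character vector of band names (non-empty, each a band of
#'   `mat`).
#' @return A `de_matrix` with `length(subset) * C` columns.
#' @export
select_bands <- function(mat, subset) {
  bn <- attr(mat, "band_names")
  if (length(subset) == 0L) stop("band subset must be non-empty")
  if (!all(subset %in% bn)) {
    stop("unknown band(s): ", paste(setdiff(subset, bn), collapse = ", "))
  }
  keep_bands <- bn[bn %in% subset]            # preserve stored order
  C <- length(attr(mat, "channel_labels"))
  cols <- unlist(lapply(match(keep_bands, bn), function(b) ((b - 1) * C + 1):(b * C)))
  de_matrix(unclass(mat)[, cols, drop = FALSE],
            band_names = keep_bands,
            channel_labels = attr(mat, "channel_labels"),
            log_base = attr(mat, "log_base"),
            row_meta = attr(mat, "row_meta"))
}
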