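# Plain-text I/O: recordings as CSV (rows = samples, header = channel
# labels) with a JSON sidecar carrying the sampling rate and trial
# metadata; ratings and suite results as CSV/JSON.

#' Write a recording to CSV + JSON sidecar
#'
#' @param rec A [recording()].
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channel_labels = rec$channel_labels,
                            meta = rec$meta),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a recording written by [write_recording_csv()]
#'
#' @param path CSV path with an adjacent `.json` sidecar.
#' @return A [recording()].
#' @export
read_recording_csv <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  recording(t(as.matrix(df)), fs = side$fs,
            channel_labels = side$channel_labels,
            meta = as.list(side$meta))
}

#' Write a ratings table
#'
#' Columns: trial_id, class, valence, arousal.
#'
#' @param ratings Data frame from [make_dataset()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(ratings, path) {
  stopifnot(all(c("trial_id", "class", "valence", "arousal") %in%
                  names(ratings)))
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' Read a ratings table
#'
#' @param path CSV path.
#' @return Data frame with trial_id, class, valence, arousal.
#' @export
read_ratings_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a DE feature matrix to CSV + JSON sidecar
#'
#' The CSV holds the feature values plus the row-metadata columns; the
#' sidecar records band order, channel order and log base so the band-major
#' column layout is explicit.
#'
#' @param features A `de_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  meta <- attr(features, "row_meta")
  df <- cbind(as.data.frame(unclass(features)), meta)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(band_order = attr(features, "band_names"),
                            channel_order = attr(features, "channel_labels"),
                            log_base = attr(features, "log_base"),
                            ordering = attr(features, "ordering"),
                            n_meta_cols = ncol(meta)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a DE feature matrix written by [write_features_csv()]
#'
#' @param path CSV path with an adjacent `.json` sidecar.
#' @return A `de_matrix`.
#' @export
read_features_csv <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  n_feat <- ncol(df) - side$n_meta_cols
  de_matrix(as.matrix(df[, seq_len(n_feat)]),
            band_names = side$band_order,
            channel_labels = side$channel_order,
            log_base = side$log_base,
            row_meta = df[, (n_feat + 1):ncol(df), drop = FALSE])
}

#' Write suite results as CSV and JSON
#'
#' @param result Data frame from [run_ablation_suite()] or
#'   [run_band_suite()].
#' @param path Base path without extension; writes `.csv` and `.json`.
#' @param config Optional list echoed into the JSON for provenance.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, config = NULL) {
  utils::write.csv(result, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(config = config, results = result),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
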