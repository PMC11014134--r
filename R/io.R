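#' Write / read a recording as CSV
#'
#' Columns `time_s, ch1..chN`; labels, sampling rate, stimulation parameters
#' and seed go to a JSON sidecar (`<path>.json`). Round-trips values at full
#' printed precision (15 significant digits, relative error < 1e-9).
#'
#' @param rec A `fessemg_recording`.
#' @param path Output CSV path.
#' @return `read_recording_csv` returns a `fessemg_recording` (without the
#'   synthetic ground-truth `clean` matrix).
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "fessemg_recording"))
  n <- ncol(rec$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sampling_rate_hz)
  for (ch in seq_len(nrow(rec$samples)))
    df[[paste0("ch", ch)]] <- rec$samples[ch, ]
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(sampling_rate_hz = rec$sampling_rate_hz,
               motion_label = rec$motion_label,
               fatigue_label = rec$fatigue_label,
               stim_params = rec$stim_params,
               seed = rec$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path)
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  if (!"time_s" %in% names(df) || length(ch_cols) == 0)
    stop_input("malformed recording CSV '", path,
               "': expected columns time_s, ch1..chN; found: ",
               paste(names(df), collapse = ", "))
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop_input("missing metadata sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  samples <- t(as.matrix(df[, ch_cols, drop = FALSE]))
  dimnames(samples) <- NULL
  structure(list(samples = samples,
                 clean = NULL,
                 sampling_rate_hz = meta$sampling_rate_hz,
                 motion_label = meta$motion_label,
                 fatigue_label = meta$fatigue_label,
                 stim_params = as.list(meta$stim_params),
                 seed = as.integer(meta$seed)),
            class = "fessemg_recording")
}

#' Write / read a labels manifest
#'
#' CSV with columns `recording_id, motion, fatigue, seed`; reading a file
#' without all four columns raises an explicit schema error.
#'
#' @param manifest Data frame with the four columns (e.g. the `manifest`
#'   attribute of [generate_dataset()]).
#' @param path CSV path.
#' @export
write_manifest_csv <- function(manifest, path) {
  need <- c("recording_id", "motion", "fatigue", "seed")
  stopifnot(all(need %in% names(manifest)))
  utils::write.csv(manifest[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "motion", "fatigue", "seed")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_input("manifest '", path, "' is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  df
}

#' Write a time-frequency image to disk
#'
#' 8-bit RGB PNG via the `png` package when available, otherwise a
#' plain-text PPM (P3). A JSON sidecar stores method, labels and axes.
#' Images are written with the frequency axis pointing up (row 1 of the
#' file is the highest frequency).
#'
#' @param img A `fessemg_tfimage`.
#' @param path Output path (`.png` or `.ppm`; extension adjusted to the
#'   writer actually used).
#' @return The path actually written, invisibly.
#' @export
write_tf_image <- function(img, path) {
  stopifnot(inherits(img, "fessemg_tfimage"))
  px <- img$pixels[dim(img$pixels)[1]:1, , , drop = FALSE] # freq axis up
  if (requireNamespace("png", quietly = TRUE)) {
    if (!grepl("\\.png$", path)) path <- sub("\\.[a-z]+$", "", path)
    if (!grepl("\\.png$", path)) path <- paste0(path, ".png")
    png::writePNG(px, path)
  } else {
    path <- sub("\\.png$", ".ppm", path)
    if (!grepl("\\.ppm$", path)) path <- paste0(path, ".ppm")
    write_ppm(px, path)
  }
  meta <- list(method = img$method, channel_id = img$channel_id,
               motion_label = img$motion_label,
               fatigue_label = img$fatigue_label,
               freq_axis_hz = img$freq_axis, time_axis_s = img$time_axis)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = 8)
  invisible(path)
}

# Plain-text PPM (P3) writer: portable, no compiled dependencies.
write_ppm <- function(px, path) {
  d <- dim(px)
  v <- round(pmin(pmax(px, 0), 1) * 255)
  # interleave RGB row-major
  rows <- matrix(0L, nrow = d[1], ncol = d[2] * 3)
  rows[, seq(1, d[2] * 3, by = 3)] <- v[, , 1]
  rows[, seq(2, d[2] * 3, by = 3)] <- v[, , 2]
  rows[, seq(3, d[2] * 3, by = 3)] <- v[, , 3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), "255"), con)
  utils::write.table(rows, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a feature table as CSV
#'
#' One row per example: recording id, labels, then the feature columns.
#'
#' @param features Numeric feature matrix (rows = examples).
#' @param labels Data frame with `recording_id`, `motion`, `fatigue`.
#' @param path CSV path.
#' @export
write_features_csv <- function(features, labels, path) {
  stopifnot(nrow(features) == nrow(labels))
  utils::write.csv(cbind(labels, as.data.frame(features)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a metrics report (CSV + JSON)
#'
#' @param metrics A `fessemg_metrics`.
#' @param path_base Path without extension; writes `<base>.csv` and
#'   `<base>.json`.
#' @export
write_metrics <- function(metrics, path_base) {
  df <- as.data.frame(metrics)
  utils::write.csv(df, paste0(path_base, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(accuracy = attr(metrics, "accuracy"),
                            macro = as.list(attr(metrics, "macro")),
                            per_class = df),
                       paste0(path_base, ".json"),
                       auto_unbox = TRUE, digits = 6)
  invisible(path_base)
}

#' Write a confusion matrix as CSV
#' @param cm A `fessemg_confusion`.
#' @param path CSV path.
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "fessemg_confusion"))
  df <- as.data.frame(cm$matrix)
  utils::write.csv(cbind(class = cm$labels, df), path, row.names = FALSE)
  invisible(path)
}
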