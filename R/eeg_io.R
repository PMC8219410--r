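# Reading, validating, channel-selecting and epoching multichannel EEG.

#' Default EEG channel layout
#'
#' The four frontal/temporal channels used for attention monitoring, in the
#' fixed order that determines feature indexing.
#' @return Character vector `c("TP9", "AF7", "AF8", "TP10")`.
#' @export
default_channels <- function() c("TP9", "AF7", "AF8", "TP10")

new_recording <- function(data, channel_names, fs) {
  if (anyDuplicated(channel_names)) {
    abort_fmt("duplicate channel names: %s",
              paste(unique(channel_names[duplicated(channel_names)]),
                    collapse = ", "))
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort_fmt("sampling rate must be a positive number, got %s",
              paste(fs, collapse = ","))
  }
  if (nrow(data) < 1) abort_fmt("recording must contain at least one sample")
  colnames(data) <- channel_names
  structure(list(data = data, channel_names = channel_names, fs = as.numeric(fs)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$data), length(x$channel_names), x$fs,
              nrow(x$data) / x$fs))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a multichannel EEG recording
#'
#' CSV files must carry a header row of channel names and one sample per
#' row; the sampling rate comes from `fs` (CSV has no rate field). EDF
#' files are read with a built-in minimal EDF/EDF+ reader and the rate
#' comes from the file header.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`.
#' @param fs Sampling rate in Hz for CSV input (default 256).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("csv", "edf"), fs = 256) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  if (format == "edf") return(read_edf(path))
  raw <- tryCatch(
    read.csv(path, check.names = FALSE, colClasses = "character",
             fill = FALSE, strip.white = TRUE),
    error = function(e) abort_fmt("malformed CSV '%s': %s", path,
                                  conditionMessage(e))
  )
  if (ncol(raw) < 1 || nrow(raw) < 1) abort_fmt("empty recording: %s", path)
  channels <- colnames(raw)
  data <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw))
  for (j in seq_along(channels)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !(raw[[j]] %in% c("NA", "")))
    if (length(bad) > 0) {
      abort_fmt("non-numeric value '%s' in channel %s, data row %d of %s",
                raw[[j]][bad[1]], channels[j], bad[1], path)
    }
    if (anyNA(v)) {
      abort_fmt("missing value in channel %s, data row %d of %s",
                channels[j], which(is.na(v))[1], path)
    }
    data[, j] <- v
  }
  new_recording(data, channels, fs)
}

#' Select and reorder channels
#'
#' @param rec An `eeg_recording`.
#' @param names Ordered channel names to keep (default the four-channel
#'   attention montage TP9, AF7, AF8, TP10).
#' @return An `eeg_recording` with exactly the requested channels in the
#'   requested order.
#' @export
select_channels <- function(rec, names = default_channels()) {
  m <- match(names, rec$channel_names)
  if (anyNA(m)) {
    abort_fmt("unknown channel(s) %s; available: %s",
              paste(names[is.na(m)], collapse = ", "),
              paste(rec$channel_names, collapse = ", "))
  }
  new_recording(rec$data[, m, drop = FALSE], names, rec$fs)
}

new_epoch <- function(data, fs, start_index, label = NULL) {
  structure(list(data = data, fs = fs, start_index = as.integer(start_index),
                 label = if (is.null(label)) NULL else as_attention_level(label)),
            class = "eeg_epoch")
}

#' Cut a recording into fixed-length epochs
#'
#' Epochs tile the recording left to right with stride
#' `epoch_samples * (1 - overlap_fraction)`; a trailing partial window is
#' dropped. Sample indices are 0-based and epochs are half-open
#' `[start, start + len)`.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_seconds Epoch duration in seconds (default 1).
#' @param overlap_fraction Fractional overlap in `[0, 1)` (default 0).
#' @param labels Optional per-epoch attention labels (recycled check: must
#'   match the number of epochs produced).
#' @return List of `eeg_epoch` objects (empty, with a warning, if the
#'   recording is shorter than one epoch).
#' @export
epoch_recording <- function(rec, epoch_seconds = 1.0, overlap_fraction = 0,
                            labels = NULL) {
  if (!is.numeric(epoch_seconds) || epoch_seconds <= 0) {
    abort_fmt("epoch_seconds must be positive")
  }
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 ||
      overlap_fraction >= 1) {
    abort_fmt("overlap_fraction must be in [0, 1)")
  }
  len <- round(epoch_seconds * rec$fs)
  n <- nrow(rec$data)
  if (len > n) {
    warning(sprintf("recording (%d samples) shorter than one epoch (%d samples); no epochs produced",
                    n, len))
    return(list())
  }
  stride <- max(1L, as.integer(round(len * (1 - overlap_fraction))))
  starts <- seq(0L, n - len, by = stride)
  if (!is.null(labels) && length(labels) != length(starts)) {
    abort_fmt("got %d labels for %d epochs", length(labels), length(starts))
  }
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    new_epoch(rec$data[(s + 1):(s + len), , drop = FALSE], rec$fs, s,
              label = if (is.null(labels)) NULL else labels[i])
  })
}

feature_names <- function(channels = default_channels(), bands = eeg_bands()) {
  as.vector(t(outer(channels, bands, paste, sep = "_")))
}

#' Write a feature matrix to CSV
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip is lossless to at least 1e-12 relative tolerance. Labels, when
#' present, are stored by name in a trailing `label` column.
#'
#' @param m A `feature_matrix` (see [extract_matrix()]).
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(inherits(m, "feature_matrix"))
  cells <- matrix(sprintf("%.17g", m$x), nrow = nrow(m$x))
  header <- colnames(m$x)
  if (!is.null(m$labels)) {
    cells <- cbind(cells, attention_level_name(m$labels))
    header <- c(header, "label")
  }
  lines <- c(paste(header, collapse = ","),
             apply(cells, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV path written by [write_feature_matrix()].
#' @param channels,bands Expected channel and band grid; the file header
#'   must match `CHANNEL_band` for every pair (plus an optional `label`
#'   column) or a format error is raised.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, channels = default_channels(),
                                bands = eeg_bands()) {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE)
  expected <- feature_names(channels, bands)
  has_label <- "label" %in% colnames(df)
  feat_cols <- setdiff(colnames(df), "label")
  if (!identical(feat_cols, expected)) {
    missing <- setdiff(expected, feat_cols)
    extra <- setdiff(feat_cols, expected)
    abort_fmt("feature header mismatch with the %d-channel x %d-band grid%s%s",
              length(channels), length(bands),
              if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
              if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else "")
  }
  x <- as.matrix(df[, expected, drop = FALSE])
  if (!is.numeric(x)) abort_fmt("non-numeric feature values in %s", path)
  labels <- if (has_label) as_attention_level(df$label) else NULL
  new_feature_matrix(x, labels)
}
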