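# Band-power feature extraction: each epoch channel is decomposed,
# denoised, and reconstructed band by band; per-band power gives the
# 4 channels x 5 bands = 20-dimensional feature vector. The finest detail
# D1 (64-128 Hz) is treated as noise and excluded.

#' Mean power of a band-limited signal
#'
#' The per-band "PSD feature": the mean of squared samples of the
#' band-limited reconstruction over the epoch.
#'
#' @param band_signal Nonempty numeric vector.
#' @return Nonnegative scalar.
#' @export
band_power <- function(band_signal) {
  if (length(band_signal) == 0) abort_fmt("band_power: empty signal")
  mean(band_signal^2)
}

new_feature_matrix <- function(x, labels = NULL) {
  if (!is.null(labels)) {
    labels <- as_attention_level(labels)
    if (length(labels) != nrow(x)) {
      abort_fmt("got %d labels for %d feature rows", length(labels), nrow(x))
    }
  }
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d%s\n", nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) "" else " (labeled)"))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' Extract the 20-dimensional band-power feature vector of one epoch
#'
#' Per channel: wavelet decomposition, optional SURE soft-threshold
#' denoising, reconstruction of the five named subbands (A5 = delta,
#' D5 = theta, D4 = alpha, D3 = beta, D2 = gamma at fs = 256, L = 5), and
#' mean power of each reconstruction. Features are ordered channel-major:
#' all five bands of TP9, then AF7, AF8, TP10.
#'
#' @param epoch An `eeg_epoch` with exactly the configured channels.
#' @param cfg A [wavelet_config()]; its named band map must cover the five
#'   EEG bands (the default fs = 256, L = 5 does).
#' @param log_transform Apply `log10(power + 1e-12)` (default TRUE, for
#'   classifier stability).
#' @param relative Divide band powers by their per-channel sum before any
#'   log transform (default FALSE: absolute power).
#' @param denoise Apply SURE denoising before reconstruction (default TRUE).
#' @param channels Required channel set and order.
#' @return Named numeric vector of length `channels x bands`, with the
#'   epoch label (if any) in attribute `"label"`.
#' @export
extract_features <- function(epoch, cfg = wavelet_config(),
                             log_transform = TRUE, relative = FALSE,
                             denoise = TRUE, channels = default_channels()) {
  have <- colnames(epoch$data)
  if (!identical(have, channels)) {
    abort_fmt("epoch channels (%s) do not match the configured set (%s)",
              paste(have, collapse = ", "), paste(channels, collapse = ", "))
  }
  bm <- band_map(cfg)
  bands <- eeg_bands()
  sub_of_band <- bm$subband[match(bands, bm$band)]
  if (anyNA(sub_of_band)) {
    abort_fmt("configuration (fs=%g, levels=%d) does not produce the named EEG bands",
              cfg$fs, cfg$levels)
  }
  out <- numeric(0)
  for (ch in channels) {
    dec <- decompose(epoch$data[, ch], cfg)
    if (denoise) dec <- denoise(dec)
    p <- vapply(sub_of_band, function(sb) band_power(reconstruct_band(dec, sb)), 0)
    if (relative) {
      tot <- sum(p)
      if (tot > 0) p <- p / tot
    }
    if (log_transform) p <- log10(p + 1e-12)
    out <- c(out, p)
  }
  names(out) <- feature_names(channels, bands)
  attr(out, "label") <- epoch$label
  out
}

#' Extract a feature matrix from a list of epochs
#'
#' @param epochs List of `eeg_epoch` objects sharing one channel set.
#' @param cfg,log_transform,relative,denoise,channels Passed to
#'   [extract_features()].
#' @return A `feature_matrix`; labels are carried through when every epoch
#'   is labeled.
#' @export
extract_matrix <- function(epochs, cfg = wavelet_config(),
                           log_transform = TRUE, relative = FALSE,
                           denoise = TRUE, channels = default_channels()) {
  nm <- feature_names(channels, eeg_bands())
  if (length(epochs) == 0) {
    return(new_feature_matrix(matrix(numeric(0), 0, length(nm),
                                     dimnames = list(NULL, nm))))
  }
  rows <- lapply(epochs, extract_features, cfg = cfg,
                 log_transform = log_transform, relative = relative,
                 denoise = denoise, channels = channels)
  x <- do.call(rbind, lapply(rows, as.numeric))
  colnames(x) <- nm
  labs <- lapply(epochs, `[[`, "label")
  labeled <- !vapply(labs, is.null, TRUE)
  labels <- if (all(labeled)) unlist(labs) else NULL
  new_feature_matrix(x, labels)
}
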