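# Synthetic EEG generator: labeled epochs whose band-power profile varies
# monotonically with the attention class (beta/gamma rise, theta falls,
# following the theta/beta-ratio convention), plus broadband white noise.
# This provides the statistical structure the pipeline assumes without any
# recorded data; it makes no claim of physiological realism (no 1/f
# background, no artifacts).

#' Band-center test frequencies
#'
#' One sinusoid frequency per EEG band, placed inside each dyadic subband
#' (2, 6, 12, 24, 48 Hz) to minimize leakage across subband edges at
#' fs = 256, L = 5.
#' @return Named numeric vector of frequencies in Hz.
#' @export
band_center_freqs <- function() {
  c(delta = 2, theta = 6, alpha = 12, beta = 24, gamma = 48)
}

#' Per-class synthetic band-amplitude profile
#'
#' Default amplitudes (microvolts) per attention class and band. Beta and
#' gamma amplitudes increase strictly and theta decreases strictly with the
#' class, so classes are separable in band power; delta and alpha are held
#' flat. Broadband white noise (sd 5 uV) is added on every channel.
#'
#' @param noise_sd White-noise standard deviation in microvolts (default 5).
#' @param drift Amplitude of an optional linear low-frequency trend
#'   (default 0).
#' @param separation Multiplier on the class-dependent amplitude spread:
#'   0 collapses all classes onto the middle profile (chance-level data),
#'   1 is the default spread.
#' @return A `class_profile`: list with `amplitudes` (5 classes x 5 bands
#'   matrix), `noise_sd`, `drift`.
#' @export
class_profile <- function(noise_sd = 5, drift = 0, separation = 1) {
  if (noise_sd < 0) abort_fmt("noise_sd must be >= 0")
  cls <- 0:4
  base <- cbind(
    delta = rep(20, 5),
    theta = 12 - separation * 3 * (cls - 2),
    alpha = rep(10, 5),
    beta = 9 + separation * 2.5 * (cls - 2),
    gamma = 5 + separation * 1.5 * (cls - 2))
  if (any(base < 0)) abort_fmt("profile amplitudes must be >= 0; lower separation")
  rownames(base) <- attention_levels()
  structure(list(amplitudes = base, noise_sd = noise_sd, drift = drift),
            class = "class_profile")
}

#' Generate one labeled synthetic EEG epoch
#'
#' Each channel is a sum of band-center sinusoids with the class's
#' amplitudes and independent uniform random phases, plus white Gaussian
#' noise and an optional linear drift.
#'
#' @param cls Attention class (code 0..4 or name).
#' @param profile A [class_profile()].
#' @param fs Sampling rate in Hz (default 256).
#' @param seconds Epoch duration (default 1).
#' @param seed Integer seed; the epoch is a pure function of its arguments.
#' @param channels Channel names (default TP9, AF7, AF8, TP10).
#' @return A labeled `eeg_epoch`.
#' @export
generate_epoch <- function(cls, profile = class_profile(), fs = 256,
                           seconds = 1, seed = 1,
                           channels = default_channels()) {
  code <- as_attention_level(cls)
  stopifnot(length(code) == 1)
  n <- round(fs * seconds)
  t <- (seq_len(n) - 1) / fs
  freqs <- band_center_freqs()
  amps <- profile$amplitudes[code + 1, ]
  set.seed(seed)
  data <- matrix(0, nrow = n, ncol = length(channels))
  for (ch in seq_along(channels)) {
    phases <- runif(length(freqs), 0, 2 * pi)
    sig <- numeric(n)
    for (b in seq_along(freqs)) {
      sig <- sig + amps[b] * sin(2 * pi * freqs[b] * t + phases[b])
    }
    if (profile$noise_sd > 0) sig <- sig + rnorm(n, 0, profile$noise_sd)
    if (profile$drift != 0) sig <- sig + profile$drift * (t / seconds - 0.5)
    data[, ch] <- sig
  }
  colnames(data) <- channels
  new_epoch(data, fs, 0L, label = code)
}

#' Generate a balanced labeled synthetic dataset
#'
#' `n_per_class` epochs per attention class, deterministically shuffled.
#'
#' @param n_per_class Epochs per class (>= 1).
#' @inheritParams generate_epoch
#' @return List with `epochs` (list of labeled `eeg_epoch`) and `labels`
#'   (integer codes, aligned).
#' @export
generate_dataset <- function(n_per_class, profile = class_profile(),
                             fs = 256, seconds = 1, seed = 1,
                             channels = default_channels()) {
  if (!is_count(n_per_class)) abort_fmt("n_per_class must be a positive integer")
  epochs <- list()
  labels <- integer(0)
  for (code in 0:4) {
    for (i in seq_len(n_per_class)) {
      epochs[[length(epochs) + 1]] <-
        generate_epoch(code, profile, fs, seconds,
                       seed = derive_seed(seed, "epoch", code, i),
                       channels = channels)
      labels <- c(labels, code)
    }
  }
  set.seed(derive_seed(seed, "shuffle"))
  ord <- sample.int(length(epochs))
  list(epochs = epochs[ord], labels = labels[ord])
}

#' Sample an attention-level stream from a Markov chain
#'
#' @param transition_matrix 5x5 row-stochastic matrix over the attention
#'   levels (rows must sum to 1 within 1e-9).
#' @param length Stream length (>= 1).
#' @param seed Integer seed.
#' @param start Starting level (code or name, default `"medium"`).
#' @return Integer vector of attention codes of the requested length,
#'   beginning at `start`.
#' @export
generate_level_stream <- function(transition_matrix, length, seed = 1,
                                  start = "medium") {
  P <- as.matrix(transition_matrix)
  if (!all(dim(P) == c(5, 5)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9)) {
    abort_fmt("transition matrix must be 5x5 row-stochastic (rows sum to 1)")
  }
  if (!is_count(length)) abort_fmt("length must be a positive integer")
  set.seed(seed)
  out <- integer(length)
  out[1] <- as_attention_level(start)
  if (length > 1) {
    for (i in 2:length) {
      out[i] <- sample.int(5, 1, prob = P[out[i - 1] + 1, ]) - 1L
    }
  }
  out
}
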