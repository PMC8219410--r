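# Discrete wavelet multiresolution analysis (Mallat algorithm) with
# Daubechies filters, plus SURE soft-threshold denoising. The five-level
# db4 decomposition of a 256 Hz signal yields six subbands whose dyadic
# edges coincide with the canonical EEG bands (delta..gamma, plus a
# 64-128 Hz "noise" detail).

#' Daubechies scaling filter
#'
#' Constructs the orthonormal Daubechies scaling (lowpass) filter with `N`
#' vanishing moments (2N taps) by spectral factorization of the Daubechies
#' polynomial, selecting the minimum-phase root set. `N = 4` gives the db4
#' filter used throughout the attention pipeline.
#'
#' @param N Number of vanishing moments (1..10).
#' @return Numeric vector of 2N filter taps summing to sqrt(2).
#' @export
daubechies_scaling <- function(N) {
  if (!is_count(N) || N > 10) abort_fmt("N must be an integer in 1..10")
  if (N == 1) return(rep(1 / sqrt(2), 2))
  k <- 0:(N - 1)
  Pcoef <- choose(N - 1 + k, k)
  yr <- polyroot(Pcoef)
  zroots <- complex(0)
  for (y in yr) {
    b <- 2 - 4 * y
    disc <- sqrt(b^2 - 4 + 0i)
    z1 <- (b + disc) / 2
    z2 <- (b - disc) / 2
    zroots <- c(zroots, if (Mod(z1) < 1) z1 else z2)
  }
  coef <- 1
  for (i in seq_len(N)) coef <- convolve(coef, c(1, 1), type = "open")
  for (z0 in zroots) coef <- convolve(coef, rev(c(-z0, 1)), type = "open")
  h <- Re(coef)
  h <- h * sqrt(2) / sum(h)
  # standard ordering: largest taps toward the front (h starts 0.2304 for db4)
  if (abs(h[1]) < abs(h[length(h)])) h <- rev(h)
  h
}

# analysis/synthesis filter bank from a scaling filter (alternating flip)
wavelet_filters <- function(h) {
  L <- length(h)
  k <- seq_len(L) - 1
  dec_hi <- (-1)^k * h
  list(dec_lo = rev(h), dec_hi = dec_hi, rec_lo = h, rec_hi = rev(dec_hi),
       length = L)
}

#' Wavelet decomposition configuration
#'
#' @param basis Wavelet basis name, `"dbN"` with N in 1..10 (default
#'   `"db4"`, compactly supported and orthonormal).
#' @param levels Decomposition depth L (default 5, so a 256 Hz signal splits
#'   into six subbands aligned with the EEG bands).
#' @param fs Sampling rate in Hz (default 256).
#' @param boundary Extension rule for finite signals: `"symmetric"`
#'   (default) or `"periodic"` (exactly orthonormal; requires length
#'   divisible by 2^levels).
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(basis = "db4", levels = 5, fs = 256,
                           boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  if (!grepl("^db([1-9]|10)$", basis)) {
    abort_fmt("unsupported basis '%s' (supported: db1..db10)", basis)
  }
  if (!is_count(levels)) abort_fmt("levels must be a positive integer")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort_fmt("fs must be a positive number")
  }
  N <- as.integer(sub("^db", "", basis))
  structure(
    list(basis = basis, levels = as.integer(levels), fs = as.numeric(fs),
         boundary = boundary, filters = wavelet_filters(daubechies_scaling(N))),
    class = "wavelet_config"
  )
}

# full linear convolution, vectorized over filter taps
conv_full <- function(x, flt) {
  n <- length(x)
  L <- length(flt)
  y <- numeric(n + L - 1)
  for (j in seq_len(L)) {
    idx <- j:(j + n - 1)
    y[idx] <- y[idx] + flt[j] * x
  }
  y
}

# one analysis step: returns approximation and detail coefficients
dwt_step <- function(x, f, boundary) {
  n <- length(x)
  L <- f$length
  if (boundary == "symmetric") {
    if (n < L - 1) {
      abort_fmt("signal segment too short (%d) for filter length %d", n, L)
    }
    ext <- c(rev(x[seq_len(L - 1)]), x, rev(x)[seq_len(L - 1)])
    lo <- conv_full(ext, f$dec_lo)
    hi <- conv_full(ext, f$dec_hi)
    v <- seq(L, L + n + L - 2)             # valid region, length n + L - 1
    keep <- seq(2, n + L - 1, by = 2)
    list(a = lo[v][keep], d = hi[v][keep])
  } else {
    if (n %% 2 != 0) abort_fmt("periodic mode requires even length, got %d", n)
    half <- n / 2
    a <- numeric(half)
    d <- numeric(half)
    base <- 2 * (seq_len(half) - 1)
    for (m in seq_len(L)) {
      src <- (base + m - 1) %% n + 1
      a <- a + f$dec_lo[m] * x[src]
      d <- d + f$dec_hi[m] * x[src]
    }
    list(a = a, d = d)
  }
}

# one synthesis step; out_len is the length of the signal that produced (a, d)
idwt_step <- function(a, d, f, out_len, boundary) {
  L <- f$length
  if (boundary == "symmetric") {
    up <- function(cf) {
      u <- numeric(2 * length(cf))
      u[seq(1, length(u), by = 2)] <- cf
      u
    }
    y <- conv_full(up(a), f$rec_lo) + conv_full(up(d), f$rec_hi)
    crop <- L - 2
    y[(crop + 1):(crop + out_len)]
  } else {
    n <- out_len
    x <- numeric(n)
    base <- 2 * (seq_along(a) - 1)
    for (m in seq_len(L)) {
      dst <- (base + m - 1) %% n + 1
      contrib <- f$dec_lo[m] * a + f$dec_hi[m] * d
      # adjoint of the circular analysis operator
      for (i in seq_along(dst)) x[dst[i]] <- x[dst[i]] + contrib[i]
    }
    x
  }
}

min_signal_length <- function(cfg) 2L^cfg$levels + 1L

#' Multilevel wavelet decomposition
#'
#' Decomposes a signal into `levels` detail coefficient sets D1 (finest)
#' .. DL and one approximation set A_L, following the Mallat cascade. For
#' the default db4, L = 5, fs = 256 configuration this produces the six
#' subbands used for EEG band-power features.
#'
#' @param signal Numeric vector.
#' @param cfg A [wavelet_config()].
#' @return An object of class `subband_decomposition` with elements
#'   `detail` (list of L coefficient vectors, finest first), `approx`,
#'   `input_lengths`, `original_length`, and `config`.
#' @export
decompose <- function(signal, cfg = wavelet_config()) {
  if (!is.numeric(signal) || any(!is.finite(signal))) {
    abort_fmt("signal must be a finite numeric vector")
  }
  n <- length(signal)
  if (n < min_signal_length(cfg)) {
    abort_fmt("signal length %d too short for %d-level decomposition (minimum %d samples)",
              n, cfg$levels, min_signal_length(cfg))
  }
  if (cfg$boundary == "periodic" && n %% 2L^cfg$levels != 0) {
    abort_fmt("periodic boundary requires length divisible by 2^levels = %d",
              2L^cfg$levels)
  }
  detail <- vector("list", cfg$levels)
  input_lengths <- integer(cfg$levels)
  a <- signal
  for (j in seq_len(cfg$levels)) {
    input_lengths[j] <- length(a)
    st <- dwt_step(a, cfg$filters, cfg$boundary)
    detail[[j]] <- st$d
    a <- st$a
  }
  names(detail) <- paste0("D", seq_len(cfg$levels))
  structure(
    list(detail = detail, approx = a, input_lengths = input_lengths,
         original_length = n, config = cfg),
    class = "subband_decomposition"
  )
}

subband_ids <- function(cfg) c(paste0("D", seq_len(cfg$levels)), paste0("A", cfg$levels))

# inverse cascade from explicit coefficient sets
invert_mra <- function(dec, detail, approx) {
  cfg <- dec$config
  a <- approx
  for (j in rev(seq_len(cfg$levels))) {
    a <- idwt_step(a, detail[[j]], cfg$filters, dec$input_lengths[j],
                   cfg$boundary)
  }
  a
}

#' Reconstruct the full signal from a decomposition
#' @param dec A `subband_decomposition`.
#' @return Numeric vector of length `dec$original_length`.
#' @export
reconstruct_signal <- function(dec) {
  invert_mra(dec, dec$detail, dec$approx)
}

#' Reconstruct a single subband signal
#'
#' Inverse transform with every other subband zeroed, so the output is the
#' band-limited component of the original signal carried by `subband_id`.
#' Summing the reconstructions of all L+1 subbands recovers the signal.
#'
#' @param dec A `subband_decomposition`.
#' @param subband_id One of `"D1"`..`"DL"` or `"AL"` (e.g. `"A5"`).
#' @return Numeric vector of length `dec$original_length`.
#' @export
reconstruct_band <- function(dec, subband_id) {
  ids <- subband_ids(dec$config)
  if (!(length(subband_id) == 1 && subband_id %in% ids)) {
    abort_fmt("unknown subband '%s' (expected one of %s)",
              paste(subband_id, collapse = ","), paste(ids, collapse = ", "))
  }
  zero_detail <- lapply(dec$detail, function(d) numeric(length(d)))
  if (startsWith(subband_id, "D")) {
    j <- as.integer(sub("^D", "", subband_id))
    zero_detail[[j]] <- dec$detail[[j]]
    approx <- numeric(length(dec$approx))
  } else {
    approx <- dec$approx
  }
  invert_mra(dec, zero_detail, approx)
}

#' Subband-to-frequency-band map
#'
#' Each detail subband Dj covers the dyadic band (fs/2^(j+1), fs/2^j] and
#' the approximation A_L covers (0, fs/2^(L+1)]. For the canonical fs = 256,
#' L = 5 configuration the subbands align with the EEG bands: D1 is treated
#' as noise (64-128 Hz), D2 gamma (32-64), D3 beta (16-32), D4 alpha (8-16),
#' D5 theta (4-8), A5 delta (0-4). Other configurations yield the dyadic
#' edges with `NA` band names.
#'
#' @param cfg A [wavelet_config()].
#' @return data.frame with columns `subband`, `f_lo`, `f_hi`, `band`.
#' @export
band_map <- function(cfg = wavelet_config()) {
  L <- cfg$levels
  subband <- subband_ids(cfg)
  f_hi <- c(cfg$fs / 2^(seq_len(L)), cfg$fs / 2^(L + 1))
  f_lo <- c(cfg$fs / 2^(seq_len(L) + 1), 0)
  band <- rep(NA_character_, L + 1)
  if (cfg$fs == 256 && L == 5) {
    band <- c("noise", "gamma", "beta", "alpha", "theta", "delta")
  }
  data.frame(subband = subband, f_lo = f_lo, f_hi = f_hi, band = band,
             stringsAsFactors = FALSE)
}

#' Canonical EEG band names (low to high frequency)
#' @return Character vector delta, theta, alpha, beta, gamma.
#' @export
eeg_bands <- function() c("delta", "theta", "alpha", "beta", "gamma")

#' SURE adaptive threshold
#'
#' Selects the soft threshold minimizing Stein's unbiased risk estimate
#' over the candidate set of rescaled coefficient magnitudes (the
#' "rigrsure" rule). Coefficients are normalized by `noise_scale` before
#' risk evaluation; the returned threshold is on the normalized scale.
#' Ties in the risk curve resolve to the smaller threshold.
#'
#' @param coeffs Nonempty numeric vector of wavelet coefficients.
#' @param noise_scale Positive noise standard deviation estimate.
#' @return Threshold t with 0 <= t <= max(abs(coeffs))/noise_scale.
#' @export
sure_threshold <- function(coeffs, noise_scale = 1) {
  if (length(coeffs) == 0) abort_fmt("sure_threshold: empty coefficient set")
  if (!is.numeric(noise_scale) || length(noise_scale) != 1 || noise_scale <= 0) {
    abort_fmt("noise_scale must be a positive number")
  }
  c2 <- sort((coeffs / noise_scale)^2)
  n <- length(c2)
  k <- seq_len(n)
  risks <- (n - 2 * k + cumsum(c2) + (n - k) * c2) / n
  sqrt(c2[which.min(risks)])
}

#' Soft thresholding
#'
#' Shrinks each coefficient toward zero by `t`:
#' `sign(c) * max(abs(c) - t, 0)`.
#'
#' @param coeffs Numeric vector.
#' @param t Nonnegative threshold.
#' @return Thresholded vector of the same length.
#' @export
soft_threshold <- function(coeffs, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    abort_fmt("threshold must be a single nonnegative number")
  }
  sign(coeffs) * pmax(abs(coeffs) - t, 0)
}

#' SURE soft-threshold denoising of a decomposition
#'
#' Estimates the noise scale sigma once from the finest detail level
#' (median absolute coefficient / 0.6745) and soft-thresholds every detail
#' level at its own SURE threshold (times sigma). Approximation
#' coefficients are never touched. With a (near-)zero noise estimate the
#' decomposition is returned unchanged.
#'
#' @param dec A `subband_decomposition`.
#' @param sigma_rule Noise-scale estimator; only `"mad_d1"` is defined.
#' @return A denoised `subband_decomposition`.
#' @export
denoise <- function(dec, sigma_rule = c("mad_d1")) {
  sigma_rule <- match.arg(sigma_rule)
  sigma <- median(abs(dec$detail[[1]])) / 0.6745
  ref <- max(abs(unlist(dec$detail)), abs(dec$approx), 1)
  if (sigma <= ref * 1e-12) {
    return(dec)
  }
  for (j in seq_along(dec$detail)) {
    t_j <- sure_threshold(dec$detail[[j]], sigma)
    dec$detail[[j]] <- soft_threshold(dec$detail[[j]], t_j * sigma)
  }
  dec
}
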