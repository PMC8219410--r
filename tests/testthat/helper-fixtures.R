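# Shared fixtures and independent oracles. Everything is generated in code
# at test time; nothing is read from disk except files the tests write.

# ---- cached expensive fixtures (built once per test run) -------------------
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# default synthetic dataset at acceptance scale (n = 250), features extracted
default_features_250 <- function() {
  cached("feat250", function() {
    ds <- generate_dataset(50, seed = 2024)
    fm <- extract_matrix(ds$epochs)
    list(fm = fm, labels = fm$labels)
  })
}

small_features_100 <- function() {
  cached("feat100", function() {
    ds <- generate_dataset(20, seed = 77)
    fm <- extract_matrix(ds$epochs)
    list(fm = fm, labels = fm$labels)
  })
}

# well-separated Gaussian blob matrices (fast, no wavelet pipeline)
make_blobs <- function(n_per_class, sep = 3, p = 2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(0:4, function(cl) {
    matrix(rnorm(n_per_class * p, mean = sep * cl), ncol = p)
  }))
  list(x = x, y = rep(0:4, each = n_per_class))
}

# ---- signal helpers --------------------------------------------------------
make_sine <- function(freq, fs = 256, n = 256, amp = 1, phase = 0) {
  t <- (seq_len(n) - 1) / fs
  amp * sin(2 * pi * freq * t + phase)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / max(sum(b^2), 1e-300))

snr_db <- function(signal, noisy) {
  10 * log10(sum(signal^2) / sum((noisy - signal)^2))
}

# FFT band-energy oracle: fraction of spectral energy in (f_lo, f_hi]
fft_band_energy <- function(x, f_lo, f_hi, fs) {
  n <- length(x)
  spec <- abs(fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sel <- half & freqs > f_lo & freqs <= f_hi
  sum(spec[sel]) / sum(spec[half])
}

# brute-force SURE risk oracle: risk(t) = n - 2*#{|c|<=t} + sum(min(c^2, t^2))
sure_oracle <- function(coeffs, noise_scale = 1) {
  c_ <- coeffs / noise_scale
  cand <- sort(abs(c_))
  risks <- vapply(cand, function(t) {
    length(c_) - 2 * sum(abs(c_) <= t) + sum(pmin(c_^2, t^2))
  }, 0)
  cand[which.min(risks)]
}

# ---- brute-force CART oracle ----------------------------------------------
# Independent recursive reimplementation of the tree-growing rules: Gini
# impurity, midpoint thresholds, strict-improvement tie-breaks (lowest
# feature index, smallest threshold), stop on purity or min_samples_leaf,
# leaf ties toward the lower class. Considers ALL features (no sampling).
oracle_cart_predict <- function(x, y, x_new, min_samples_leaf = 1) {
  grow <- function(rows) {
    cnt <- tabulate(y[rows] + 1L, 5L)
    maj <- which.max(cnt) - 1L
    if (max(cnt) == length(rows) || length(rows) < 2 * min_samples_leaf) {
      return(list(leaf = TRUE, klass = maj))
    }
    best <- list(imp = Inf, f = NA, thr = NA)
    for (f in seq_len(ncol(x))) {
      v <- sort(unique(x[rows, f]))
      if (length(v) < 2) next
      for (i in seq_len(length(v) - 1)) {
        thr <- (v[i] + v[i + 1]) / 2
        l <- rows[x[rows, f] <= thr]
        r <- rows[x[rows, f] > thr]
        if (length(l) < min_samples_leaf || length(r) < min_samples_leaf) next
        gl <- tabulate(y[l] + 1L, 5L)
        gr <- tabulate(y[r] + 1L, 5L)
        imp <- (length(l) - sum(gl^2) / length(l)) +
               (length(r) - sum(gr^2) / length(r))
        if (imp < best$imp - 1e-12) best <- list(imp = imp, f = f, thr = thr)
      }
    }
    if (!is.finite(best$imp)) return(list(leaf = TRUE, klass = maj))
    list(leaf = FALSE, f = best$f, thr = best$thr,
         left = grow(rows[x[rows, best$f] <= best$thr]),
         right = grow(rows[x[rows, best$f] > best$thr]))
  }
  tree <- grow(seq_len(nrow(x)))
  classify <- function(node, row) {
    while (!node$leaf) {
      node <- if (x_new[row, node$f] <= node$thr) node$left else node$right
    }
    node$klass
  }
  vapply(seq_len(nrow(x_new)), function(r) classify(tree, r), 1L)
}

# ---- tiny EDF writer (generates the binary fixture at run time) ------------
pad <- function(s, w) formatC(as.character(s), width = -w)

write_test_edf <- function(path, data, fs, labels,
                           phys_min = -200, phys_max = 200) {
  ns <- ncol(data)
  spr <- fs                 # one-second records
  n_records <- nrow(data) / spr
  stopifnot(n_records == as.integer(n_records))
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44)
  wr(n_records, 8); wr("1", 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("test", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(phys_min, 8)
  for (i in seq_len(ns)) wr(phys_max, 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("none", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((data - phys_min) / gain + dig_min)
  for (r in seq_len(n_records)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(ns)) {
      writeBin(as.integer(dig[rows, j]), con, size = 2, endian = "little")
    }
  }
  # physical values actually encoded (after digital rounding)
  phys_min + (dig - dig_min) * gain
}

write_recording_csv <- function(path, data) {
  df <- as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
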