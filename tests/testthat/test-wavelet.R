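test_that("Daubechies filters are orthonormal with the right support", {
  for (N in c(1, 2, 4, 6, 8)) {
    h <- daubechies_scaling(N)
    expect_length(h, 2 * N)
    expect_equal(sum(h), sqrt(2), tolerance = 1e-12)
    expect_equal(sum(h^2), 1, tolerance = 1e-12)
    for (s in seq_len(N - 1)) {
      expect_equal(sum(h[seq_len(2 * N - 2 * s)] * h[-seq_len(2 * s)]), 0,
                   tolerance = 1e-10)
    }
  }
  expect_error(daubechies_scaling(11), "1..10")
})

test_that("decomposition yields L detail sets plus one approximation", {
  x <- rnorm(256)
  dec <- decompose(x, wavelet_config())
  expect_s3_class(dec, "subband_decomposition")
  expect_length(dec$detail, 5)
  expect_identical(names(dec$detail), paste0("D", 1:5))
  expect_equal(length(dec$detail) + 1L, 6L)  # six subbands
  expect_equal(dec$original_length, 256L)

  # db4 vanishing moments annihilate constants
  decc <- decompose(rep(3.7, 256))
  expect_lt(max(abs(unlist(decc$detail))), 1e-8)

  decz <- decompose(numeric(256))
  expect_true(all(unlist(decz$detail) == 0) && all(decz$approx == 0))

  expect_error(decompose(rnorm(20)), "minimum 33 samples")
  expect_error(decompose(c(rnorm(255), NA)), "finite")
})

test_that("perfect reconstruction holds across lengths and bases", {
  set.seed(42)
  for (n in c(64, 100, 257, 1024, 4096)) {
    x <- rnorm(n)
    dec <- decompose(x, wavelet_config())
    expect_lt(rel_l2(reconstruct_signal(dec), x), 1e-8)
    parts <- lapply(c(paste0("D", 1:5), "A5"),
                    function(id) reconstruct_band(dec, id))
    expect_lt(rel_l2(Reduce(`+`, parts), x), 1e-8)
  }
  # another basis and depth through the extensibility hook
  x <- rnorm(200)
  cfg <- wavelet_config(basis = "db6", levels = 3)
  expect_lt(rel_l2(reconstruct_signal(decompose(x, cfg)), x), 1e-8)
})

test_that("periodized transform conserves energy and reconstructs", {
  set.seed(43)
  for (n in c(64, 256, 1024, 4096)) {
    x <- rnorm(n)
    cfg <- wavelet_config(boundary = "periodic")
    dec <- decompose(x, cfg)
    e_coef <- sum(unlist(dec$detail)^2) + sum(dec$approx^2)
    expect_lt(abs(e_coef - sum(x^2)) / sum(x^2), 1e-6)
    expect_lt(rel_l2(reconstruct_signal(dec), x), 1e-8)
  }
  expect_error(decompose(rnorm(100), wavelet_config(boundary = "periodic")),
               "divisible")
})

test_that("band map carries the canonical EEG assignment at fs=256, L=5", {
  bm <- band_map(wavelet_config())
  expect_identical(bm$subband, c("D1", "D2", "D3", "D4", "D5", "A5"))
  expect_identical(bm$band, c("noise", "gamma", "beta", "alpha", "theta", "delta"))
  gamma <- bm[bm$band == "gamma", ]
  expect_equal(c(gamma$f_lo, gamma$f_hi), c(32, 64))
  delta <- bm[bm$band == "delta", ]
  expect_equal(c(delta$f_lo, delta$f_hi), c(0, 4))
  expect_equal(bm$f_hi[1], 128)

  # other configs: dyadic edges, no names
  bm2 <- band_map(wavelet_config(fs = 128, levels = 4))
  expect_equal(c(bm2$f_lo[1], bm2$f_hi[1]), c(32, 64))
  expect_true(all(is.na(bm2$band)))
})

test_that("subband reconstructions are band-localized (FFT oracle)", {
  cfg <- wavelet_config()
  bm <- band_map(cfg)
  # 40 Hz sits in D2/gamma and must carry most of the energy there
  dec <- decompose(make_sine(40), cfg)
  energies <- vapply(bm$subband,
                     function(id) sum(reconstruct_band(dec, id)^2), 0)
  expect_gte(energies[["D2"]] / sum(energies), 0.7)
  # FFT oracle agrees that D2's reconstruction lives mostly in 32-64 Hz
  expect_gt(fft_band_energy(reconstruct_band(dec, "D2"), 32, 64, 256), 0.7)

  # reconstructing A5 of a constant returns the constant
  expect_equal(reconstruct_band(decompose(rep(2, 256)), "A5"), rep(2, 256),
               tolerance = 1e-10)
  expect_error(reconstruct_band(dec, "D9"), "unknown subband")
})

test_that("SURE threshold minimizes the brute-force risk curve", {
  expect_equal(sure_threshold(numeric(64)), 0)
  expect_error(sure_threshold(numeric(0)), "empty")
  expect_error(sure_threshold(rnorm(10), noise_scale = 0), "positive")

  set.seed(1)
  c1 <- rnorm(1024)
  t1 <- sure_threshold(c1, 1)
  expect_gte(t1, 0)
  expect_lte(t1, sqrt(2 * log(1024)))
  expect_equal(t1, sure_oracle(c1), tolerance = 1e-12)

  # single large spike among near-zero coefficients: threshold stays below it
  spike <- c(rnorm(255, sd = 0.01), 10)
  ts <- sure_threshold(spike, 1)
  expect_lt(ts, 10)
  expect_equal(ts, sure_oracle(spike), tolerance = 1e-12)

  # oracle equivalence on assorted draws
  for (s in 1:5) {
    set.seed(100 + s)
    cc <- rnorm(200, sd = runif(1, 0.5, 3))
    expect_equal(sure_threshold(cc, 1.3), sure_oracle(cc, 1.3),
                 tolerance = 1e-12)
  }
})

test_that("soft thresholding shrinks toward zero", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(c(-0.5, 0.2, 1), 1), c(0, 0, 0))
  x <- rnorm(20)
  expect_identical(soft_threshold(x, 0), x)
  expect_equal(soft_threshold(c(-4, 4), 1.5), c(-2.5, 2.5))
  expect_error(soft_threshold(x, -1), "nonnegative")
})

test_that("denoising leaves clean signals alone and zero stays zero", {
  # a signal strictly inside the approximation space has no detail content
  base <- decompose(make_sine(2, n = 512))
  clean <- reconstruct_band(base, "A5")
  dec <- decompose(clean)
  den <- denoise(dec)
  expect_lt(rel_l2(reconstruct_signal(den), clean), 1e-6)

  decz <- denoise(decompose(numeric(256)))
  expect_true(all(reconstruct_signal(decz) == 0))
})

test_that("denoising improves SNR on noisy sinusoids", {
  set.seed(9)
  for (s in 1:5) {
    clean <- make_sine(10, n = 512, amp = 1)
    target_snr <- runif(1, 0, 10)
    noise_sd <- sqrt(sum(clean^2) / length(clean) / 10^(target_snr / 10))
    noisy <- clean + rnorm(512, sd = noise_sd)
    den <- reconstruct_signal(denoise(decompose(noisy)))
    expect_gt(snr_db(clean, den), snr_db(clean, noisy))
  }
})
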