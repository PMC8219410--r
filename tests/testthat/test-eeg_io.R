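test_that("CSV recordings parse with channel names and configured fs", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TP9,AF7,AF8,TP10", "1,2,3,4", "5,6,7,8", "9,10,11,12"), f)
  rec <- read_recording(f, fs = 256)
  expect_s3_class(rec, "eeg_recording")
  expect_identical(rec$channel_names, c("TP9", "AF7", "AF8", "TP10"))
  expect_equal(dim(rec$data), c(3, 4))
  expect_equal(rec$fs, 256)
  expect_equal(rec$data[, "AF8"], c(3, 7, 11))
})

test_that("malformed CSV input raises informative format errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TP9,AF7", "1,2", "3,oops"), f)
  expect_error(read_recording(f), "non-numeric value 'oops' in channel AF7, data row 2")

  writeLines(c("TP9,AF7", "1,2", "3"), f)
  expect_error(read_recording(f), "malformed CSV")

  expect_error(read_recording(file.path(tempdir(), "nope.csv")), "file not found")

  writeLines(c("TP9,TP9", "1,2"), f)
  expect_error(read_recording(f), "duplicate channel")

  writeLines(c("TP9,AF7", "1,2"), f)
  expect_error(read_recording(f, fs = -1), "sampling rate")
})

test_that("channel selection extracts the montage in order and is idempotent", {
  chans <- c("FP1", "TP9", "C3", "AF7", "O1", "AF8", "C4", "TP10")
  rec <- attneeg:::new_recording(matrix(seq_len(16), 2, 8), chans, 256)
  sel <- select_channels(rec)
  expect_identical(sel$channel_names, default_channels())
  expect_equal(sel$data[, "TP9"], rec$data[, "TP9"])
  # idempotent and order-preserving
  expect_identical(select_channels(sel), sel)
  # identity selection
  expect_identical(select_channels(rec, chans), rec)
  expect_error(select_channels(rec, "XX"), "unknown channel.*available")
})

test_that("epoching tiles the recording and drops the partial tail", {
  rec <- attneeg:::new_recording(
    matrix(rnorm(2560 * 4), ncol = 4), default_channels(), 256)
  eps <- epoch_recording(rec, 1.0, 0)
  expect_length(eps, 10)
  expect_true(all(vapply(eps, function(e) nrow(e$data), 1L) == 256))
  starts <- vapply(eps, `[[`, 1L, "start_index")
  expect_identical(starts, seq(0L, 2304L, by = 256L))

  rec2 <- attneeg:::new_recording(
    matrix(rnorm(640 * 4), ncol = 4), default_channels(), 256)
  expect_length(epoch_recording(rec2, 1.0), 2)

  rec3 <- attneeg:::new_recording(
    matrix(rnorm(128 * 4), ncol = 4), default_channels(), 256)
  expect_warning(eps3 <- epoch_recording(rec3, 1.0), "shorter than one epoch")
  expect_identical(eps3, list())
})

test_that("epoching conservation and overlap stride hold across sizes", {
  set.seed(5)
  for (n in sample(300:3000, 5)) {
    rec <- attneeg:::new_recording(matrix(rnorm(n * 2), ncol = 2),
                                   c("TP9", "AF7"), 256)
    eps <- epoch_recording(rec, 1.0, 0)
    total <- sum(vapply(eps, function(e) nrow(e$data), 1L))
    expect_lte(total, n)
    expect_lt(n - total, 256)
  }
  rec <- attneeg:::new_recording(matrix(rnorm(1024 * 2), ncol = 2),
                                 c("TP9", "AF7"), 256)
  eps <- epoch_recording(rec, 1.0, 0.5)
  starts <- vapply(eps, `[[`, 1L, "start_index")
  expect_true(all(diff(starts) == 128))
})

test_that("feature matrix CSV round trip is lossless and validates its header", {
  set.seed(7)
  x <- matrix(rnorm(5 * 20) * 10^runif(100, -6, 6), 5, 20)
  colnames(x) <- attneeg:::feature_names()
  fm <- attneeg:::new_feature_matrix(x, labels = c(0, 3, 4, 1, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_identical(back$labels, fm$labels)

  # unlabeled round trip
  fm2 <- attneeg:::new_feature_matrix(x)
  write_feature_matrix(fm2, f)
  expect_null(read_feature_matrix(f)$labels)

  # header mismatch: drop a feature column
  df <- utils::read.csv(f, check.names = FALSE)
  utils::write.csv(df[, -3], f, row.names = FALSE)
  expect_error(read_feature_matrix(f), "header mismatch.*missing")
})

test_that("minimal EDF reader recovers header rate and scaled signals", {
  set.seed(11)
  fs <- 128
  data <- cbind(make_sine(10, fs = fs, n = fs * 2, amp = 50),
                rnorm(fs * 2, sd = 20))
  f <- withr::local_tempfile(fileext = ".edf")
  encoded <- write_test_edf(f, data, fs, c("TP9", "AF7"))
  rec <- read_recording(f, format = "edf")
  expect_equal(rec$fs, fs)
  expect_identical(rec$channel_names, c("TP9", "AF7"))
  expect_equal(dim(rec$data), dim(data))
  # exact up to the 16-bit quantization the writer applied
  expect_equal(unname(rec$data), unname(encoded), tolerance = 1e-12)
  expect_lt(max(abs(rec$data - data)), (400 / 65535) * 0.51)
})
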