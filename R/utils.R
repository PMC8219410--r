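#' @keywords internal
"_PACKAGE"

#' @useDynLib attneeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats convolve median rnorm runif sd pt fft
#' @importFrom utils read.csv write.csv head
NULL

# Deterministic seed derivation: one master seed fans out into named
# substreams (per tree, per fold, per grid point) so that independent
# components never share an RNG stream. Lehmer-style mixing kept below
# 2^31 so the result is always a valid argument to set.seed().
.seed_mod <- 2147483647

derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- abs(as.numeric(seed)) %% .seed_mod
  keys <- list(...)
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k))
    for (ki in as.numeric(k)) {
      s <- (s * 48271 + (abs(ki) %% .seed_mod) + 1) %% .seed_mod
    }
  }
  as.integer(s)
}

# Order-insensitive rolling hash of an integer partition, used to log that
# classifier comparisons really saw byte-identical folds.
fold_hash <- function(folds) {
  h <- 0
  for (i in seq_along(folds)) {
    f <- sort(as.integer(folds[[i]]))
    for (v in f) h <- (h * 31 + v + i * 7919) %% .seed_mod
  }
  as.integer(h)
}

abort_fmt <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == as.integer(x)
}
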