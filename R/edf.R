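# Minimal EDF/EDF+ reader (16-bit integer records, ASCII header). Written
# in-package because no EDF reader is available in the supported
# dependency set; covers uniformly sampled continuous recordings, which is
# all the pipeline consumes.

edf_field <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", width)))
}

edf_num <- function(con, width, what) {
  v <- suppressWarnings(as.numeric(edf_field(con, width)))
  if (is.na(v)) abort_fmt("EDF header: invalid %s field", what)
  v
}

#' Read an EDF/EDF+ file
#'
#' Supports the standard 16-bit continuous EDF layout. All signals must
#' share one sampling rate (signals whose rate differs from the first are
#' rejected), and digital-to-physical scaling from the header is applied.
#'
#' @param path EDF file path.
#' @return An `eeg_recording` with `fs` taken from the header.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))

  edf_field(con, 8)                       # version
  edf_field(con, 80); edf_field(con, 80)  # patient / recording id
  edf_field(con, 8); edf_field(con, 8)    # start date / time
  edf_num(con, 8, "header bytes")
  edf_field(con, 44)                      # reserved
  n_records <- edf_num(con, 8, "record count")
  rec_dur <- edf_num(con, 8, "record duration")
  ns <- as.integer(edf_num(con, 4, "signal count"))
  if (ns < 1) abort_fmt("EDF file has no signals: %s", path)
  if (rec_dur <= 0) abort_fmt("EDF record duration must be positive")

  labels <- vapply(seq_len(ns), function(i) edf_field(con, 16), "")
  for (i in seq_len(ns)) edf_field(con, 80)     # transducer
  for (i in seq_len(ns)) edf_field(con, 8)      # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) edf_num(con, 8, "physical min"), 0)
  phys_max <- vapply(seq_len(ns), function(i) edf_num(con, 8, "physical max"), 0)
  dig_min <- vapply(seq_len(ns), function(i) edf_num(con, 8, "digital min"), 0)
  dig_max <- vapply(seq_len(ns), function(i) edf_num(con, 8, "digital max"), 0)
  for (i in seq_len(ns)) edf_field(con, 80)     # prefiltering
  spr <- vapply(seq_len(ns), function(i) edf_num(con, 8, "samples per record"), 0)
  for (i in seq_len(ns)) edf_field(con, 32)     # reserved

  if (any(spr != spr[1])) {
    abort_fmt("EDF signals have differing sampling rates (%s); not supported",
              paste(unique(spr / rec_dur), collapse = ", "))
  }
  fs <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  if (any(!is.finite(gain))) abort_fmt("EDF header: degenerate digital range")

  total <- n_records * sum(spr)
  raw <- readBin(con, "integer", n = total, size = 2, endian = "little",
                 signed = TRUE)
  if (length(raw) < total) abort_fmt("EDF data truncated: %s", path)

  data <- matrix(NA_real_, nrow = n_records * spr[1], ncol = ns)
  per_rec <- sum(spr)
  offs <- c(0, cumsum(spr))
  for (r in seq_len(n_records)) {
    base <- (r - 1) * per_rec
    rows <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (j in seq_len(ns)) {
      dig <- raw[(base + offs[j] + 1):(base + offs[j + 1])]
      data[rows, j] <- phys_min[j] + (dig - dig_min[j]) * gain[j]
    }
  }
  new_recording(data, labels, fs)
}
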