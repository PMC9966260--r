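# Minimal EDF (European Data Format) I/O: 16-bit integer samples with
# per-signal physical/digital scaling, enough for clinical-style exports of
# continuous EEG. Annotations, discontinuous records and EDF+ extras are not
# supported.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) .edf_pad(format(x, trim = TRUE, scientific = FALSE), width)

#' Read an EDF file
#'
#' @param path Path to an EDF file.
#' @return A list with \code{patient}, \code{recording}, \code{n_records},
#'   \code{record_duration_s}, and \code{signals}: a list per signal of
#'   \code{label}, \code{fs} and the numeric \code{data} vector in physical
#'   units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr(8)
  patient <- hdr(80)
  recording <- hdr(80)
  hdr(8); hdr(8)                               # start date / time
  header_bytes <- as.integer(hdr(8))
  hdr(44)                                      # reserved
  n_records <- as.integer(hdr(8))
  record_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  field <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels <- field(16)
  field(80); field(8)                          # transducer, physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                                    # prefiltering
  spr <- as.integer(field(8))                  # samples per record
  field(32)                                    # reserved
  stopifnot(header_bytes == 256L + 256L * ns)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- numeric(n_records * spr[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      data[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        phys_min[i] + (d - dig_min[i]) * gain[i]
    }
  }
  signals <- lapply(seq_len(ns), function(i) {
    list(label = labels[i], fs = spr[i] / record_dur, data = data[[i]])
  })
  list(patient = patient, recording = recording, n_records = n_records,
       record_duration_s = record_dur, signals = signals)
}

#' Write an EDF file
#'
#' Samples are quantized to 16-bit integers over each channel's physical
#' range, so the round trip is exact only to that quantization.
#'
#' @param path Output path.
#' @param samples Channels-by-time numeric matrix.
#' @param labels Character vector of signal labels (one per row).
#' @param fs Sampling rate in Hz, shared by all signals.
#' @param patient Patient identification string.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(path, samples, labels, fs, patient = "X") {
  samples <- as.matrix(samples)
  ns <- nrow(samples)
  n <- ncol(samples)
  stopifnot(length(labels) == ns, fs > 0)
  if (n %% fs == 0) {                          # 1-second records
    record_dur <- 1
    spr <- as.integer(fs)
    n_records <- as.integer(n / fs)
  } else {                                     # single record of full length
    record_dur <- n / fs
    spr <- n
    n_records <- 1L
  }
  rng <- apply(samples, 1, function(x) max(abs(x), 1e-9))
  phys_min <- -rng
  phys_max <- rng
  dig_min <- -32768
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeBin(charToRaw(s), con)
  put(.edf_pad("0", 8))
  put(.edf_pad(patient, 80))
  put(.edf_pad("qeeg export", 80))
  put(.edf_pad("01.01.00", 8))
  put(.edf_pad("00.00.00", 8))
  put(.edf_num(256L + 256L * ns, 8))
  put(.edf_pad("", 44))
  put(.edf_num(n_records, 8))
  put(.edf_num(record_dur, 8))
  put(.edf_num(ns, 4))
  putv <- function(vals, w) for (v in vals) put(.edf_pad(v, w))
  putv(labels, 16)
  putv(rep("", ns), 80)                        # transducer
  putv(rep("uV", ns), 8)                       # physical dimension
  putv(format(phys_min, trim = TRUE, digits = 7, scientific = FALSE), 8)
  putv(format(phys_max, trim = TRUE, digits = 7, scientific = FALSE), 8)
  putv(rep(dig_min, ns), 8)
  putv(rep(dig_max, ns), 8)
  putv(rep("", ns), 80)                        # prefiltering
  putv(rep(spr, ns), 8)
  putv(rep("", ns), 32)
  # re-read the header's printed physical range so scaling matches readers
  pm <- as.numeric(format(phys_min, trim = TRUE, digits = 7, scientific = FALSE))
  px <- as.numeric(format(phys_max, trim = TRUE, digits = 7, scientific = FALSE))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- samples[i, ((r - 1L) * spr + 1L):(r * spr)]
      d <- round((seg - pm[i]) / (px[i] - pm[i]) * (dig_max - dig_min) + dig_min)
      d <- pmin(pmax(d, dig_min), dig_max)
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
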