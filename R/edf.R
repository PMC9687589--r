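#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: 16-bit samples, one data record per
#' second, physical range taken from the data per channel. Sufficient for
#' round-tripping the synthetic cohorts produced by this package; not a general
#' EDF+ implementation (no annotations, no discontinuous records).
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path. Recordings are truncated to a whole number of
#'   seconds.
#' @param patient_id,recording_id Optional ASCII identification strings.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient_id = "X", recording_id = "X") {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- length(rec$channel_names)
  n_rec <- floor(ncol(rec$signal) / rec$fs)
  if (n_rec < 1) stop("recording shorter than one second")
  sig <- rec$signal[, seq_len(n_rec * rec$fs), drop = FALSE]

  pmin <- apply(sig, 1, min)
  pmax <- apply(sig, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(x, n) {
    x <- substr(as.character(x), 1, n)
    formatC(x, width = -n, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(pad(x, n), con, nchars = n, eos = NULL)

  wr("0", 8); wr(patient_id, 80); wr(recording_id, 80)
  wr("01.01.01", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (lab in rec$channel_names) wr(paste("EEG", lab), 16)
  for (i in seq_len(ns)) wr("", 80)                      # transducer
  for (i in seq_len(ns)) wr("uV", 8)                     # physical dimension
  for (i in seq_len(ns)) wr(sprintf("%.8g", pmin[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", pmax[i]), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                      # prefiltering
  for (i in seq_len(ns)) wr(rec$fs, 8)                   # samples per record
  for (i in seq_len(ns)) wr("", 32)                      # reserved

  gain <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rec$fs + 1):(r * rec$fs)
    for (i in seq_len(ns)) {
      dig <- round((sig[i, idx] - pmin[i]) * gain[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Counterpart of [write_edf()]. Assumes a uniform sampling rate across
#' channels and a whole-second record duration.
#'
#' @param path EDF file path.
#' @param channel_names Optional override for channel labels; by default labels
#'   are parsed from the header (an `"EEG "` prefix is stripped) and
#'   normalized.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channel_names = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))

  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                              # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  if (length(unique(spr)) != 1L) stop("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      sig[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (dig - dmin[i]) * scale[i] + pmin[i]
    }
  }
  labels <- sub("^EEG[ _]*", "", labels)
  if (is.null(channel_names)) channel_names <- normalize_channel_names(labels)
  eeg_recording(sig, fs, channel_names)
}
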