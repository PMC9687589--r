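#' Construct a raw EEG recording
#'
#' Container for a continuous multichannel recording in microvolts.
#'
#' @param signal Numeric matrix, channels x samples, in uV.
#' @param fs Sampling rate in Hz (128 or 256).
#' @param channel_names Character vector of channel labels (defaults to the
#'   19-channel 10-20 set); aliases are normalized.
#' @param meta Optional named list of subject metadata.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_names = channels_1020(),
                          meta = list()) {
  signal <- as.matrix(signal)
  channel_names <- normalize_channel_names(channel_names)
  if (nrow(signal) != length(channel_names)) {
    stop("signal has ", nrow(signal), " rows but ", length(channel_names),
         " channel names were given")
  }
  if (!fs %in% c(128, 256)) {
    stop("sampling rate must be 128 or 256 Hz, got ", fs)
  }
  if (anyDuplicated(channel_names)) stop("duplicated channel names")
  rownames(signal) <- channel_names
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$signal)
duration_s <- function(rec) ncol(rec$signal) / rec$fs

#' Construct an epoch set
#'
#' Fixed-length non-overlapping EEG segments with per-epoch quality flags.
#'
#' @param epochs 3-D numeric array, epoch x channel x sample, in uV.
#' @param fs Sampling rate in Hz.
#' @param epoch_length_s Epoch length in seconds; `dim(epochs)[3]` must equal
#'   `fs * epoch_length_s` exactly.
#' @param channel_names Channel labels (length `dim(epochs)[2]`).
#' @param kept Logical per-epoch keep flag (default all `TRUE`).
#' @param interpolation_log List (one entry per epoch) of repaired channel
#'   labels.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, fs, epoch_length_s,
                       channel_names, kept = NULL, interpolation_log = NULL) {
  stopifnot(length(dim(epochs)) == 3L)
  if (dim(epochs)[3] != fs * epoch_length_s) {
    stop("epoch sample count ", dim(epochs)[3], " != fs * epoch_length_s = ",
         fs * epoch_length_s)
  }
  if (dim(epochs)[2] != length(channel_names)) stop("channel name mismatch")
  if (is.null(kept)) kept <- rep(TRUE, dim(epochs)[1])
  if (is.null(interpolation_log)) {
    interpolation_log <- rep(list(character(0)), dim(epochs)[1])
  }
  dimnames(epochs) <- list(NULL, channel_names, NULL)
  structure(list(epochs = epochs, fs = fs, epoch_length_s = epoch_length_s,
                 channel_names = channel_names, kept = kept,
                 interpolation_log = interpolation_log),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d epochs (%d kept) x %d channels x %d samples @ %g Hz\n",
    dim(x$epochs)[1], sum(x$kept), dim(x$epochs)[2], dim(x$epochs)[3], x$fs))
  invisible(x)
}

n_epochs <- function(es) dim(es$epochs)[1]

# Epoch array restricted to kept epochs.
kept_epochs <- function(es) {
  es$epochs[es$kept, , , drop = FALSE]
}
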