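#' Band-pass filter a recording
#'
#' Symmetric linear-phase FIR band-pass filter (Hamming design) with a window
#' of 6.6 s, applied with group-delay compensation so the output is aligned
#' with the input (zero-phase equivalent). The filter length is
#' `round(6.6 * fs)` forced odd.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Pass-band edges in Hz (defaults 1 and 40).
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low_hz = 1, high_hz = 40) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * high_hz) {
    stop("sampling rate must exceed twice the upper edge (", 2 * high_hz, " Hz)")
  }
  L <- round(6.6 * rec$fs)
  if (L %% 2 == 0) L <- L + 1L
  if (n_samples(rec) < 3 * L) {
    stop(sprintf("recording too short for the 6.6 s filter: need >= %.1f s",
                 3 * L / rec$fs))
  }
  b <- design_bandpass(rec$fs, low_hz, high_hz)
  half <- (L - 1L) / 2L
  filt <- t(apply(rec$signal, 1, function(x) {
    y <- signal::fftfilt(b, c(x, numeric(half)))
    y[(half + 1L):(half + length(x))]
  }))
  eeg_recording(filt, rec$fs, rec$channel_names, rec$meta)
}

# Hamming-window FIR band-pass coefficients; DC response nulled exactly.
design_bandpass <- function(fs, low_hz, high_hz) {
  L <- round(6.6 * fs)
  if (L %% 2 == 0) L <- L + 1L
  b <- signal::fir1(L - 1L, c(low_hz, high_hz) / (fs / 2), type = "pass",
                    window = signal::hamming(L))
  b - mean(b)
}

#' Cut a recording into fixed-length epochs
#'
#' Optionally decimates the signal by an integer factor (safe here because the
#' pipeline has already low-passed at 40 Hz), then cuts it into
#' non-overlapping epochs; a trailing remainder shorter than one epoch is
#' discarded.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_length_s Epoch length in seconds.
#' @param target_fs Target sampling rate; must divide `rec$fs`.
#' @return An [eeg_epochs()].
#' @export
make_epochs <- function(rec, epoch_length_s, target_fs = rec$fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs %% target_fs != 0) {
    stop("target_fs (", target_fs, ") must divide the sampling rate (",
         rec$fs, ")")
  }
  spe <- epoch_length_s * target_fs
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_length_s * target_fs must be an integer")
  }
  spe <- as.integer(round(spe))
  sig <- rec$signal
  dec <- rec$fs %/% target_fs
  if (dec > 1L) sig <- sig[, seq(1L, ncol(sig), by = dec), drop = FALSE]
  n_ep <- floor(ncol(sig) / spe)
  if (n_ep < 1) {
    stop(sprintf("recording (%.1f s) shorter than one epoch (%g s)",
                 duration_s(rec), epoch_length_s))
  }
  ep <- array(0, dim = c(n_ep, nrow(sig), spe))
  for (e in seq_len(n_ep)) {
    ep[e, , ] <- sig[, ((e - 1L) * spe + 1L):(e * spe)]
  }
  eeg_epochs(ep, target_fs, epoch_length_s, rec$channel_names)
}

#' Flag flat epochs
#'
#' Drops (flags) epochs whose maximum peak-to-peak amplitude across all
#' channels is below `min_ptp_uV` (default 1 uV), removing zero-signal
#' segments.
#'
#' @param es An [eeg_epochs()].
#' @param min_ptp_uV Minimum peak-to-peak amplitude in uV.
#' @return The epoch set with its `kept` mask updated.
#' @export
drop_flat_epochs <- function(es, min_ptp_uV = 1) {
  stopifnot(inherits(es, "eeg_epochs"))
  ptp <- apply(es$epochs, 1, function(m) max(apply(m, 1, function(x)
    diff(range(x)))))
  es$kept <- es$kept & (ptp >= min_ptp_uV)
  es
}

# Column medians with fast paths for the small row counts CV folds produce.
col_medians <- function(m) {
  v <- nrow(m)
  if (v == 1L) return(m[1L, ])
  if (v == 2L) return(colMeans(m))
  if (v == 3L) return(colSums(m) - pmax(m[1L, ], m[2L, ], m[3L, ]) -
                        pmin(m[1L, ], m[2L, ], m[3L, ]))
  apply(m, 2, stats::median)
}

# Per-epoch, per-channel peak-to-peak amplitudes: epochs x channels matrix.
epoch_ptp <- function(es) {
  t(apply(es$epochs, 1, function(m) apply(m, 1, function(x) diff(range(x)))))
}

#' Clean epochs with cross-validated per-channel rejection thresholds
#'
#' A compact re-implementation of cross-validated artifact rejection: for each
#' channel a peak-to-peak rejection threshold is chosen from a log-spaced
#' candidate grid (40 values, 10-500 uV) by 10-fold cross-validation over
#' epochs: the CV error is the distance between the mean evoked signal of the
#' sub-threshold training epochs and the per-sample median of the validation
#' epochs, and the chosen threshold is the largest one within 5% of the
#' minimum error (so noise-level dips on artifact-free channels do not
#' reject epochs). Per epoch, channels exceeding their threshold are repaired by
#' inverse-distance-weighted interpolation from the 3 nearest clean channels
#' when at most `max_interp` channels are bad; otherwise the epoch is dropped.
#'
#' @param es An [eeg_epochs()] with monopolar 10-20 channels.
#' @param n_folds Number of CV folds (default 10); requires at least that many
#'   kept epochs.
#' @param max_interp Maximum number of repairable channels per epoch
#'   (default 3).
#' @param grid Optional threshold grid in uV.
#' @return The epoch set with updated `kept` mask and `interpolation_log`.
#'   Emits a warning when more than half of the epochs end up dropped.
#' @export
clean_epochs <- function(es, n_folds = 10, max_interp = 3, grid = NULL) {
  stopifnot(inherits(es, "eeg_epochs"))
  keep_idx <- which(es$kept)
  if (length(keep_idx) < n_folds) {
    stop("need at least ", n_folds, " kept epochs for ", n_folds, "-fold CV")
  }
  if (is.null(grid)) grid <- exp(seq(log(10), log(500), length.out = 40))
  ep <- es$epochs[keep_idx, , , drop = FALSE]
  n_ep <- dim(ep)[1]; n_ch <- dim(ep)[2]
  ptp <- t(apply(ep, 1, function(m) apply(m, 1, function(x) diff(range(x)))))

  folds <- rep(seq_len(n_folds), length.out = n_ep)   # deterministic folds
  thresholds <- numeric(n_ch)
  for (c_i in seq_len(n_ch)) {
    xc <- ep[, c_i, , drop = TRUE]
    if (is.null(dim(xc))) xc <- matrix(xc, nrow = n_ep)
    err <- numeric(length(grid))
    for (f in seq_len(n_folds)) {
      va <- folds == f
      med_va <- col_medians(xc[va, , drop = FALSE])
      comp <- which(!va)
      ord <- comp[order(ptp[comp, c_i])]
      cs <- xc[ord, , drop = FALSE]
      for (r in seq_len(length(ord))[-1]) cs[r, ] <- cs[r - 1, ] + cs[r, ]
      cnts <- findInterval(grid, sort(ptp[ord, c_i]))
      rmse_by_cnt <- c(Inf, vapply(seq_along(ord), function(cnt)
        sqrt(mean((cs[cnt, ] / cnt - med_va)^2)), numeric(1)))
      err <- err + rmse_by_cnt[cnts + 1L]
    }
    # parsimony rule: the largest threshold within 5% of the minimum CV
    # error; on artifact-free channels the error curve is flat above the
    # data's peak-to-peak range and noise-level dips must not reject epochs
    thresholds[c_i] <- grid[max(which(err <= min(err) * 1.05))]
  }

  pos <- electrode_positions()
  have_pos <- es$channel_names %in% rownames(pos)
  dmat <- as.matrix(stats::dist(pos[es$channel_names[have_pos], , drop = FALSE]))

  kept <- es$kept
  ilog <- es$interpolation_log
  for (k in seq_along(keep_idx)) {
    e <- keep_idx[k]
    bad <- which(ptp[k, ] > thresholds)
    if (length(bad) == 0L) next
    if (length(bad) > max_interp) {
      kept[e] <- FALSE
      next
    }
    good <- setdiff(seq_len(n_ch), bad)
    for (b in bad) {
      d <- dmat[es$channel_names[b], es$channel_names[good]]
      nn <- good[order(d)][seq_len(min(3L, length(good)))]
      w <- 1 / d[order(d)][seq_len(length(nn))]
      w <- w / sum(w)
      es$epochs[e, b, ] <- colSums(es$epochs[e, nn, , drop = TRUE] * w)
    }
    ilog[[e]] <- es$channel_names[bad]
  }
  dropped <- sum(es$kept) - sum(kept)
  if (dropped > 0.5 * length(keep_idx)) {
    warning(sprintf("epoch cleaning dropped %d of %d epochs (> 50%%)",
                    dropped, length(keep_idx)))
  }
  es$kept <- kept
  es$interpolation_log <- ilog
  attr(es, "rejection_thresholds") <- stats::setNames(thresholds,
                                                      es$channel_names)
  es
}

#' Derive a longitudinal bipolar montage
#'
#' Re-references monopolar epochs to the 18 longitudinal bipolar channels
#' (anode minus cathode, sample-wise).
#'
#' @param es An [eeg_epochs()] containing all 19 monopolar channels.
#' @param layout A [bipolar_montage()].
#' @return An [eeg_epochs()] with 18 bipolar channels; `kept` and the
#'   interpolation log carry over.
#' @export
to_bipolar <- function(es, layout = bipolar_montage()) {
  stopifnot(inherits(es, "eeg_epochs"))
  missing <- setdiff(unique(c(layout$pairs$anode, layout$pairs$cathode)),
                     es$channel_names)
  if (length(missing) > 0) {
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  }
  ai <- match(layout$pairs$anode, es$channel_names)
  ci <- match(layout$pairs$cathode, es$channel_names)
  bp <- es$epochs[, ai, , drop = FALSE] - es$epochs[, ci, , drop = FALSE]
  eeg_epochs(bp, es$fs, es$epoch_length_s, layout$pairs$label,
             kept = es$kept, interpolation_log = es$interpolation_log)
}
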