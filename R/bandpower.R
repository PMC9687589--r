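#' Welch power spectral density of one epoch
#'
#' Welch's method with 2 s Hamming segments and 50% overlap, one-sided, in
#' uV^2/Hz.
#'
#' @param epoch Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param seg_s Segment length in seconds (default 2).
#' @return A list with `freqs` (Hz) and `psd` (channels x bins, uV^2/Hz).
#' @export
welch_psd <- function(epoch, fs, seg_s = 2) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  seg <- round(seg_s * fs)
  if (n < seg) {
    stop("epoch (", n, " samples) shorter than one Welch segment (", seg, ")")
  }
  w <- signal::hamming(seg)
  starts <- seq(1L, n - seg + 1L, by = seg %/% 2L)
  nb <- seg %/% 2L + 1L
  psd <- matrix(0, nrow(epoch), nb)
  for (s in starts) {
    xw <- t(epoch[, s:(s + seg - 1L), drop = FALSE]) * w
    P <- Mod(stats::mvfft(xw))^2 / (fs * sum(w^2))
    P <- P[seq_len(nb), , drop = FALSE]
    P[2:(nb - 1L), ] <- 2 * P[2:(nb - 1L), ]      # one-sided
    psd <- psd + t(P)
  }
  psd <- psd / length(starts)
  list(freqs = seq(0, fs / 2, length.out = nb), psd = psd)
}

#' Correct a PSD for the 1/f background
#'
#' Multiplies each frequency bin's power by its frequency in Hz, flattening
#' the 1/f decay so all bands are represented on a comparable scale. The 0 Hz
#' bin is zeroed.
#'
#' @param psd A list as returned by [welch_psd()].
#' @return The corrected PSD (same structure).
#' @export
one_over_f_correct <- function(psd) {
  psd$psd <- sweep(psd$psd, 2, psd$freqs, `*`)
  psd
}

#' Relative band powers from a corrected PSD
#'
#' Integrates the PSD over each band (rectangle rule over bins with
#' `lo <= f < hi`) and divides by the total mass over the global band, so the
#' four fractions sum to 1 per channel.
#'
#' @param psd A (1/f-corrected) PSD list.
#' @param bands A [band_definitions()] tibble.
#' @return A channels x 4 matrix of fractions (delta, theta, alpha, beta);
#'   attribute `"total_abs_power"` holds the per-channel global-band mass in
#'   uV^2. Zero total power yields all-zero fractions with a warning.
#' @export
relative_band_power <- function(psd, bands = band_definitions("bandpower")) {
  df <- psd$freqs[2] - psd$freqs[1]
  g <- bands[bands$band == "global", ]
  total <- rowSums(psd$psd[, band_mask(psd$freqs, g$lo_hz, g$hi_hz),
                           drop = FALSE]) * df
  four <- bands[bands$band != "global", ]
  frac <- vapply(seq_len(nrow(four)), function(i) {
    m <- band_mask(psd$freqs, four$lo_hz[i], four$hi_hz[i])
    rowSums(psd$psd[, m, drop = FALSE]) * df
  }, numeric(nrow(psd$psd)))
  frac <- matrix(frac, nrow = nrow(psd$psd),
                 dimnames = list(NULL, four$band))
  zero <- total <= 0
  if (any(zero)) {
    warning("zero total power in ", sum(zero), " channel(s); fractions set to 0")
    frac[zero, ] <- 0
    frac[!zero, ] <- frac[!zero, , drop = FALSE] / total[!zero]
  } else {
    frac <- frac / total
  }
  attr(frac, "total_abs_power") <- total
  frac
}

# Population variance (divides by n, not n - 1).
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

#' Band powers, total power and the global band-power score per epoch
#'
#' Computes, for every epoch of an epoch set, the 1/f-corrected Welch band
#' powers, the channel-averaged relative band powers, the channel-averaged
#' total absolute power and the global band-power score
#' `GBP = TotalAbsolutePower / max(BandPowerVariance, 1e-12)`, where
#' `BandPowerVariance` is the population variance across the four
#' channel-averaged relative band powers. High GBP marks epochs with strong,
#' spectrally even activity.
#'
#' @param es An [eeg_epochs()].
#' @param bands A [band_definitions()] tibble.
#' @return A `band_power_set`: list with `rel` (epoch x channel x band array),
#'   `rel_avg` (epoch x band), `total_abs` (epoch x channel),
#'   `total_abs_avg`, `gbp` (per-epoch vectors), `bands`, and the epoch set's
#'   `kept` mask.
#' @export
band_power_set <- function(es, bands = band_definitions("bandpower")) {
  stopifnot(inherits(es, "eeg_epochs"))
  ne <- n_epochs(es); nc <- dim(es$epochs)[2]
  rel <- array(0, c(ne, nc, 4),
               dimnames = list(NULL, es$channel_names,
                               c("delta", "theta", "alpha", "beta")))
  tot <- matrix(0, ne, nc)
  for (e in seq_len(ne)) {
    p <- one_over_f_correct(welch_psd(es$epochs[e, , , drop = TRUE], es$fs))
    fr <- suppressWarnings(relative_band_power(p, bands))
    rel[e, , ] <- fr
    tot[e, ] <- attr(fr, "total_abs_power")
  }
  rel_avg <- apply(rel, c(1, 3), mean)
  gbp_v <- vapply(seq_len(ne), function(e) {
    tot_avg <- mean(tot[e, ])
    tot_avg / max(pop_var(rel_avg[e, ]), 1e-12)
  }, numeric(1))
  structure(list(rel = rel, rel_avg = rel_avg, total_abs = tot,
                 total_abs_avg = rowMeans(tot), gbp = gbp_v, bands = bands,
                 kept = es$kept),
            class = "band_power_set")
}

#' Global band-power score of one epoch
#'
#' @param band_set A [band_power_set()].
#' @param epoch_index Epoch number.
#' @return The scalar GBP.
#' @export
gbp <- function(band_set, epoch_index) {
  stopifnot(inherits(band_set, "band_power_set"))
  band_set$gbp[epoch_index]
}

#' Select the most informative epochs for a band
#'
#' Ranks kept epochs by channel-averaged relative power in the named band, or
#' by GBP for `"global"`, and returns the indices of the top `k` (ties broken
#' by earlier epoch index). When fewer than `k` epochs are available, all are
#' returned and the shortfall is recorded in attribute `"shortfall"`.
#'
#' @param es An [eeg_epochs()].
#' @param criterion One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"global"`.
#' @param k Number of epochs to select (default 50).
#' @param band_set Optional precomputed [band_power_set()] for `es`.
#' @return Integer epoch indices (into `es`), best first.
#' @export
select_top_epochs <- function(es, criterion, k = 50, band_set = NULL) {
  criterion <- match.arg(criterion,
                         c("delta", "theta", "alpha", "beta", "global"))
  if (is.null(band_set)) band_set <- band_power_set(es)
  keep <- which(band_set$kept)
  if (length(keep) < 1) stop("no kept epochs to select from")
  score <- if (criterion == "global") {
    band_set$gbp[keep]
  } else {
    band_set$rel_avg[keep, criterion]
  }
  ord <- keep[order(-score, keep)]      # ties -> earlier epoch index
  out <- ord[seq_len(min(k, length(ord)))]
  attr(out, "shortfall") <- max(0L, k - length(ord))
  out
}

#' Band-power feature block
#'
#' For each band (delta/theta/alpha/beta): the median and standard deviation,
#' over that band's selected epochs, of the group-mean relative band power,
#' per scalp group (32 features). For the global selection: median and
#' standard deviation of the group-mean total absolute power per group
#' (8 features). 40 features, named `bp_<band>_<group>_<stat>` and
#' `tap_<group>_<stat>`. Standard deviations are population SDs.
#'
#' @param es A bipolar [eeg_epochs()].
#' @param layout A [bipolar_montage()].
#' @param selections Named list (delta, theta, alpha, beta, global) of epoch
#'   indices from [select_top_epochs()].
#' @param band_set Optional precomputed [band_power_set()] for `es`.
#' @return Named numeric vector of 40 features.
#' @export
bandpower_features <- function(es, layout = bipolar_montage(), selections,
                               band_set = NULL) {
  stopifnot(all(c("delta", "theta", "alpha", "beta", "global") %in%
                  names(selections)))
  if (is.null(band_set)) band_set <- band_power_set(es)
  groups <- layout$groups
  out <- c()
  for (b in c("delta", "theta", "alpha", "beta")) {
    sel <- selections[[b]]
    for (g in names(groups)) {
      gi <- match(groups[[g]], es$channel_names)
      gm <- rowMeans(band_set$rel[sel, gi, b, drop = FALSE][, , 1])
      out[paste("bp", b, g, "median", sep = "_")] <- stats::median(gm)
      out[paste("bp", b, g, "sd", sep = "_")] <- pop_sd(gm)
    }
  }
  sel <- selections$global
  for (g in names(groups)) {
    gi <- match(groups[[g]], es$channel_names)
    gm <- rowMeans(band_set$total_abs[sel, gi, drop = FALSE])
    out[paste("tap", g, "median", sep = "_")] <- stats::median(gm)
    out[paste("tap", g, "sd", sep = "_")] <- pop_sd(gm)
  }
  out
}
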