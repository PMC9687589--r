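#' Specify a synthetic EEG cohort
#'
#' Bundles the generative parameters for a cohort of 19-channel resting-state
#' recordings with known ground-truth connectivity. Each subject is an order-8
#' multivariate autoregressive (MVAR) process whose off-diagonal coefficients
#' are restricted to within-scalp-group electrode pairs, superposed on
#' band-limited oscillators and 1/f background noise, with injected frontal
#' EOG transients and occasional flat segments. Subjects of the
#' "epileptic-like" class have the planted within-group directed coupling
#' scaled by `1 + effect_size`.
#'
#' @param n_subjects Number of subjects.
#' @param prevalence Fraction of epileptic-like subjects (per-subject Bernoulli).
#' @param effect_size Coupling gain multiplier delta >= 0 applied to the
#'   planted group's directed edges in the positive class.
#' @param duration_s Recording length in seconds (>= 60).
#' @param fs Sampling rate in Hz (128 or 256).
#' @param planted_group Scalp group carrying the class effect ("AL", "AR",
#'   "PL" or "PR").
#' @param eog_per_min Expected EOG (blink-like) transients per minute.
#' @param flat_prob Probability that a recording contains a short flat
#'   (zero-signal) segment.
#' @param clinician_sens,clinician_spec Sensitivity and specificity used to
#'   synthesize the clinician's "EEG result" label from the true diagnosis.
#'   Defaults follow the clinician benchmark performance of the
#'   first-EEG reading (0.660 / 0.629).
#' @param seed Integer seed; fixes the cohort bit-for-bit.
#' @return A `cohort_spec` list.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 4, duration_s = 60, fs = 128, seed = 1)
cohort_spec <- function(n_subjects, prevalence = 0.5, effect_size = 2,
                        duration_s = 120, fs = 256, planted_group = "AL",
                        eog_per_min = 4, flat_prob = 0.1,
                        clinician_sens = 0.660, clinician_spec = 0.629,
                        seed = 1) {
  stopifnot(prevalence >= 0, prevalence <= 1, fs >= 128, duration_s >= 60,
            effect_size >= 0,
            clinician_sens >= 0, clinician_sens <= 1,
            clinician_spec >= 0, clinician_spec <= 1,
            planted_group %in% c("AL", "AR", "PL", "PR"))
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 effect_size = effect_size, duration_s = duration_s, fs = fs,
                 planted_group = planted_group, eog_per_min = eog_per_min,
                 flat_prob = flat_prob, clinician_sens = clinician_sens,
                 clinician_spec = clinician_spec, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Evaluate code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Spectral radius of the companion matrix of an MVAR coefficient set.
# A: K x (K*p) matrix [A_1 | ... | A_p].
companion_spectral_radius <- function(A, p) {
  K <- nrow(A)
  comp <- matrix(0, K * p, K * p)
  comp[seq_len(K), ] <- A
  if (p > 1) {
    comp[(K + 1):(K * p), seq_len(K * (p - 1))] <- diag(K * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Base within-group MVAR coefficients shared by the whole cohort.
# Sparse off-diagonal entries (|a| <= 0.15) at random lags restricted to
# within-scalp-group electrode pairs, plus a smooth diagonal AR backbone;
# off-diagonals rescaled until the companion spectral radius is <= 0.95.
base_coupling <- function(spec) {
  K <- 19L; p <- 8L
  chans <- channels_1020()
  groups <- electrode_groups()
  with_seed(spec$seed * 7L + 13L, {
    A <- matrix(0, K, K * p)
    # diagonal AR(2) backbone per channel: broadband, strongly stable
    for (i in seq_len(K)) {
      A[i, i] <- 0.45
      A[i, K + i] <- -0.15
    }
    planted <- matrix(0, K, K, dimnames = list(chans, chans))
    for (g in names(groups)) {
      idx <- match(groups[[g]], chans)
      for (i in idx) for (j in idx) {
        if (i == j) next
        if (stats::runif(1) < 0.35) {
          lag <- sample.int(p, 1)
          a <- sample(c(-1, 1), 1) * stats::runif(1, 0.05, 0.15)
          A[i, (lag - 1) * K + j] <- a
          if (g == spec$planted_group) planted[i, j] <- a
        }
      }
    }
    # enforce stability margin on the base model
    repeat {
      if (companion_spectral_radius(A, p) <= 0.95) break
      off <- A
      for (i in seq_len(K)) for (m in seq_len(p)) off[i, (m - 1) * K + i] <- 0
      A <- (A - off) + off * 0.9
      planted <- planted * 0.9
    }
    list(A = A, p = p, planted = planted, channels = chans)
  })
}

# Apply the class-dependent gain to the planted group's directed edges.
class_coupling <- function(base, spec, positive) {
  A <- base$A
  if (positive && spec$effect_size > 0) {
    K <- nrow(A)
    idx <- which(base$planted != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      for (m in seq_len(base$p)) {
        A[i, (m - 1) * K + j] <- A[i, (m - 1) * K + j] * (1 + spec$effect_size)
      }
    }
  }
  A
}

# 1/f background noise via spectral shaping of white noise (power ~ 1/f);
# heavy-tailed base noise keeps the background identifiable for ICA.
one_over_f_noise <- function(n, fs) {
  w <- stats::rt(n, df = 5) / sqrt(5 / 3)
  W <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)                    # fold to two-sided frequencies
  shape <- ifelse(f > 0.5, 1 / sqrt(f), 1 / sqrt(0.5))
  shape[1] <- 0
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Biphasic low-frequency blink-like waveform, duration ~0.4 s.
eog_waveform <- function(fs) {
  t <- seq(0, 0.4, by = 1 / fs)
  sin(2 * pi * t / 0.4) * exp(-((t - 0.2) / 0.12)^2)
}

# Fixed frontal spatial loading for EOG transients (strongest at Fp1/Fp2).
eog_loading <- function() {
  pos <- electrode_positions()
  d <- sqrt((pos[, "x"])^2 + (pos[, "y"] - 1.15)^2)
  l <- exp(-2.2 * d)
  l / max(l)
}

#' Generate one synthetic subject's EEG
#'
#' Simulates a stable order-8 MVAR process over 19 channels, adds per-band
#' oscillators (delta/theta/alpha/beta sinusoids with random phases) and 1/f
#' background noise, injects frontal EOG transients, and with probability
#' `spec$flat_prob` zeroes a short segment. Positive-class subjects have the
#' planted group's directed coupling scaled by `1 + effect_size`.
#'
#' @param spec A [cohort_spec()].
#' @param class_label `"positive"` (epileptic-like) or `"negative"`.
#' @param seed Integer seed; the signal is a deterministic function of
#'   `(spec, class_label, seed)`.
#' @return A list with elements `recording` ([eeg_recording()]),
#'   `ground_truth_coupling` (19 x 19 matrix of planted directed gains, zero
#'   diagonal), and `flat_inserted` (logical).
#' @export
generate_subject_eeg <- function(spec, class_label = c("negative", "positive"),
                                 seed = spec$seed) {
  class_label <- match.arg(class_label)
  positive <- class_label == "positive"
  base <- base_coupling(spec)
  A <- class_coupling(base, spec, positive)
  rho <- companion_spectral_radius(A, base$p)
  if (rho >= 1) {
    stop(sprintf(paste0("unstable coupling specification: companion spectral ",
                        "radius %.3f >= 1 (reduce effect_size or base ",
                        "coupling)"), rho))
  }
  K <- 19L
  n <- round(spec$duration_s * spec$fs)
  burn <- 512L
  with_seed(seed, {
    # heavy-tailed innovations: EEG-like burstiness, and non-Gaussianity the
    # ICA stage needs to identify components
    innov <- matrix(stats::rt(K * (n + burn), df = 5) / sqrt(5 / 3), K)
    X <- simulate_mvar_cpp(A, base$p, innov, burn)
    X <- X / stats::sd(X) * 10                     # MVAR component ~10 uV rms

    tt <- seq_len(n) / spec$fs
    centers <- c(delta = 2.5, theta = 6, alpha = 10, beta = 20)
    amps <- c(delta = 4, theta = 3, alpha = 5, beta = 2)
    osc <- matrix(0, K, n)
    drift_sd <- pi / sqrt(2.5 * spec$fs)  # phase decorrelates over ~2.5 s
    for (b in names(centers)) {
      ph0 <- stats::runif(K, 0, 2 * pi)
      # narrowband stochastic rhythm: independent phase diffusion per channel
      # (real oscillations are not phase-locked over minutes), plus a second
      # harmonic locked to the fundamental as in arc-shaped cortical rhythms
      drift <- apply(matrix(stats::rnorm(K * n, 0, drift_sd), K), 1, cumsum)
      arg <- outer(rep(2 * pi * centers[[b]], K), tt) + ph0 + t(drift)
      osc <- osc + amps[[b]] * (sin(arg) + 0.35 * sin(2 * arg))
    }
    bg <- t(vapply(seq_len(K), function(i) one_over_f_noise(n, spec$fs) * 6,
                   numeric(n)))
    sig <- X + osc + bg

    # frontal EOG transients
    n_ev <- stats::rpois(1, spec$eog_per_min * spec$duration_s / 60)
    if (n_ev > 0) {
      wf <- eog_waveform(spec$fs)
      load <- eog_loading()
      starts <- sort(sample.int(max(1L, n - length(wf)), n_ev))
      for (s in starts) {
        idx <- s:(s + length(wf) - 1L)
        amp <- stats::runif(1, 80, 150)
        sig[, idx] <- sig[, idx] + amp * outer(load, wf)
      }
    }

    flat <- stats::runif(1) < spec$flat_prob
    if (flat) {
      flen <- round(5 * spec$fs)   # long enough to blank a whole 2.5 s epoch
      fstart <- sample.int(max(1L, n - flen), 1)
      sig[, fstart:(fstart + flen - 1L)] <- 0
    }

    gt <- base$planted * (if (positive) spec$effect_size else 0)
    diag(gt) <- 0
    list(recording = eeg_recording(sig, spec$fs,
                                   meta = list(class = class_label)),
         ground_truth_coupling = gt,
         flat_inserted = flat)
  })
}

#' Generate a synthetic cohort with metadata
#'
#' Draws per-subject diagnosis at the specified prevalence, synthesizes the
#' clinician "EEG result" label as a Bernoulli draw with `clinician_sens`
#' given an epileptic diagnosis and `clinician_spec` given a non-epileptic
#' one, assigns ages uniformly on 16-98 years and balanced sex, and (unless
#' `signals = FALSE`) simulates each subject's recording.
#'
#' Epileptic-like subjects receive a concrete subtype (focal lesional by
#' majority, with smaller generalized idiopathic and focal non-lesional
#' shares mirroring a first-seizure cohort's imbalance); all subtypes share
#' the same planted coupling effect.
#'
#' @param spec A [cohort_spec()] with `n_subjects >= 2`.
#' @param signals If `FALSE`, only the metadata table is generated (useful for
#'   large-sample checks of the clinician-label calibration).
#' @return A list of class `eeg_cohort` with elements `metadata` (tibble:
#'   subject_id, age, sex, diagnosis, epileptic, clinician_eeg_result, seed)
#'   and `recordings` (named list of [generate_subject_eeg()] results, or
#'   `NULL` when `signals = FALSE`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(3, duration_s = 60, fs = 128, seed = 2))
#' coh$metadata
generate_cohort <- function(spec, signals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 2) stop("a cohort needs at least 2 subjects")
  n <- spec$n_subjects
  meta <- with_seed(spec$seed, {
    epileptic <- stats::runif(n) < spec$prevalence
    subtype <- ifelse(epileptic,
                      sample(c("focal_lesional", "generalized_idiopathic",
                               "focal_nonlesional"), n, replace = TRUE,
                             prob = c(219, 24, 48) / 291),
                      "non_epileptic")
    clin <- ifelse(epileptic,
                   stats::runif(n) < spec$clinician_sens,
                   stats::runif(n) >= spec$clinician_spec)
    tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = round(stats::runif(n, 16, 98)),
      sex = sample(rep(c("M", "F"), length.out = n)),
      diagnosis = subtype,
      epileptic = epileptic,
      clinician_eeg_result = ifelse(clin, "abnormal", "normal"),
      seed = sample.int(.Machine$integer.max %/% 2L, n))
  })
  recs <- NULL
  if (signals) {
    recs <- lapply(seq_len(n), function(i) {
      generate_subject_eeg(spec,
                           if (meta$epileptic[i]) "positive" else "negative",
                           seed = meta$seed[i])
    })
    names(recs) <- meta$subject_id
  }
  structure(list(metadata = meta, recordings = recs, spec = spec),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d subjects (%d epileptic-like), %s\n",
              nrow(x$metadata), sum(x$metadata$epileptic),
              if (is.null(x$recordings)) "metadata only" else
                sprintf("%g s @ %g Hz", x$spec$duration_s, x$spec$fs)))
  invisible(x)
}

#' Write a cohort to disk as EDF files plus a metadata CSV
#'
#' @param cohort An `eeg_cohort` with recordings.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"), !is.null(cohort$recordings))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(cohort$recordings)) {
    write_edf(cohort$recordings[[id]]$recording,
              file.path(dir, paste0(id, ".edf")), patient_id = id)
  }
  utils::write.csv(
    cohort$metadata[, c("subject_id", "age", "sex", "diagnosis",
                        "clinician_eeg_result")],
    file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}
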