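# Discrete prolate spheroidal (Slepian) tapers via the tridiagonal
# eigenproblem; returns n x k matrix of unit-energy tapers. Cached per (n, nw).
dpss_tapers <- local({
  cache <- list()
  function(n, nw = 4, k = 2 * nw - 1) {
    key <- paste(n, nw, k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    W <- nw / n
    t0 <- seq_len(n) - 1
    md <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
    od <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
    Tm <- diag(md)
    Tm[cbind(seq_len(n - 1), 2:n)] <- od
    Tm[cbind(2:n, seq_len(n - 1))] <- od
    eg <- eigen(Tm, symmetric = TRUE)
    tap <- eg$vectors[, seq_len(k), drop = FALSE]
    tap <- sweep(tap, 2, sqrt(colSums(tap^2)), `/`)
    # fix sign: positive mean (even order) / positive initial slope (odd)
    for (j in seq_len(k)) {
      s <- sum(tap[, j])
      if (abs(s) > 1e-8) {
        if (s < 0) tap[, j] <- -tap[, j]
      } else if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
    }
    cache[[key]] <<- tap
    tap
  }
})

#' Multitaper cross-spectral statistics for a band
#'
#' Computes DPSS multitaper (time-bandwidth 4, 7 tapers) cross- and
#' auto-spectra for every channel pair on the epoch set's natural frequency
#' grid (0.4 Hz for 2.5 s epochs), restricted to `lo <= f < hi`, and
#' accumulates the two epoch averages the spectral estimators need:
#' `E[Sxy]` and `E[Sxy / |Sxy|]`.
#'
#' @param es An [eeg_epochs()] (typically 2.5 s epochs at 128 Hz).
#' @param band A row of [band_definitions()] (list/row with `lo_hz`, `hi_hz`)
#'   within 0 to Nyquist.
#' @param epochs Epoch indices to use (e.g. from [select_top_epochs()]);
#'   defaults to all kept epochs.
#' @param nw Time-bandwidth product (default 4).
#' @return A `spectral_estimate`: list with `freqs`, `mean_Sxy` and
#'   `mean_phase` (K x K x nbins complex arrays), `mean_Sxx` (K x nbins),
#'   `n_epochs`, `channel_names`.
#' @export
cross_spectra <- function(es, band, epochs = NULL, nw = 4) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (is.null(epochs)) epochs <- which(es$kept)
  if (length(epochs) < 2) stop("need at least 2 epochs for cross-spectra")
  ns <- dim(es$epochs)[3]
  K <- dim(es$epochs)[2]
  freqs_all <- seq(0, es$fs - es$fs / ns, by = es$fs / ns)
  sel_bins <- which(band_mask(freqs_all, band$lo_hz, band$hi_hz) &
                      freqs_all <= es$fs / 2)
  if (length(sel_bins) == 0) {
    stop(sprintf("band %g-%g Hz outside the spectral range", band$lo_hz,
                 band$hi_hz))
  }
  tap <- dpss_tapers(ns, nw)
  ntap <- ncol(tap)
  nb <- length(sel_bins)
  ii <- rep(seq_len(K), times = K)
  jj <- rep(seq_len(K), each = K)

  sum_Sxy <- matrix(0 + 0i, nb, K * K)
  sum_phase <- matrix(0 + 0i, nb, K * K)
  zero_bins <- 0L
  for (e in epochs) {
    x <- t(es$epochs[e, , , drop = TRUE])          # samples x K
    Se <- matrix(0 + 0i, nb, K * K)
    for (k in seq_len(ntap)) {
      Fk <- stats::mvfft(x * tap[, k])[sel_bins, , drop = FALSE]
      Se <- Se + Fk[, ii, drop = FALSE] * Conj(Fk[, jj, drop = FALSE])
    }
    Se <- Se / (ntap * es$fs)
    sum_Sxy <- sum_Sxy + Se
    a <- Mod(Se)
    ph <- Se
    nz <- a > 0
    ph[nz] <- ph[nz] / a[nz]
    ph[!nz] <- 0
    zero_bins <- zero_bins + sum(!nz)
    sum_phase <- sum_phase + ph
  }
  if (zero_bins > 0) {
    warning(zero_bins, " zero-magnitude cross-spectral bins contributed 0 to ",
            "the phase average")
  }
  ne <- length(epochs)
  mean_Sxy <- array(t(sum_Sxy / ne), c(K, K, nb))
  mean_phase <- array(t(sum_phase / ne), c(K, K, nb))
  mean_Sxx <- vapply(seq_len(nb), function(b) Re(diag(mean_Sxy[, , b])),
                     numeric(K))
  mean_Sxx <- matrix(mean_Sxx, K, nb)
  structure(list(freqs = freqs_all[sel_bins], mean_Sxy = mean_Sxy,
                 mean_phase = mean_phase, mean_Sxx = mean_Sxx,
                 n_epochs = ne, channel_names = es$channel_names,
                 band = band),
            class = "spectral_estimate")
}

# Connectivity matrix container.
conn_matrix <- function(values, estimator, band, directed,
                        channel_names = NULL) {
  diag(values) <- 0
  if (!is.null(channel_names)) dimnames(values) <- list(channel_names,
                                                        channel_names)
  structure(list(values = values, estimator = estimator, band = band,
                 directed = directed),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s, band %s, %s, %d channels\n", x$estimator,
              x$band, if (x$directed) "directed" else "undirected",
              nrow(x$values)))
  invisible(x)
}

#' Imaginary part of coherency
#'
#' `Im(E[Sxy]) / sqrt(E[Sxx] E[Syy])` per frequency bin, averaged over the
#' band's bins, stored as absolute value. Insensitive to zero-lag
#' (volume-conducted) coupling because self- and instantaneous coherency are
#' purely real.
#'
#' @param se A [cross_spectra()] estimate.
#' @return A `conn_matrix` (undirected, zero diagonal).
#' @export
imcoh <- function(se) {
  stopifnot(inherits(se, "spectral_estimate"))
  K <- dim(se$mean_Sxy)[1]; nb <- dim(se$mean_Sxy)[3]
  acc <- matrix(0, K, K)
  zero_power <- FALSE
  for (b in seq_len(nb)) {
    denom <- sqrt(outer(se$mean_Sxx[, b], se$mean_Sxx[, b]))
    num <- Im(se$mean_Sxy[, , b])
    v <- matrix(0, K, K)
    ok <- denom > 0
    v[ok] <- num[ok] / denom[ok]
    if (any(!ok)) zero_power <- TRUE
    acc <- acc + v
  }
  if (zero_power) warning("zero-power channel: IMCOH set to 0 there")
  conn_matrix(abs(acc / nb), "imcoh", band_name(se), FALSE, se$channel_names)
}

#' Phase-locking value
#'
#' `|E[Sxy / |Sxy|]|` per bin (epoch average of the unit-modulus
#' cross-spectral phase), averaged over the band's bins. 1 means a perfectly
#' consistent phase lag across epochs.
#'
#' @param se A [cross_spectra()] estimate.
#' @return A `conn_matrix` (undirected, zero diagonal).
#' @export
plv <- function(se) {
  stopifnot(inherits(se, "spectral_estimate"))
  K <- dim(se$mean_phase)[1]; nb <- dim(se$mean_phase)[3]
  acc <- matrix(0, K, K)
  for (b in seq_len(nb)) acc <- acc + Mod(se$mean_phase[, , b])
  conn_matrix(acc / nb, "plv", band_name(se), FALSE, se$channel_names)
}

band_name <- function(se) {
  if (!is.null(se$band$band)) as.character(se$band$band) else "band"
}

#' Mutual information between channel amplitude series
#'
#' Kraskov k-nearest-neighbour estimator (k = 3) of mutual information in
#' nats, computed per epoch and channel pair on the raw amplitude time
#' series; the per-pair subject value is the median over epochs (robust to
#' outlier epochs) and negative estimates are clipped to 0. Constant channels
#' get MI 0.
#'
#' @param es An [eeg_epochs()].
#' @param epochs Epoch indices (the global-band selection); defaults to all
#'   kept epochs.
#' @param k Number of neighbours (default 3).
#' @return A `conn_matrix` (undirected, zero diagonal), band `"global"`.
#' @export
mutual_information <- function(es, epochs = NULL, k = 3) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (is.null(epochs)) epochs <- which(es$kept)
  K <- dim(es$epochs)[2]
  per_epoch <- lapply(epochs, function(e)
    mi_ksg_matrix_cpp(es$epochs[e, , , drop = TRUE], k))
  vals <- apply(simplify2array(per_epoch), c(1, 2), stats::median)
  vals[vals < 0] <- 0
  conn_matrix(vals, "mi", "global", FALSE, es$channel_names)
}

#' Mutual information of a discrete joint distribution
#'
#' Direct evaluation of `sum p(x,y) log(p(x,y) / (p(x) p(y)))` in nats, used
#' as an exact reference for the continuous estimator.
#'
#' @param p_xy Matrix of joint probabilities (sums to 1).
#' @return MI in nats.
#' @export
mi_discrete <- function(p_xy) {
  stopifnot(all(p_xy >= 0), abs(sum(p_xy) - 1) < 1e-8)
  px <- rowSums(p_xy); py <- colSums(p_xy)
  s <- 0
  for (i in seq_len(nrow(p_xy))) for (j in seq_len(ncol(p_xy))) {
    p <- p_xy[i, j]
    if (p > 0) s <- s + p * log(p / (px[i] * py[j]))
  }
  s
}

#' Fit a multivariate autoregressive model across epochs
#'
#' Least-squares MVAR fit of order `order` pooled over the given epochs: the
#' normal equations are accumulated per epoch so no regression ever crosses
#' an epoch boundary. No ridge penalty. The innovation covariance is reported
#' from the pooled residuals.
#'
#' @param es An [eeg_epochs()].
#' @param epochs Epoch indices (the global-band selection); defaults to all
#'   kept epochs.
#' @param order Model order p (default 8).
#' @return An `mvar_model`: list with `A` (K x (K*order), blocks
#'   `[A1 | ... | Ap]`), `order`, `fs`, `sigma` (innovation covariance),
#'   `channel_names`, `spectral_radius`.
#' @export
fit_mvar <- function(es, epochs = NULL, order = 8) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (is.null(epochs)) epochs <- which(es$kept)
  K <- dim(es$epochs)[2]
  ns <- dim(es$epochs)[3]
  if (ns <= order) stop("epochs shorter than the model order")
  usable <- length(epochs) * (ns - order)
  if (usable < 10 * K * order) {
    stop("too few samples to fit a stable MVAR: have ", usable,
         ", need >= ", 10 * K * order, "; supply more epochs")
  }
  p <- order
  Szz <- matrix(0, K * p, K * p)
  Szy <- matrix(0, K * p, K)
  for (e in epochs) {
    x <- es$epochs[e, , , drop = TRUE]             # K x ns
    Y <- t(x[, (p + 1):ns, drop = FALSE])          # (ns-p) x K
    Z <- do.call(cbind, lapply(seq_len(p), function(m)
      t(x[, (p + 1 - m):(ns - m), drop = FALSE])))
    Szz <- Szz + crossprod(Z)
    Szy <- Szy + crossprod(Z, Y)
  }
  # Minimum-norm least-squares solution. The bipolar montage makes the
  # regressors structurally rank-deficient (the two longitudinal chains per
  # hemisphere telescope to the same end-to-end difference), so the normal
  # equations are solved through an eigendecomposition with a relative
  # tolerance rather than a plain inverse.
  eg <- eigen(Szz, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  if (sum(keep) < 1) {
    stop("rank-deficient normal equations in the MVAR fit; supply more epochs")
  }
  Ahat <- t(eg$vectors[, keep, drop = FALSE] %*%
              ((t(eg$vectors[, keep, drop = FALSE]) %*% Szy) / eg$values[keep]))
  # pooled residual covariance
  Sres <- matrix(0, K, K); nres <- 0L
  for (e in epochs) {
    x <- es$epochs[e, , , drop = TRUE]
    Y <- t(x[, (p + 1):ns, drop = FALSE])
    Z <- do.call(cbind, lapply(seq_len(p), function(m)
      t(x[, (p + 1 - m):(ns - m), drop = FALSE])))
    R <- Y - Z %*% t(Ahat)
    Sres <- Sres + crossprod(R)
    nres <- nres + nrow(R)
  }
  structure(list(A = Ahat, order = p, fs = es$fs, sigma = Sres / nres,
                 channel_names = es$channel_names,
                 spectral_radius = companion_spectral_radius(Ahat, p)),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> K = %d, order = %d, spectral radius %.3f\n",
              nrow(x$A), x$order, x$spectral_radius))
  invisible(x)
}

# Frequency-domain coefficient matrix Abar(f) = I - sum_m A_m e^{-i 2 pi f m / fs}
mvar_afreq <- function(model, f) {
  K <- nrow(model$A)
  Abar <- diag(K) + 0i
  for (m in seq_len(model$order)) {
    Abar <- Abar - model$A[, ((m - 1) * K + 1):(m * K)] *
      exp(-2i * pi * f * m / model$fs)
  }
  Abar
}

#' Partial directed coherence on a frequency grid
#'
#' Evaluates `PDC_ij(f) = |Abar_ij(f)| / sqrt(sum_k |Abar_kj(f)|^2)` on a
#' 0.25 Hz grid from 0.25 to 30 Hz. Column-normalized with respect to
#' outgoing flow: the squared entries of every column sum to 1 at each
#' frequency.
#'
#' @param model An [fit_mvar()] model.
#' @param freqs Frequency grid in Hz (default `seq(0.25, 30, by = 0.25)`).
#' @return Array `freq x K x K` of PDC values (source = column j, target =
#'   row i).
#' @export
pdc_bins <- function(model, freqs = seq(0.25, 30, by = 0.25)) {
  stopifnot(inherits(model, "mvar_model"))
  K <- nrow(model$A)
  out <- array(0, c(length(freqs), K, K))
  for (b in seq_along(freqs)) {
    Abar <- Mod(mvar_afreq(model, freqs[b]))
    cn <- sqrt(colSums(Abar^2))
    if (any(cn == 0)) stop("zero column norm in PDC at ", freqs[b], " Hz")
    out[b, , ] <- sweep(Abar, 2, cn, `/`)
  }
  out
}

#' Band-aggregated partial directed coherence
#'
#' Mean of the per-bin PDC over the band's bins (`lo <= f < hi` on the
#' 0.25 Hz grid), diagonal zeroed afterwards for graph use.
#'
#' @param model An [fit_mvar()] model.
#' @param band A row of `band_definitions("connectivity")`.
#' @return A directed `conn_matrix` (entry i,j = flow j -> i).
#' @export
pdc <- function(model, band) {
  freqs <- seq(0.25, 30, by = 0.25)
  m <- band_mask(freqs, band$lo_hz, band$hi_hz)
  if (!any(m)) stop("band outside the PDC frequency grid")
  bins <- pdc_bins(model, freqs[m])
  vals <- apply(bins, c(2, 3), mean)
  conn_matrix(vals, "pdc",
              if (!is.null(band$band)) as.character(band$band) else "band",
              TRUE, model$channel_names)
}

#' Summarize a connectivity matrix per scalp group
#'
#' For each scalp group, the mean and population standard deviation over the
#' within-group off-diagonal entries of the submatrix restricted to the
#' group's 5 channels: all 20 directed entries for a directed matrix, the 10
#' unique undirected entries otherwise.
#'
#' @param cm A `conn_matrix`.
#' @param layout A [bipolar_montage()].
#' @return A tibble with columns `group`, `mean`, `sd`.
#' @export
summarize_groups <- function(cm, layout = bipolar_montage()) {
  stopifnot(inherits(cm, "conn_matrix"))
  purrr::map_dfr(names(layout$groups), function(g) {
    idx <- match(layout$groups[[g]], rownames(cm$values))
    sub <- cm$values[idx, idx]
    vals <- if (cm$directed) {
      sub[row(sub) != col(sub)]
    } else {
      sub[upper.tri(sub)]
    }
    tibble::tibble(group = g, mean = mean(vals), sd = pop_sd(vals))
  })
}
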