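# FastICA-style independent component analysis (logcosh contrast, symmetric
# decorrelation) on a channels x samples matrix. Deterministic: the unmixing
# matrix is initialized from a fixed internal seed.
#
# Returns sources S (n_comp x samples), mixing (channels x n_comp spatial
# loadings), unmixing (n_comp x channels), the channel means, and the
# iteration count.
run_ica <- function(X, n_components = 15, maxit = 200, tol = 1e-3,
                    max_samples = 8192,
                    on_nonconvergence = c("warn", "error")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  K <- nrow(X)
  if (K < n_components) {
    stop("need at least ", n_components, " channels for ICA, got ", K)
  }
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(Xc)
  cv <- tcrossprod(Xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  d <- eg$values[seq_len(n_components)]
  if (any(d <= .Machine$double.eps * max(d))) {
    stop("rank-deficient data: cannot whiten to ", n_components, " components")
  }
  Kw <- diag(1 / sqrt(d)) %*% t(eg$vectors[, seq_len(n_components), drop = FALSE])
  Z <- Kw %*% Xc
  # the unmixing matrix is spatial: estimate it on a decimated subset of
  # time points (caps the per-iteration cost; the full sources are computed
  # from the final unmixing below)
  if (ncol(Z) > max_samples) {
    Z_full <- Z
    Z <- Z[, seq(1L, ncol(Z), by = ceiling(ncol(Z) / max_samples)),
           drop = FALSE]
  }
  n <- ncol(Z)

  W <- with_seed(20221114L, {
    matrix(stats::rnorm(n_components^2), n_components)
  })
  sym_decor <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values)) %*% t(s$vectors) %*% W
  }
  W <- sym_decor(W)
  # An ICA solution is only defined up to rotation inside subspaces whose
  # sources have rotation-invariant joint distributions (e.g. narrowband
  # quadrature pairs). There the per-component fixed-point residual keeps
  # oscillating while the spanned subspace is fixed, so convergence is:
  # every component's residual below tol, OR the residual-violating
  # components span a stable subspace (their projector stops changing).
  converged <- FALSE
  it <- 0L
  P_prev <- NULL
  sub_prev <- integer(0)
  stable_count <- 0L
  while (it < maxit) {
    it <- it + 1L
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- tcrossprod(G, Z) / n - diag(rowMeans(1 - G^2)) %*% W
    W1 <- sym_decor(W1)
    deltas <- abs(abs(diag(tcrossprod(W1, W))) - 1)
    delta <- max(deltas)
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
    sub <- which(deltas >= tol)
    # the projector test is only meaningful for a strict subset (for the
    # full set W W' = I makes it vacuous); require 3 consecutive stable
    # checks before accepting the orbit as converged
    if (length(sub) < n_components) {
      P <- crossprod(W[sub, , drop = FALSE])
      if (!is.null(P_prev) && identical(sub, sub_prev) &&
          max(abs(P - P_prev)) < 1e-4) {
        stable_count <- stable_count + 1L
        if (stable_count >= 3L) { converged <- TRUE; break }
      } else {
        stable_count <- 0L
      }
      P_prev <- P
      sub_prev <- sub
    } else {
      stable_count <- 0L
      P_prev <- NULL
      sub_prev <- integer(0)
    }
  }
  if (!converged) {
    msg <- sprintf("ICA did not converge: %d iterations, last delta %.2e (tol %g)",
                   it, delta, tol)
    if (on_nonconvergence == "error") stop(msg)
    warning(msg, "; using the final iterate")
  }
  unmixing <- W %*% Kw                       # n_comp x K
  mixing <- MASS_ginv(unmixing)              # K x n_comp spatial loadings
  list(sources = unmixing %*% Xc, mixing = mixing, unmixing = unmixing,
       means = mu, iterations = it)
}

# Moore-Penrose pseudoinverse via SVD (avoids a MASS dependency for one call).
MASS_ginv <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' EOG template for ICA-based artifact removal
#'
#' Spatial loading vectors of archetypal EOG (blink-like) components, used to
#' identify and drop matching independent components. The shipped default is a
#' synthetic template: it was derived by running ICA on one simulated subject
#' with strong planted EOG activity and keeping the components matching the
#' frontal blink topography (see `inst/extdata/eog_template_synthetic.csv`).
#'
#' @param components Optional channels x n matrix of loadings; rows must be
#'   named by 10-20 channel. Defaults to the shipped synthetic template.
#' @param correlation_threshold Absolute-correlation threshold above which a
#'   component is dropped (strict inequality). Default 0.8.
#' @return A list of class `ica_template`.
#' @export
eog_template <- function(components = NULL, correlation_threshold = 0.8) {
  stopifnot(correlation_threshold > 0, correlation_threshold < 1)
  if (is.null(components)) {
    path <- system.file("extdata", "eog_template_synthetic.csv",
                        package = "epifc")
    df <- utils::read.csv(path, row.names = 1)
    components <- as.matrix(df)
  }
  components <- components[channels_1020(), , drop = FALSE]
  if (ncol(components) < 1) stop("template needs at least one component")
  structure(list(components = components,
                 correlation_threshold = correlation_threshold),
            class = "ica_template")
}

#' Remove EOG artifacts by ICA template matching
#'
#' Decomposes the (already band-pass filtered) recording into `n_components`
#' independent components, compares each component's spatial loading with the
#' template loadings by absolute Pearson correlation, zeroes every component
#' whose correlation strictly exceeds the template threshold, and subtracts
#' the removed components from the signal. Matching is done on topographies,
#' not time courses, so it is independent of recording length.
#'
#' @param rec An [eeg_recording()].
#' @param template An [eog_template()].
#' @param n_components Number of ICA components (default 15).
#' @return The cleaned [eeg_recording()], with a `removal` report attached as
#'   attribute `"removal"`: a tibble of component index, best absolute
#'   template correlation, and whether it was removed.
#' @export
remove_eog <- function(rec, template = eog_template(), n_components = 15) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(template, "ica_template"))
  ica <- run_ica(rec$signal, n_components = n_components)
  tmpl <- template$components[rec$channel_names, , drop = FALSE]
  best_cor <- vapply(seq_len(n_components), function(j) {
    max(abs(stats::cor(ica$mixing[, j], tmpl)))
  }, numeric(1))
  removed <- best_cor > template$correlation_threshold
  clean <- rec$signal
  if (any(removed)) {
    clean <- clean - ica$mixing[, removed, drop = FALSE] %*%
      ica$sources[removed, , drop = FALSE]
  }
  out <- eeg_recording(clean, rec$fs, rec$channel_names, rec$meta)
  attr(out, "removal") <- tibble::tibble(
    component = seq_len(n_components),
    template_correlation = best_cor,
    removed = removed)
  out
}
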