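# Shared fixtures, built in code. Extraction results for the reference
# synthetic subject are cached across test files.

.fixtures <- new.env(parent = emptyenv())

# One reference subject (epileptic-like, planted AL coupling), 60 s at 128 Hz.
reference_subject <- function() {
  if (is.null(.fixtures$subject)) {
    spec <- cohort_spec(2, duration_s = 60, fs = 128, effect_size = 2,
                        flat_prob = 0, seed = 101)
    .fixtures$subject <- generate_subject_eeg(spec, "positive", seed = 2024)
  }
  .fixtures$subject
}

reference_features <- function() {
  if (is.null(.fixtures$features)) {
    .fixtures$features <-
      suppressWarnings(extract_subject_features(reference_subject()$recording))
  }
  .fixtures$features
}

# Two-channel epoch set built from a generator function returning list(x, y).
make_pair_epochs <- function(gen, n_epochs, ns = 320, fs = 128) {
  a <- array(0, c(n_epochs, 2, ns))
  for (e in seq_len(n_epochs)) {
    xy <- gen()
    a[e, 1, ] <- xy[[1]]
    a[e, 2, ] <- xy[[2]]
  }
  eeg_epochs(a, fs, ns / fs, c("x", "y"))
}

# Random feature table with an optional planted class difference.
synthetic_feature_table <- function(n, effect = 0, n_signal = 30, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  tax <- feature_taxonomy()$name
  withr_seed({
    X <- matrix(stats::rnorm(n * length(tax)), n,
                dimnames = list(NULL, tax))
    y <- rep(c(TRUE, FALSE), length.out = n)
    X[y, seq_len(n_signal)] <- X[y, seq_len(n_signal)] + effect
    dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)), label = y,
                     age = sample(20:90, n, replace = TRUE),
                     sex = sample(c("M", "F"), n, replace = TRUE),
                     clinician_eeg_result = sample(c("normal", "abnormal"), n,
                                                   replace = TRUE)),
      tibble::as_tibble(X))
  })
}
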