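test_that("band-pass filter suppresses DC and stop-band, passes mid-band", {
  fs <- 128
  t <- seq(1 / fs, 30, by = 1 / fs)
  mid <- 1500:2500
  dc <- eeg_recording(matrix(1, 19, length(t)), fs)
  y <- bandpass_filter(dc)$signal[1, mid]
  expect_lt(max(abs(y)), 1e-6)

  tone <- function(f) eeg_recording(
    matrix(rep(sin(2 * pi * f * t), each = 19), 19), fs)
  y10 <- bandpass_filter(tone(10))$signal[1, mid]
  expect_lt(abs(max(abs(y10)) - 1), 0.01)
  y60 <- bandpass_filter(tone(60))$signal[1, mid]
  expect_lt(max(abs(y60)), 0.01)

  short <- eeg_recording(matrix(0, 19, fs * 10), fs)
  expect_error(bandpass_filter(short), "too short")
})

test_that("epoch arithmetic floors trailing remainders and checks durations", {
  rec <- eeg_recording(matrix(rnorm(19 * 1020 * 256), 19), 256)
  es1 <- make_epochs(rec, 5, 256)
  expect_equal(n_epochs(es1), 204)
  expect_equal(dim(es1$epochs)[3], 1280)
  es2 <- make_epochs(rec, 2.5, 128)
  expect_equal(n_epochs(es2), 408)
  expect_equal(dim(es2$epochs)[3], 320)
  short <- eeg_recording(matrix(0, 19, 4 * 256), 256)
  expect_error(make_epochs(short, 5, 256), "shorter than one epoch")
  expect_error(make_epochs(rec, 5, 100), "must divide")
})

test_that("flat-epoch exclusion follows the max-across-channels rule", {
  a <- array(0, c(10, 19, 128))
  for (e in 1:7) a[e, , ] <- rnorm(19 * 128, sd = 5)
  es <- eeg_epochs(a, 128, 1, channels_1020())
  es <- drop_flat_epochs(es)
  expect_equal(sum(es$kept), 7)

  # one channel spanning 2 uV keeps the epoch
  b <- array(0, c(1, 19, 128))
  b[1, 5, ] <- seq(-1, 1, length.out = 128)
  es2 <- drop_flat_epochs(eeg_epochs(b, 128, 1, channels_1020()))
  expect_true(es2$kept[1])
})

test_that("bipolar derivation is exact subtraction and linear", {
  lay <- bipolar_montage()
  expect_equal(nrow(lay$pairs), 18)
  expect_true(all(vapply(lay$groups, length, integer(1)) == 5))
  expect_true("Fz-Cz" %in% lay$groups$AL && "Fz-Cz" %in% lay$groups$AR)
  expect_true("Cz-Pz" %in% lay$groups$PL && "Cz-Pz" %in% lay$groups$PR)

  set.seed(2)
  a <- array(rnorm(2 * 19 * 64), c(2, 19, 64))
  es <- eeg_epochs(a, 128, 0.5, channels_1020())
  bp <- to_bipolar(es, lay)
  for (r in seq_len(18)) {
    ai <- match(lay$pairs$anode[r], channels_1020())
    ci <- match(lay$pairs$cathode[r], channels_1020())
    expect_equal(bp$epochs[, r, ], a[, ai, ] - a[, ci, ])
  }
  # linearity
  es2 <- eeg_epochs(2 * a, 128, 0.5, channels_1020())
  bp2 <- to_bipolar(es2, lay)
  expect_equal(bp2$epochs, 2 * bp$epochs)
  # identical anode and cathode cancel
  a3 <- a
  a3[, match("F7", channels_1020()), ] <- a3[, match("Fp1", channels_1020()), ]
  bp3 <- to_bipolar(eeg_epochs(a3, 128, 0.5, channels_1020()), lay)
  expect_true(all(bp3$epochs[, 1, ] == 0))

  es_bad <- eeg_epochs(a[, 1:18, , drop = FALSE], 128, 0.5,
                       channels_1020()[1:18])
  expect_error(to_bipolar(es_bad, lay), "O2")
})

test_that("epoch cleaning repairs planted spikes and drops broad corruption", {
  set.seed(4)
  ns <- 256
  a <- array(rnorm(30 * 19 * ns, sd = 10), c(30, 19, ns))
  clean_es <- eeg_epochs(a, 128, 2, channels_1020())
  out <- clean_epochs(clean_es)
  expect_equal(sum(out$kept), 30)
  expect_equal(sum(lengths(out$interpolation_log)), 0)

  # one channel with 500 uV spikes in 5 epochs -> repaired, epochs kept
  b <- a
  for (e in 1:5) b[e, 7, seq(10, ns, by = 25)] <- 500
  es2 <- eeg_epochs(b, 128, 2, channels_1020())
  out2 <- clean_epochs(es2)
  expect_true(all(out2$kept[1:5]))
  for (e in 1:5) {
    expect_true(channels_1020()[7] %in% out2$interpolation_log[[e]])
    expect_lt(max(abs(out2$epochs[e, 7, ])), 100)
  }
  # untouched epochs are not modified
  expect_equal(out2$epochs[10, , ], b[10, , ], ignore_attr = TRUE)

  # an epoch with 10 corrupted channels exceeds max_interp and is dropped
  d <- a
  d[3, 1:10, ] <- d[3, 1:10, ] + 800
  out3 <- clean_epochs(eeg_epochs(d, 128, 2, channels_1020()))
  expect_false(out3$kept[3])
})

test_that("EOG template matching removes only matching components", {
  spec <- cohort_spec(2, duration_s = 60, fs = 128, eog_per_min = 15,
                      flat_prob = 0, seed = 5)
  rec <- bandpass_filter(generate_subject_eeg(spec, "negative",
                                              seed = 21)$recording)
  out <- suppressWarnings(remove_eog(rec))
  rep <- attr(out, "removal")
  expect_gte(sum(rep$removed), 1)
  expect_gt(max(rep$template_correlation), 0.9)

  # frontal low-frequency variance drops by at least half
  lowpow <- function(x) {
    p <- welch_psd(x, 128)
    sum(p$psd[, p$freqs < 4]) * (p$freqs[2] - p$freqs[1])
  }
  v0 <- lowpow(rec$signal["Fp1", , drop = FALSE])
  v1 <- lowpow(out$signal["Fp1", , drop = FALSE])
  expect_lt(v1 / v0, 0.5)

  # a template nothing matches leaves the signal unchanged
  flat_tmpl <- eog_template(matrix(rep(c(1, -1), length.out = 19),
                                   dimnames = list(channels_1020(), "t1")))
  out2 <- suppressWarnings(remove_eog(rec, flat_tmpl))
  if (!any(attr(out2, "removal")$removed)) {
    expect_lt(max(abs(out2$signal - rec$signal)), 1e-6)
  }
})
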