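conn_bands <- band_definitions("connectivity")
alpha_band <- conn_bands[conn_bands$band == "alpha", ]
global_band <- conn_bands[conn_bands$band == "global", ]

test_that("cross-spectra behave on identical, inverted and independent pairs", {
  set.seed(1)
  es <- make_pair_epochs(function() {
    x <- rnorm(320)
    list(x, x)
  }, 20)
  se <- cross_spectra(es, alpha_band)
  expect_equal(dim(se$mean_Sxy)[3], length(se$freqs))
  expect_true(all(abs(Im(se$mean_Sxy[1, 1, ])) < 1e-12))
  expect_equal(Re(se$mean_Sxy[1, 2, ]), se$mean_Sxx[1, ], tolerance = 1e-10)

  es_neg <- make_pair_epochs(function() {
    x <- rnorm(320)
    list(x, -x)
  }, 20)
  se_neg <- cross_spectra(es_neg, alpha_band)
  expect_equal(Re(se_neg$mean_Sxy[1, 2, ]), -se_neg$mean_Sxx[1, ],
               tolerance = 1e-10)

  es_ind <- make_pair_epochs(function() list(rnorm(320), rnorm(320)), 200)
  se_ind <- cross_spectra(es_ind, alpha_band)
  coh <- abs(se_ind$mean_Sxy[1, 2, ]) /
    sqrt(se_ind$mean_Sxx[1, ] * se_ind$mean_Sxx[2, ])
  expect_lt(max(coh), 0.15)
  expect_error(cross_spectra(es, list(lo_hz = 70, hi_hz = 80)),
               "outside the spectral range")
})

test_that("IMCOH is zero for identical signals and high for quadrature pairs", {
  set.seed(2)
  es_id <- make_pair_epochs(function() {
    x <- rnorm(320)
    list(x, x)
  }, 30)
  expect_equal(max(abs(imcoh(cross_spectra(es_id, alpha_band))$values)), 0)

  tt <- seq(1 / 128, 2.5, by = 1 / 128)
  es_q <- make_pair_epochs(function() {
    ph <- runif(1, 0, 2 * pi)
    list(sin(2 * pi * 10 * tt + ph) + 0.05 * rnorm(320),
         cos(2 * pi * 10 * tt + ph) + 0.05 * rnorm(320))
  }, 40)
  expect_gt(imcoh(cross_spectra(es_q, alpha_band))$values[1, 2], 0.9)

  es_ind <- make_pair_epochs(function() list(rnorm(320), rnorm(320)), 200)
  expect_lt(imcoh(cross_spectra(es_ind, alpha_band))$values[1, 2], 0.1)
})

test_that("PLV is 1 for constant phase lags and near the Rayleigh null otherwise", {
  set.seed(3)
  tt <- seq(1 / 128, 2.5, by = 1 / 128)
  es_lag <- make_pair_epochs(function() {
    ph <- runif(1, 0, 2 * pi)
    list(sin(2 * pi * 10 * tt + ph), sin(2 * pi * 10 * tt + ph + 1.1))
  }, 30)
  se <- cross_spectra(es_lag, alpha_band)
  expect_gt(plv(se)$values[1, 2], 0.999)

  es_id <- make_pair_epochs(function() {
    x <- rnorm(320)
    list(x, x)
  }, 30)
  expect_equal(plv(cross_spectra(es_id, alpha_band))$values[1, 2], 1)

  # E[PLV] under independence with E epochs is about sqrt(pi)/(2 sqrt(E))
  plvs <- replicate(6, {
    es0 <- make_pair_epochs(function() list(rnorm(320), rnorm(320)), 50)
    plv(cross_spectra(es0, alpha_band))$values[1, 2]
  })
  expect_lt(abs(mean(plvs) - sqrt(pi) / (2 * sqrt(50))), 0.05)
})

test_that("amplitude rescaling leaves PLV and IMCOH unchanged", {
  set.seed(4)
  a <- array(rnorm(20 * 2 * 320), c(20, 2, 320))
  es1 <- eeg_epochs(a, 128, 2.5, c("x", "y"))
  a2 <- a
  a2[, 1, ] <- 5 * a2[, 1, ]
  a2[, 2, ] <- 0.3 * a2[, 2, ]
  es2 <- eeg_epochs(a2, 128, 2.5, c("x", "y"))
  se1 <- cross_spectra(es1, alpha_band)
  se2 <- cross_spectra(es2, alpha_band)
  expect_equal(plv(se1)$values, plv(se2)$values, tolerance = 1e-10)
  expect_equal(imcoh(se1)$values, imcoh(se2)$values, tolerance = 1e-10)
})

test_that("mutual information matches discrete and Gaussian references", {
  expect_equal(mi_discrete(matrix(c(0.5, 0, 0, 0.5), 2)), log(2))
  expect_equal(mi_discrete(matrix(0.25, 2, 2)), 0)

  set.seed(5)
  rho <- 0.9
  ests <- replicate(5, {
    x <- rnorm(320)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(320)
    epifc:::mi_ksg_cpp(x, y, 3)
  })
  expect_lt(abs(mean(ests) - (-0.5 * log(1 - rho^2))), 0.1)

  # symmetry and the constant-channel rule on an epoch set
  a <- array(rnorm(6 * 3 * 320), c(6, 3, 320))
  a[, 3, ] <- 1
  es <- eeg_epochs(a, 128, 2.5, c("x", "y", "z"))
  cm <- mutual_information(es)
  expect_equal(cm$values, t(cm$values))
  expect_true(all(cm$values[, 3] == 0))
  expect_true(all(cm$values >= 0))
})

test_that("MVAR fitting recovers planted coefficients and is deterministic", {
  set.seed(6)
  A <- matrix(c(0.5, 0.4, 0, 0.5), 2)      # channel 1 drives channel 2
  innov <- matrix(rnorm(2 * 21000), 2)
  X <- epifc:::simulate_mvar_cpp(A, 1, innov, 1000)
  es <- eeg_epochs(array(X[, 1:20000], c(1, 2, 20000)), 128, 20000 / 128,
                   c("a", "b"))
  m <- fit_mvar(es, epochs = 1, order = 8)
  expect_lt(max(abs(m$A[, 1:2] - A)), 0.05)
  expect_lt(max(abs(m$A[, 3:16])), 0.05)
  m2 <- fit_mvar(es, epochs = 1, order = 8)
  expect_identical(m$A, m2$A)

  # white noise recovers the null model
  Xw <- matrix(rnorm(2 * 20000), 2)
  esw <- eeg_epochs(array(Xw, c(1, 2, 20000)), 128, 20000 / 128, c("a", "b"))
  mw <- fit_mvar(esw, epochs = 1, order = 8)
  expect_lt(max(abs(mw$A)), 0.05)

  tiny <- eeg_epochs(array(rnorm(2 * 2 * 64), c(2, 2, 64)), 128, 0.5,
                     c("a", "b"))
  expect_error(fit_mvar(tiny, order = 8), "too few samples")
})

test_that("PDC is column-normalized, directional, and vanishes when uncoupled", {
  set.seed(7)
  A <- matrix(c(0.5, 0.4, 0, 0.5), 2)
  innov <- matrix(rnorm(2 * 21000), 2)
  X <- epifc:::simulate_mvar_cpp(A, 1, innov, 1000)
  es <- eeg_epochs(array(X[, 1:20000], c(1, 2, 20000)), 128, 20000 / 128,
                   c("a", "b"))
  m <- fit_mvar(es, epochs = 1, order = 8)
  bins <- pdc_bins(m)
  norms <- apply(bins^2, c(1, 3), sum)
  expect_lt(max(abs(norms - 1)), 1e-10)

  p <- pdc(m, global_band)
  expect_gt(p$values[2, 1], 0.2)           # flow 1 -> 2
  expect_lt(p$values[1, 2], 0.05)          # no reverse flow
  # closed-form evaluation on the true coefficients agrees in direction
  mt <- structure(list(A = A, order = 1, fs = 128,
                       channel_names = c("a", "b")), class = "mvar_model")
  pt <- pdc(mt, global_band)
  expect_equal(p$values[2, 1], pt$values[2, 1], tolerance = 0.05)

  # uncoupled diagonal model has zero off-diagonal PDC
  md <- structure(list(A = diag(c(0.5, 0.3)), order = 1, fs = 128,
                       channel_names = c("a", "b")), class = "mvar_model")
  pd0 <- pdc(md, global_band)
  expect_equal(max(abs(pd0$values - diag(diag(pd0$values)))), 0)

  # band aggregation equals the mean of bin values
  freqs <- seq(0.25, 30, by = 0.25)
  mask <- freqs >= global_band$lo_hz & freqs < global_band$hi_hz
  vals <- apply(pdc_bins(m, freqs[mask]), c(2, 3), mean)
  diag(vals) <- 0
  expect_equal(p$values, vals, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("group summaries enumerate the correct off-diagonal entries", {
  lay <- bipolar_montage()
  ones <- matrix(1, 18, 18, dimnames = list(lay$pairs$label, lay$pairs$label))
  cm <- epifc:::conn_matrix(ones, "plv", "alpha", FALSE, lay$pairs$label)
  s <- summarize_groups(cm, lay)
  expect_equal(s$mean, rep(1, 4))
  expect_equal(s$sd, rep(0, 4))

  # block construction: AL entries 0.8, others 0.1
  v <- matrix(0.1, 18, 18, dimnames = list(lay$pairs$label, lay$pairs$label))
  al <- match(lay$groups$AL, lay$pairs$label)
  v[al, al] <- 0.8
  cm2 <- epifc:::conn_matrix(v, "imcoh", "alpha", FALSE, lay$pairs$label)
  s2 <- summarize_groups(cm2, lay)
  expect_equal(s2$mean[s2$group == "AL"], 0.8)
  # AR shares Fz-Cz with AL but its other pairs stay at 0.1
  expect_lt(s2$mean[s2$group == "PR"], 0.2)

  # random symmetric matrix equals a direct enumeration over unique pairs
  set.seed(8)
  r <- matrix(rnorm(18 * 18), 18)
  r <- abs(r + t(r)) / 2
  dimnames(r) <- list(lay$pairs$label, lay$pairs$label)
  cm3 <- epifc:::conn_matrix(r, "plv", "beta", FALSE, lay$pairs$label)
  s3 <- summarize_groups(cm3, lay)
  for (g in names(lay$groups)) {
    idx <- match(lay$groups[[g]], lay$pairs$label)
    vals <- c()
    for (i in 1:4) for (j in (i + 1):5) {
      vals <- c(vals, cm3$values[idx[i], idx[j]])
    }
    expect_equal(s3$mean[s3$group == g], mean(vals))
  }

  # directed matrices use all 20 ordered within-group entries
  dvals <- matrix(abs(rnorm(18 * 18)), 18,
                  dimnames = list(lay$pairs$label, lay$pairs$label))
  cmd <- epifc:::conn_matrix(dvals, "pdc", "alpha", TRUE, lay$pairs$label)
  sd_ <- summarize_groups(cmd, lay)
  idx <- match(lay$groups$AL, lay$pairs$label)
  sub <- cmd$values[idx, idx]
  expect_equal(sd_$mean[sd_$group == "AL"],
               mean(sub[row(sub) != col(sub)]))
})
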