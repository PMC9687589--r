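test_that("the stratified split preserves proportions and is disjoint", {
  tb <- synthetic_feature_table(100)
  sp <- split_train_test(tb, seed = 1)
  expect_equal(nrow(sp$train), 80)
  expect_equal(sum(sp$train$label), 40)
  expect_equal(sum(sp$test$label), 10)
  sp2 <- split_train_test(tb, seed = 1)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  for (s in 1:50) {
    spx <- split_train_test(tb, seed = s)
    expect_length(intersect(spx$train$subject_id, spx$test$subject_id), 0)
    expect_setequal(c(spx$train$subject_id, spx$test$subject_id),
                    tb$subject_id)
  }
  one_class <- tb; one_class$label <- TRUE
  expect_error(split_train_test(one_class), "both classes")
})

test_that("z-score normalization uses training population statistics", {
  m <- matrix(c(2, 4, 6), 3, 1, dimnames = list(NULL, "f"))
  nz <- normalize_features(m, matrix(4, 1, 1, dimnames = list(NULL, "f")))
  expect_equal(as.numeric(nz$train), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-6)
  expect_equal(as.numeric(nz$test), 0)     # test value equal to train mean

  m2 <- cbind(m, g = c(5, 5, 5))
  expect_warning(nz2 <- normalize_features(m2, m2), "zero-variance")
  expect_equal(colnames(nz2$train), "f")
  expect_equal(colnames(nz2$test), "f")
  expect_equal(nz2$dropped, "g")
})

test_that("ANOVA selection ranks a strongly separated feature first", {
  # textbook two-group F on a 6-subject toy table
  x <- matrix(c(1, 2, 3, 7, 8, 9,
                5, 5, 5, 5, 5, 6), 6, 2)
  y <- rep(c(FALSE, TRUE), each = 3)
  g <- factor(y)
  f_ref <- vapply(1:2, function(j)
    summary(stats::aov(x[, j] ~ g))[[1]]$`F value`[1], numeric(1))
  n1 <- 3; n0 <- 3
  expect_equal(anova_kbest(x, y, 1), 1L)
  # own F equals aov on both features
  ssb <- function(j) {
    m1 <- mean(x[y, j]); m0 <- mean(x[!y, j]); gm <- mean(x[, j])
    (3 * (m1 - gm)^2 + 3 * (m0 - gm)^2) /
      ((sum((x[y, j] - m1)^2) + sum((x[!y, j] - m0)^2)) / 4)
  }
  expect_equal(ssb(1), f_ref[1])
  expect_equal(ssb(2), f_ref[2])

  set.seed(1)
  hits <- replicate(40, {
    X <- matrix(rnorm(40 * 20), 40)
    yy <- rep(c(TRUE, FALSE), 20)
    X[yy, 7] <- X[yy, 7] + 3
    anova_kbest(X, yy, 1) == 7
  })
  expect_gt(mean(hits), 0.95)
  X <- matrix(rnorm(20 * 5), 20)
  expect_setequal(anova_kbest(X, rep(c(TRUE, FALSE), 10), 5), 1:5)
  expect_error(anova_kbest(X, rep(c(TRUE, FALSE), 10), 9), "exceeds")
})

test_that("PCA reduction reconstructs and orders variance", {
  set.seed(2)
  base <- matrix(rnorm(30 * 2), 30)
  X <- base %*% matrix(rnorm(2 * 10), 2)     # exactly rank 2
  pc <- pca_reduce(X, X, 2)
  recon <- pc$train %*% t(pc$rotation)
  recon <- sweep(recon, 2, -pc$center)
  expect_lt(max(abs(recon - X)), 1e-8)
  X2 <- matrix(rnorm(30 * 6), 30)
  pc2 <- pca_reduce(X2, NULL, 6)
  expect_true(all(diff(pc2$sdev) <= 1e-12))
  roundtrip <- sweep(pc2$train %*% t(pc2$rotation), 2, -pc2$center)
  expect_lt(max(abs(roundtrip - X2)), 1e-8)
})

test_that("correlation pruning is deterministic with a strict threshold", {
  set.seed(3)
  x <- matrix(rnorm(50 * 4), 50)
  x <- cbind(x, x[, 2])                      # exact duplicate of column 2
  keep <- correlation_prune(x, 0.92)
  expect_true(2 %in% keep)
  expect_false(5 %in% keep)

  orth <- qr.Q(qr(matrix(rnorm(20 * 5), 20)))
  expect_equal(correlation_prune(orth, 0.92), 1:5)

  # |r| exactly at the threshold keeps both (strict inequality)
  a <- rnorm(80)
  b <- rnorm(80)
  b <- as.numeric(scale(residuals(lm(b ~ a))))
  av <- as.numeric(scale(a))
  y <- 0.92 * av + sqrt(1 - 0.92^2) * b
  thr <- abs(cor(cbind(av, y)))[1, 2]      # approximately 0.92 by design
  expect_equal(thr, 0.92, tolerance = 1e-12)
  expect_equal(correlation_prune(cbind(av, y), thr), 1:2)
  expect_equal(correlation_prune(cbind(av, y), thr - 1e-9), 1L)
})

test_that("grid-search CV training is leak-free and deterministic", {
  tb <- synthetic_feature_table(80, effect = 1.5, seed = 4)
  sp <- split_train_test(tb, seed = 2)
  m1 <- train_model(sp$train, model = "svm", reduction = "pca", seed = 5)
  m2 <- train_model(sp$train, model = "svm", reduction = "pca", seed = 5)
  expect_identical(m1$best, m2$best)
  expect_equal(m1$cv_report$auc, m2$cv_report$auc)
  expect_gt(mean(m1$cv_report$auc), 0.9)    # separable features

  # leakage audit: corrupting test labels never changes the fitted model
  test_corrupt <- sp$test
  test_corrupt$label <- !test_corrupt$label
  s1 <- predict(m1, sp$test)
  s2 <- predict(m1, test_corrupt)
  expect_identical(s1, s2)

  # a fold with one class errors
  bad <- sp$train
  bad$label <- c(TRUE, rep(FALSE, nrow(bad) - 1))
  expect_error(train_model(bad, model = "svm", reduction = "pca", seed = 1),
               "single class")
})

test_that("evaluation reproduces hand-computed confusion metrics", {
  # TP=3 TN=2 FP=1 FN=2 -> acc 0.625, sens 0.6, spec 0.6667
  cm <- c(TP = 3, TN = 2, FP = 1, FN = 2)
  met <- epifc:::metrics_from_confusion(cm)
  expect_equal(met$accuracy, 0.625)
  expect_equal(met$sensitivity, 0.6)
  expect_equal(met$specificity, 2 / 3)

  tb <- synthetic_feature_table(60, effect = 3, seed = 6)
  sp <- split_train_test(tb, seed = 3)
  m <- train_model(sp$train, model = "logreg", reduction = "anova",
                   reduction_grid = 25, seed = 7)
  ev <- evaluate_model(m, sp$test)
  expect_equal(ev$auc, 1)                    # fully separable
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(sum(ev$confusion), nrow(sp$test))
  expect_true(ev$surrogate_q95 <= 1 && length(ev$surrogate_auc) == 100)

  one <- sp$test
  one$label <- rep(TRUE, nrow(one))
  expect_error(evaluate_model(m, one), "single class")
})

test_that("the Youden cut-off resolves ties toward the lower threshold", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  s <- c(0.9, 0.8, 0.2, 0.1)
  expect_equal(epifc:::youden_cutoff(y, s), 0.8)
  # scores identical to labels give a diagonal confusion matrix
  cut <- epifc:::youden_cutoff(y, as.numeric(y))
  cm <- epifc:::confusion_counts(y, as.numeric(y) >= cut)
  expect_equal(unname(cm[c("FP", "FN")]), c(0, 0))
})

test_that("subgroup tasks partition by sex and age with boundary at 50", {
  tb <- synthetic_feature_table(140, effect = 2, seed = 8)
  tb$age[1] <- 50                            # boundary goes to the old group
  res <- suppressWarnings(subgroup_tasks(tb, seed = 1))
  expect_named(res, c("male", "female", "young", "old"))
  n_m <- sum(tb$sex == "M"); n_f <- sum(tb$sex == "F")
  expect_equal(n_m + n_f, nrow(tb))
  all_male <- tb[tb$sex == "M", ]
  expect_warning(r2 <- subgroup_tasks(all_male, seed = 1), "skipped")
  expect_null(r2$female)
})

test_that("clinician fusion follows the truth tables and monotonicity", {
  expect_false(fuse_with_clinician(1, 0, TRUE, "AND")$fused)
  expect_true(fuse_with_clinician(1, 0, TRUE, "OR")$fused)

  # clinician identical to model leaves metrics unchanged
  set.seed(9)
  truth <- rep(c(TRUE, FALSE), 10)
  pred <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  for (op in c("AND", "OR")) {
    f <- fuse_with_clinician(pred, pred, truth, op)
    expect_equal(f$confusion, epifc:::confusion_counts(truth, pred))
  }

  # exhaustive check over all prediction patterns: OR can only gain
  # sensitivity, AND can only gain specificity
  pats <- expand.grid(m = c(TRUE, FALSE), c = c(TRUE, FALSE),
                      t = c(TRUE, FALSE))
  for (rep_i in 1:30) {
    idx <- sample(nrow(pats), 12, replace = TRUE)
    m <- pats$m[idx]; cl <- pats$c[idx]; tr <- pats$t[idx]
    if (length(unique(tr)) < 2) next
    sens <- function(p) sum(p & tr) / sum(tr)
    spec <- function(p) sum(!p & !tr) / sum(!tr)
    or_f <- fuse_with_clinician(m, cl, tr, "OR")
    and_f <- fuse_with_clinician(m, cl, tr, "AND")
    expect_gte(or_f$metrics$sensitivity, max(sens(m), sens(cl)))
    expect_gte(and_f$metrics$specificity, max(spec(m), spec(cl)))
  }

  # missing clinician labels are excluded and counted
  f <- fuse_with_clinician(c(TRUE, FALSE, TRUE), c(TRUE, NA, FALSE),
                           c(TRUE, FALSE, TRUE), "OR")
  expect_equal(f$n_excluded, 1)
  expect_equal(length(f$fused), 2)
})
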