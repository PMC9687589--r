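# Feature-table conventions: a feature table is a tibble with one row per
# subject, a logical `label` column (TRUE = positive class of the task),
# optional metadata columns, and the 784 canonical feature columns.

feature_cols <- function(df) intersect(feature_taxonomy()$name, names(df))

#' Stratified train/test split
#'
#' Splits subjects into train and test sets at the given ratio, preserving
#' the class proportion within one subject per class. Deterministic given
#' `seed`.
#'
#' @param table Feature table with a logical `label` column.
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(table, ratio = 0.8, seed = 1) {
  stopifnot(is.logical(table$label))
  if (nrow(table) < 10) stop("need at least 10 subjects to split")
  if (length(unique(table$label)) < 2) {
    stop("both classes must be present to split")
  }
  idx_tr <- with_seed(seed, {
    unlist(lapply(c(FALSE, TRUE), function(cl) {
      ids <- which(table$label == cl)
      ids <- sample(ids)
      ids[seq_len(round(ratio * length(ids)))]
    }))
  })
  list(train = table[sort(idx_tr), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), idx_tr), , drop = FALSE])
}

#' Z-score normalization with training statistics
#'
#' `(x - mu) / sigma` per feature, with mean and population standard
#' deviation computed on the training subjects only; the test set is
#' transformed with the training statistics. Zero-variance features are
#' dropped from both sets with a warning.
#'
#' @param train,test Feature matrices or tables (feature columns only are
#'   used for tables).
#' @return List with matrices `train`, `test`, vectors `mu`, `sigma`, and
#'   `dropped` (names of removed features).
#' @export
normalize_features <- function(train, test = NULL) {
  xtr <- as_feature_matrix(train)
  xte <- if (!is.null(test)) as_feature_matrix(test)
  mu <- colMeans(xtr)
  sigma <- apply(xtr, 2, pop_sd)
  drop <- sigma == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance feature(s)")
  }
  keep <- which(!drop)
  ztr <- sweep(sweep(xtr[, keep, drop = FALSE], 2, mu[keep]), 2, sigma[keep],
               `/`)
  zte <- if (!is.null(xte)) {
    sweep(sweep(xte[, keep, drop = FALSE], 2, mu[keep]), 2, sigma[keep], `/`)
  }
  list(train = ztr, test = zte, mu = mu[keep], sigma = sigma[keep],
       dropped = names(sigma)[drop])
}

as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  fc <- feature_cols(x)
  if (length(fc) == 0) {
    fc <- setdiff(names(x)[vapply(x, is.numeric, logical(1))],
                  c("age", "seed"))
  }
  as.matrix(x[, fc, drop = FALSE])
}

#' ANOVA F-score feature selection
#'
#' One-way (two-group) ANOVA F statistic per feature on the training data;
#' returns the indices of the top `k` features, ties broken by lower index.
#'
#' @param x Numeric training matrix (subjects x features).
#' @param y Logical or binary class labels.
#' @param k Number of features to keep.
#' @return Integer column indices, best first.
#' @export
anova_kbest <- function(x, y, k) {
  y <- as.logical(y)
  if (k > ncol(x)) stop("k exceeds the number of features")
  n1 <- sum(y); n0 <- sum(!y); n <- n1 + n0
  m1 <- colMeans(x[y, , drop = FALSE])
  m0 <- colMeans(x[!y, , drop = FALSE])
  gm <- colMeans(x)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ssw <- colSums((x[y, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((x[!y, , drop = FALSE] - rep(m0, each = n0))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[!is.finite(f)] <- 0
  order(-f, seq_along(f))[seq_len(k)]
}

#' PCA dimensionality reduction fitted on training data
#'
#' Principal components are fitted on the (normalized) training matrix only;
#' both sets are projected. The rotation is kept so each component's most
#' loaded features can be reported.
#'
#' @param train,test Numeric matrices.
#' @param n_components Number of components.
#' @return List with `train`, `test` (projected matrices), `rotation`,
#'   `center`, `sdev`.
#' @export
pca_reduce <- function(train, test = NULL, n_components = 17) {
  n_components <- min(n_components, ncol(train), nrow(train))
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  proj <- function(m) sweep(m, 2, pc$center) %*% rot
  list(train = proj(train), test = if (!is.null(test)) proj(test),
       rotation = rot, center = pc$center,
       sdev = pc$sdev[seq_len(n_components)])
}

#' Correlation-based feature pruning
#'
#' Iterates features in canonical (column) order and removes a feature when
#' its absolute Pearson correlation with any already-retained feature
#' strictly exceeds the threshold. Deterministic, unlike random victim
#' selection.
#'
#' @param x Numeric training matrix.
#' @param threshold Absolute-correlation threshold (default 0.92).
#' @return Integer indices of retained columns.
#' @export
correlation_prune <- function(x, threshold = 0.92) {
  if (ncol(x) < 2) stop("need at least 2 features")
  cm <- abs(suppressWarnings(stats::cor(x)))
  cm[is.na(cm)] <- 0
  retained <- 1L
  for (j in 2:ncol(x)) {
    if (all(cm[j, retained] <= threshold)) retained <- c(retained, j)
  }
  retained
}

# ---- model fitting -------------------------------------------------------

default_grid <- function(model) {
  switch(model,
         svm = {
           cs <- c(0.01, 0.1, 1, 10, 100)
           rbind(
             data.frame(kernel = "linear", C = cs, gamma = NA),
             expand.grid(kernel = "radial", C = cs, gamma = c(0.5, 1, 2),
                         stringsAsFactors = FALSE))
         },
         mlp = data.frame(size = c(16, 64, 128)),
         rfc = expand.grid(ntree = c(100, 300), depth = c(NA, 5, 10)),
         logreg = data.frame(C = c(0.01, 0.1, 1, 10, 100)))
}

# Fit one classifier on a reduced matrix; returns a scoring closure.
fit_classifier <- function(x, y, model, params, seed) {
  yf <- factor(as.integer(y), levels = c(0, 1))
  if (model == "svm") {
    g <- if (is.na(params$gamma)) NULL else params$gamma / ncol(x)
    fit <- if (params$kernel == "linear") {
      e1071::svm(x, yf, kernel = "linear", cost = params$C, scale = FALSE)
    } else {
      e1071::svm(x, yf, kernel = "radial", cost = params$C, gamma = g,
                 scale = FALSE)
    }
    dv_tr <- attr(stats::predict(fit, x, decision.values = TRUE),
                  "decision.values")[, 1]
    flip <- mean(dv_tr[y]) < mean(dv_tr[!y])
    function(newx) {
      dv <- attr(stats::predict(fit, newx, decision.values = TRUE),
                 "decision.values")[, 1]
      if (flip) -dv else dv
    }
  } else if (model == "mlp") {
    rng <- apply(x, 2, range)
    span <- pmax(rng[2, ] - rng[1, ], 1e-12)
    sc <- function(m) sweep(sweep(m, 2, rng[1, ]), 2, span, `/`)
    fit <- with_seed(seed, nnet::nnet(sc(x), as.integer(y), size = params$size,
                                      maxit = 200, trace = FALSE,
                                      entropy = TRUE, MaxNWts = 1e5))
    function(newx) as.numeric(stats::predict(fit, sc(newx)))
  } else if (model == "rfc") {
    maxnodes <- if (is.na(params$depth)) NULL else 2^params$depth
    fit <- with_seed(seed, randomForest::randomForest(
      x, yf, ntree = params$ntree, maxnodes = maxnodes))
    function(newx) stats::predict(fit, newx, type = "prob")[, "1"]
  } else if (model == "logreg") {
    lam <- 1 / (params$C * nrow(x))
    fit <- glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                          lambda = lam, standardize = FALSE)
    function(newx) as.numeric(stats::predict(fit, newx = newx, type = "link"))
  } else stop("unknown model ", model)
}

# Normalization + reduction fitted on one training portion; applied to both.
apply_reduction <- function(xtr, ytr, xva, reduction, red_param) {
  nz <- suppressWarnings(normalize_features(xtr, xva))
  xtr <- nz$train; xva <- nz$test
  info <- list(norm = nz[c("mu", "sigma", "dropped")])
  if (reduction == "anova") {
    sel <- anova_kbest(xtr, ytr, min(red_param, ncol(xtr)))
    xtr <- xtr[, sel, drop = FALSE]; xva <- xva[, sel, drop = FALSE]
    info$selected <- colnames(xtr)
  } else if (reduction == "pca") {
    pc <- pca_reduce(xtr, xva, red_param)
    info$rotation <- pc$rotation
    xtr <- pc$train; xva <- pc$test
  } else if (reduction == "corr_anova") {
    keep <- correlation_prune(xtr)
    xtr <- xtr[, keep, drop = FALSE]; xva <- xva[, keep, drop = FALSE]
    sel <- anova_kbest(xtr, ytr, min(red_param, ncol(xtr)))
    xtr <- xtr[, sel, drop = FALSE]; xva <- xva[, sel, drop = FALSE]
    info$selected <- colnames(xtr)
  } else if (reduction != "none") stop("unknown reduction ", reduction)
  list(train = xtr, val = xva, info = info)
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      ids <- sample(which(y == cl))
      f[ids] <- rep(seq_len(k), length.out = length(ids))
    }
    f
  })
}

auc_score <- function(y, score) {
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' Train a classifier with stratified cross-validated grid search
#'
#' Hyperparameters (and the reduction parameter) are chosen by grid search
#' maximizing mean AUC over stratified CV folds. Normalization and the
#' reduction are re-fitted inside every fold's training portion, so no
#' validation information leaks into them. The final model is refitted on the
#' full training set with the winning configuration.
#'
#' @param table Training feature table (logical `label` column + features).
#' @param model One of `"svm"`, `"mlp"`, `"rfc"`, `"logreg"`.
#' @param reduction One of `"pca"`, `"anova"`, `"corr_anova"`, `"none"`.
#' @param reduction_grid Candidate reduction parameters (PCA components or
#'   ANOVA k). Defaults: 17 components for PCA, `c(10, 25, 50, 100, 200)`
#'   for ANOVA-based reductions.
#' @param grid Optional hyperparameter data frame (defaults per model).
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Integer seed controlling folds and any model randomness.
#' @return An `epifc_model` with elements `scorer`, `cv_report` (per-fold
#'   tibble), `best` (chosen configuration), `train_auc_gap`, and the
#'   training-set objects needed to transform new data.
#' @export
train_model <- function(table, model = c("svm", "mlp", "rfc", "logreg"),
                        reduction = c("pca", "anova", "corr_anova", "none"),
                        reduction_grid = NULL, grid = NULL, cv_folds = 5,
                        seed = 1) {
  model <- match.arg(model)
  reduction <- match.arg(reduction)
  y <- table$label
  x <- as_feature_matrix(table)
  if (is.null(grid)) grid <- default_grid(model)
  if (is.null(reduction_grid)) {
    reduction_grid <- switch(reduction, pca = 17,
                             anova = c(10, 25, 50, 100, 200),
                             corr_anova = c(10, 25, 50, 100, 200),
                             none = NA)
  }
  folds <- stratified_folds(y, cv_folds, seed)
  if (any(vapply(seq_len(cv_folds), function(f)
    length(unique(y[folds == f])) < 2, logical(1)))) {
    stop("a CV fold contains a single class; check stratification / n")
  }

  configs <- merge(data.frame(red_param = reduction_grid), grid)
  cv_auc <- matrix(NA_real_, nrow(configs), cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    red_cache <- list()
    for (ci in seq_len(nrow(configs))) {
      rp <- configs$red_param[ci]
      key <- as.character(rp)
      if (is.null(red_cache[[key]])) {
        red_cache[[key]] <- apply_reduction(x[tr, , drop = FALSE], y[tr],
                                            x[!tr, , drop = FALSE],
                                            reduction, rp)
      }
      rd <- red_cache[[key]]
      sc <- fit_classifier(rd$train, y[tr], model, configs[ci, , drop = FALSE],
                           seed + f)
      cv_auc[ci, f] <- auc_score(y[!tr], sc(rd$val))
    }
  }
  mean_auc <- rowMeans(cv_auc)
  best_i <- which.max(mean_auc)          # first maximum: deterministic
  best <- configs[best_i, , drop = FALSE]

  # per-fold report for the winning configuration
  cv_report <- purrr::map_dfr(seq_len(cv_folds), function(f) {
    tr <- folds != f
    rd <- apply_reduction(x[tr, , drop = FALSE], y[tr],
                          x[!tr, , drop = FALSE], reduction, best$red_param)
    sc <- fit_classifier(rd$train, y[tr], model, best, seed + f)
    sv <- sc(rd$val)
    cut <- youden_cutoff(y[!tr], sv)
    cm <- confusion_counts(y[!tr], sv >= cut)
    tibble::tibble(fold = f, auc = auc_score(y[!tr], sv),
                   train_auc = auc_score(y[tr], sc(rd$train)),
                   !!!metrics_from_confusion(cm))
  })

  rd_full <- apply_reduction(x, y, NULL, reduction, best$red_param)
  scorer <- fit_classifier(rd_full$train, y, model, best, seed)
  structure(list(
    model = model, reduction = reduction, best = best,
    cv_report = cv_report, cv_grid_auc = cbind(configs, mean_auc = mean_auc),
    train_auc_gap = mean(cv_report$train_auc) - mean(cv_report$auc),
    transform = rd_full$info, scorer_fn = scorer, reduction_info = rd_full$info,
    feature_names = colnames(x), seed = seed,
    .train_x = x, .train_y = y),
    class = "epifc_model")
}

#' @export
print.epifc_model <- function(x, ...) {
  cat(sprintf("<epifc_model> %s + %s | CV AUC %.3f +/- %.3f (gap %.3f)\n",
              x$model, x$reduction, mean(x$cv_report$auc),
              stats::sd(x$cv_report$auc), x$train_auc_gap))
  invisible(x)
}

# Score new subjects with the stored normalization/reduction/classifier.
predict_scores <- function(object, newdata) {
  x <- as_feature_matrix(newdata)
  x <- x[, object$feature_names, drop = FALSE]
  rd <- apply_reduction(object$.train_x, object$.train_y, x,
                        object$reduction, object$best$red_param)
  object$scorer_fn(rd$val)
}

#' @export
predict.epifc_model <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

# ---- evaluation ----------------------------------------------------------

confusion_counts <- function(y, pred) {
  c(TP = sum(pred & y), TN = sum(!pred & !y),
    FP = sum(pred & !y), FN = sum(!pred & y))
}

metrics_from_confusion <- function(cm) {
  list(accuracy = (cm[["TP"]] + cm[["TN"]]) / sum(cm),
       sensitivity = cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]),
       specificity = cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]))
}

# Threshold maximizing Youden's J = TPR - FPR; ties -> lowest threshold.
youden_cutoff <- function(y, score) {
  cand <- sort(unique(score))
  j <- vapply(cand, function(t) {
    p <- score >= t
    tpr <- sum(p & y) / sum(y)
    fpr <- sum(p & !y) / sum(!y)
    tpr - fpr
  }, numeric(1))
  cand[which(j == max(j))[1]]
}

#' Evaluate a fitted model on a test set
#'
#' Computes the ROC curve from continuous scores, the AUC, the optimal
#' cut-off maximizing Youden's J (ties resolved to the lower threshold), the
#' confusion matrix and accuracy/sensitivity/specificity at that cut-off,
#' and a surrogate null: the 95th percentile of the AUC over 100 label
#' permutations with a fixed seed.
#'
#' @param model An `epifc_model`.
#' @param test Test feature table with a logical `label` column.
#' @param n_surrogates Number of label permutations (default 100).
#' @return An `epifc_eval` with ROC points, metrics, confusion matrix,
#'   surrogate AUCs and their 95th percentile.
#' @export
evaluate_model <- function(model, test, n_surrogates = 100) {
  y <- test$label
  if (length(unique(y)) < 2) stop("test set contains a single class")
  score <- predict_scores(model, test)
  r <- pROC::roc(response = y, predictor = score, levels = c(FALSE, TRUE),
                 direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  cut <- youden_cutoff(y, score)
  cm <- confusion_counts(y, score >= cut)
  surrogate <- with_seed(model$seed + 9973L, {
    vapply(seq_len(n_surrogates), function(i) auc_score(sample(y), score),
           numeric(1))
  })
  structure(list(
    auc = auc, cutoff = cut, confusion = cm,
    metrics = metrics_from_confusion(cm),
    roc = tibble::tibble(threshold = r$thresholds, tpr = r$sensitivities,
                         fpr = 1 - r$specificities),
    surrogate_auc = surrogate,
    surrogate_q95 = as.numeric(stats::quantile(surrogate, 0.95)),
    scores = score, labels = y, n = length(y)),
    class = "epifc_eval")
}

#' @export
print.epifc_eval <- function(x, ...) {
  cat(sprintf(paste0("<epifc_eval> n = %d | AUC %.3f (surrogate 95th pct ",
                     "%.3f)\n  acc %.3f, sens %.3f, spec %.3f @ cutoff %.3g\n"),
              x$n, x$auc, x$surrogate_q95, x$metrics$accuracy,
              x$metrics$sensitivity, x$metrics$specificity, x$cutoff))
  invisible(x)
}

#' Subgroup classification tasks
#'
#' Runs the fixed SVM + ANOVA baseline protocol (stratified split, CV grid
#' search, test evaluation) separately for male, female, younger (age below
#' the cut) and older (age at or above the cut; age exactly at the cut goes
#' to the older group) subjects. Subgroups with fewer than 10 subjects of
#' either class are skipped with a warning.
#'
#' @param table Feature table with `label`, `sex` and `age` columns.
#' @param age_cut Age threshold in years (default 50).
#' @param seed Integer seed.
#' @return Named list of `list(model, evaluation)` per subgroup (skipped
#'   subgroups are `NULL`).
#' @export
subgroup_tasks <- function(table, age_cut = 50, seed = 1) {
  subsets <- list(male = table$sex == "M",
                  female = table$sex == "F",
                  young = table$age < age_cut,
                  old = table$age >= age_cut)
  purrr::imap(subsets, function(mask, nm) {
    sub <- table[mask, , drop = FALSE]
    if (sum(sub$label) < 10 || sum(!sub$label) < 10) {
      warning("subgroup '", nm, "' skipped: fewer than 10 subjects per class")
      return(NULL)
    }
    sp <- split_train_test(sub, seed = seed)
    m <- train_model(sp$train, model = "svm", reduction = "anova",
                     seed = seed)
    list(model = m, evaluation = evaluate_model(m, sp$test))
  })
}

#' Fuse model predictions with the clinician's EEG reading
#'
#' Element-wise logical combination (positive = epileptic) of binary model
#' predictions and the clinician's normal/abnormal label, with the usual
#' confusion metrics recomputed on the fused prediction. Subjects with a
#' missing clinician label are excluded and counted in the result.
#'
#' @param model_pred Logical (or 0/1) model predictions.
#' @param clinician Logical, 0/1, or `"abnormal"`/`"normal"` clinician labels.
#' @param truth Logical true labels.
#' @param op `"AND"` or `"OR"`.
#' @return List with `fused` predictions, `confusion`, `metrics`, and
#'   `n_excluded`.
#' @export
fuse_with_clinician <- function(model_pred, clinician, truth,
                                op = c("AND", "OR")) {
  op <- match.arg(op)
  if (is.character(clinician)) clinician <- clinician == "abnormal"
  model_pred <- as.logical(model_pred)
  clinician <- as.logical(clinician)
  ok <- !is.na(clinician)
  n_excluded <- sum(!ok)
  fused <- if (op == "AND") model_pred[ok] & clinician[ok] else
    model_pred[ok] | clinician[ok]
  cm <- confusion_counts(truth[ok], fused)
  list(fused = fused, confusion = cm, metrics = metrics_from_confusion(cm),
       op = op, n_excluded = n_excluded)
}
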