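#' Tidy a fitted model's cross-validation report
#'
#' One row per CV fold with AUC, training AUC, and the confusion-derived
#' metrics at the fold's optimal cut-off.
#'
#' @param x An `epifc_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy epifc_model
#' @export
tidy.epifc_model <- function(x, ...) x$cv_report

#' One-row summary of a fitted model
#'
#' @param x An `epifc_model`.
#' @param ... Unused.
#' @return A tibble with the chosen configuration, mean/sd CV AUC and the
#'   train-validation AUC gap.
#' @method glance epifc_model
#' @export
glance.epifc_model <- function(x, ...) {
  tibble::tibble(model = x$model, reduction = x$reduction,
                 red_param = x$best$red_param,
                 cv_auc_mean = mean(x$cv_report$auc),
                 cv_auc_sd = stats::sd(x$cv_report$auc),
                 train_auc_gap = x$train_auc_gap)
}

#' Tidy an evaluation's ROC curve
#'
#' @param x An `epifc_eval`.
#' @param ... Unused.
#' @return A tibble of ROC points (threshold, tpr, fpr).
#' @method tidy epifc_eval
#' @export
tidy.epifc_eval <- function(x, ...) x$roc

#' One-row summary of a test-set evaluation
#'
#' @param x An `epifc_eval`.
#' @param ... Unused.
#' @return A tibble with AUC, the surrogate 95th percentile, and the metrics
#'   at the optimal cut-off.
#' @method glance epifc_eval
#' @export
glance.epifc_eval <- function(x, ...) {
  tibble::tibble(n = x$n, auc = x$auc, surrogate_q95 = x$surrogate_q95,
                 cutoff = x$cutoff, accuracy = x$metrics$accuracy,
                 sensitivity = x$metrics$sensitivity,
                 specificity = x$metrics$specificity)
}

#' Tidy a connectivity matrix into long format
#'
#' @param x A `conn_matrix`.
#' @param ... Unused.
#' @return A tibble with `channel_i`, `channel_j`, `estimator`, `band`,
#'   `value` (off-diagonal entries; unique pairs for undirected matrices).
#' @method tidy conn_matrix
#' @export
tidy.conn_matrix <- function(x, ...) {
  v <- x$values
  idx <- which(if (x$directed) row(v) != col(v) else upper.tri(v),
               arr.ind = TRUE)
  tibble::tibble(channel_i = rownames(v)[idx[, 1]],
                 channel_j = colnames(v)[idx[, 2]],
                 estimator = x$estimator, band = x$band,
                 value = v[idx])
}

#' Connectivity matrices of a subject as one long table
#'
#' @param mats List of `conn_matrix` objects.
#' @param subject_id Optional subject identifier column.
#' @return A tibble (subject, estimator, band, channel_i, channel_j, value).
#' @export
conn_to_table <- function(mats, subject_id = NA_character_) {
  dplyr::bind_cols(subject = subject_id,
                   dplyr::bind_rows(lapply(mats, tidy.conn_matrix)))
}

#' Plot a connectivity matrix as a heat map
#'
#' @param object A `conn_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot conn_matrix
#' @export
autoplot.conn_matrix <- function(object, ...) {
  v <- object$values
  df <- tibble::tibble(channel_i = rep(rownames(v), times = ncol(v)),
                       channel_j = rep(colnames(v), each = nrow(v)),
                       value = as.vector(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel_j, y = .data$channel_i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(rownames(v))) +
    ggplot2::scale_x_discrete(limits = colnames(v)) +
    ggplot2::labs(title = sprintf("%s (%s band)", toupper(object$estimator),
                                  object$band),
                  x = if (object$directed) "source" else NULL,
                  y = if (object$directed) "target" else NULL,
                  fill = "value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a test-set ROC curve with its surrogate reference
#'
#' @param object An `epifc_eval`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve, the chance diagonal and an annotation
#'   with the AUC and the surrogate 95th percentile.
#' @method autoplot epifc_eval
#' @export
autoplot.epifc_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::annotate("text", x = 0.65, y = 0.12,
                      label = sprintf("AUC = %.3f\nsurrogate 95th = %.3f",
                                      object$auc, object$surrogate_q95)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
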