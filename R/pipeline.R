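#' Pipeline configuration
#'
#' All tunables of the extraction and classification pipeline with their
#' default values. Unknown names are rejected.
#'
#' @param ... Name-value overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
#' @examples
#' pipeline_config(top_k = 25)
pipeline_config <- function(...) {
  defaults <- list(
    low_hz = 1, high_hz = 40,
    ica_components = 15, ica_threshold = 0.8,
    bp_epoch_s = 5, conn_epoch_s = 2.5, conn_fs = 128,
    min_ptp_uV = 1, clean_folds = 10, max_interp = 3,
    top_k = 50, welch_seg_s = 2,
    mvar_order = 8, mi_k = 3, conn_nw = 4,
    model = "svm", reduction = "pca", cv_folds = 5,
    split_ratio = 0.8, age_cut = 50)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns the
#'   configuration (round-trip identical).
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Preprocess one recording
#'
#' Runs the fixed stage order filter -> ICA -> epoch on a raw recording and
#' returns both epoch sets (band-power and connectivity) after flat-epoch
#' exclusion, cross-validated cleaning, and bipolar derivation.
#'
#' @param rec An [eeg_recording()].
#' @param config A [pipeline_config()].
#' @param template An [eog_template()].
#' @return List with bipolar epoch sets `bp` (5 s at the native rate) and
#'   `conn` (2.5 s at 128 Hz), plus the `stage_log` of executed stages.
#' @export
preprocess_recording <- function(rec, config = pipeline_config(),
                                 template = eog_template()) {
  log <- character(0)
  filt <- bandpass_filter(rec, config$low_hz, config$high_hz)
  log <- c(log, "bandpass_filter")
  clean <- remove_eog(filt, template, config$ica_components)
  log <- c(log, "remove_eog")
  layout <- bipolar_montage()
  prep_one <- function(epoch_s, target_fs) {
    es <- make_epochs(clean, epoch_s, target_fs)
    es <- drop_flat_epochs(es, config$min_ptp_uV)
    es <- clean_epochs(es, config$clean_folds, config$max_interp)
    to_bipolar(es, layout)
  }
  bp <- prep_one(config$bp_epoch_s, clean$fs)
  log <- c(log, "epoch_bandpower")
  conn <- prep_one(config$conn_epoch_s, min(config$conn_fs, clean$fs))
  log <- c(log, "epoch_connectivity")
  list(bp = bp, conn = conn, stage_log = log,
       removal = attr(clean, "removal"))
}

#' Extract the canonical 784-entry feature vector for one subject
#'
#' Full per-subject extraction: preprocessing, per-band epoch selection,
#' band-power features, the four connectivity estimators with group
#' summaries, graph measures and asymmetry ratios, assembled in canonical
#' order.
#'
#' @param rec An [eeg_recording()].
#' @param config A [pipeline_config()].
#' @param template An [eog_template()].
#' @return Named numeric vector of length 784.
#' @export
extract_subject_features <- function(rec, config = pipeline_config(),
                                     template = eog_template()) {
  pp <- preprocess_recording(rec, config, template)
  layout <- bipolar_montage()

  # band-power block on the 5 s epoch set
  bp_bands <- band_definitions("bandpower")
  bp_set <- band_power_set(pp$bp, bp_bands)
  bp_sel <- lapply(stats::setNames(nm = c("delta", "theta", "alpha", "beta",
                                          "global")),
                   function(b) select_top_epochs(pp$bp, b, config$top_k,
                                                 band_set = bp_set))
  bp_feats <- bandpower_features(pp$bp, layout, bp_sel, band_set = bp_set)

  # connectivity selections on the 2.5 s epoch set (connectivity band edges)
  cn_bands <- band_definitions("connectivity")
  cn_set <- band_power_set(pp$conn, cn_bands)
  cn_sel <- lapply(stats::setNames(nm = c("delta", "theta", "alpha", "beta",
                                          "global")),
                   function(b) select_top_epochs(pp$conn, b, config$top_k,
                                                 band_set = cn_set))

  mats <- list()
  for (bi in seq_len(nrow(cn_bands))) {
    band <- cn_bands[bi, ]
    se <- suppressWarnings(cross_spectra(pp$conn, band, cn_sel[[band$band]],
                                         nw = config$conn_nw))
    mats[[paste0("imcoh_", band$band)]] <- imcoh(se)
    mats[[paste0("plv_", band$band)]] <- plv(se)
  }
  mats[["mi_global"]] <- mutual_information(pp$conn, cn_sel$global,
                                            k = config$mi_k)
  mvar <- fit_mvar(pp$conn, cn_sel$global, order = config$mvar_order)
  for (bi in seq_len(nrow(cn_bands))) {
    band <- cn_bands[bi, ]
    mats[[paste0("pdc_", band$band)]] <- pdc(mvar, band)
  }
  assemble_features(bp_feats, mats, layout)
}

#' Extract features for a whole cohort
#'
#' @param cohort An `eeg_cohort` (from [generate_cohort()]) with recordings,
#'   or a directory containing per-subject EDF files plus `metadata.csv`.
#' @param config A [pipeline_config()].
#' @param template An [eog_template()].
#' @param cache_dir Optional directory: per-subject feature vectors are
#'   written there as CSV and reused on re-runs, making the pipeline
#'   resumable.
#' @param progress Print one line per subject.
#' @return Feature table: tibble with `subject_id`, metadata columns and the
#'   784 canonical feature columns.
#' @export
extract_features <- function(cohort, config = pipeline_config(),
                             template = eog_template(), cache_dir = NULL,
                             progress = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort_edf(cohort)
  stopifnot(inherits(cohort, "eeg_cohort"), !is.null(cohort$recordings))
  meta <- cohort$metadata
  tax_names <- feature_taxonomy()$name
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$subject_id[i]
    cache <- if (!is.null(cache_dir)) file.path(cache_dir,
                                                paste0(id, "_features.csv"))
    if (!is.null(cache) && file.exists(cache)) {
      fv <- stats::setNames(utils::read.csv(cache)$value,
                            utils::read.csv(cache)$name)
    } else {
      fv <- extract_subject_features(cohort$recordings[[id]]$recording,
                                     config, template)
      if (!is.null(cache)) {
        if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
        utils::write.csv(data.frame(name = names(fv), value = fv), cache,
                         row.names = FALSE)
      }
    }
    rows[[i]] <- fv[tax_names]
    if (progress) message(sprintf("extracted %s (%d/%d)", id, i, nrow(meta)))
  }
  fx <- do.call(rbind, rows)
  colnames(fx) <- tax_names
  dplyr::bind_cols(meta[, setdiff(names(meta), "seed")],
                   tibble::as_tibble(fx))
}

#' Read a cohort written by [write_cohort_edf()]
#'
#' @param dir Directory with `<subject_id>.edf` files and `metadata.csv`.
#' @param skip_bad Skip unreadable EDF files (named in a warning) instead of
#'   aborting.
#' @return An `eeg_cohort`.
#' @export
read_cohort_edf <- function(dir, skip_bad = FALSE) {
  meta <- tibble::as_tibble(utils::read.csv(file.path(dir, "metadata.csv"),
                                            stringsAsFactors = FALSE))
  meta$epileptic <- meta$diagnosis != "non_epileptic"
  recs <- list()
  ok <- rep(TRUE, nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$subject_id[i]
    path <- file.path(dir, paste0(id, ".edf"))
    r <- tryCatch(read_edf(path), error = function(e) e)
    if (inherits(r, "error")) {
      if (!skip_bad) stop("failed to read ", path, ": ", conditionMessage(r))
      warning("skipping unreadable EDF for subject ", id, ": ",
              conditionMessage(r))
      ok[i] <- FALSE
    } else {
      recs[[id]] <- list(recording = r, ground_truth_coupling = NULL)
    }
  }
  structure(list(metadata = meta[ok, , drop = FALSE], recordings = recs,
                 spec = NULL),
            class = "eeg_cohort")
}

#' Run the full pipeline on a cohort
#'
#' Feature extraction, stratified 80/20 split, cross-validated training,
#' test-set evaluation against the surrogate null, and AND/OR fusion with
#' the clinician's EEG reading.
#'
#' @param cohort An `eeg_cohort` with recordings, an EDF directory, or a
#'   previously extracted feature table.
#' @param config A [pipeline_config()].
#' @param task `"all_epilepsy"` (any epileptic diagnosis vs the rest) or
#'   `"focal_lesional"` (focal lesional epilepsy vs non-epileptic; other
#'   subtypes excluded).
#' @param seed Run-level seed recorded in the report.
#' @param cache_dir Optional feature cache directory (see
#'   [extract_features()]).
#' @return An `epifc_report`: list with `features`, `task`, `model`,
#'   `evaluation`, `fusion` (AND and OR), `config`, `seed`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         task = c("all_epilepsy", "focal_lesional"),
                         seed = 1, cache_dir = NULL) {
  task <- match.arg(task)
  features <- if (is.data.frame(cohort)) cohort else
    extract_features(cohort, config, cache_dir = cache_dir)
  if (task == "focal_lesional") {
    features <- features[features$diagnosis %in% c("focal_lesional",
                                                   "non_epileptic"), ,
                         drop = FALSE]
    features$label <- features$diagnosis == "focal_lesional"
  } else {
    features$label <- features$epileptic
  }
  if (nrow(features) < 10) stop("need at least 10 subjects")
  sp <- split_train_test(features, config$split_ratio, seed)
  model <- train_model(sp$train, model = config$model,
                       reduction = config$reduction,
                       cv_folds = config$cv_folds, seed = seed)
  ev <- evaluate_model(model, sp$test)
  pred <- ev$scores >= ev$cutoff
  fusion <- NULL
  if ("clinician_eeg_result" %in% names(sp$test)) {
    fusion <- list(
      AND = fuse_with_clinician(pred, sp$test$clinician_eeg_result,
                                sp$test$label, "AND"),
      OR = fuse_with_clinician(pred, sp$test$clinician_eeg_result,
                               sp$test$label, "OR"),
      clinician = {
        cl <- sp$test$clinician_eeg_result == "abnormal"
        cm <- confusion_counts(sp$test$label, cl)
        list(confusion = cm, metrics = metrics_from_confusion(cm))
      })
  }
  structure(list(features = features, task = task, split = sp, model = model,
                 evaluation = ev, fusion = fusion, config = config,
                 seed = seed),
            class = "epifc_report")
}

#' @export
print.epifc_report <- function(x, ...) {
  cat(sprintf("<epifc_report> task %s | %d subjects | %s + %s\n", x$task,
              nrow(x$features), x$model$model, x$model$reduction))
  print(x$evaluation)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `epifc_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  ev <- report$evaluation
  out <- list(
    task = report$task, seed = report$seed,
    model = report$model$model, reduction = report$model$reduction,
    best = as.list(report$model$best),
    cv = as.list(report$model$cv_report),
    train_auc_gap = report$model$train_auc_gap,
    test = list(auc = ev$auc, cutoff = ev$cutoff,
                confusion = as.list(ev$confusion), metrics = ev$metrics,
                surrogate_q95 = ev$surrogate_q95),
    fusion = if (!is.null(report$fusion)) {
      lapply(report$fusion, function(f)
        list(confusion = as.list(f$confusion), metrics = f$metrics))
    })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
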