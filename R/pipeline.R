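# End-to-end experiment driver: simulate/load -> derive ratios -> split ->
# (optional bootstrap augmentation) -> standardize+train -> evaluate ->
# calibrate -> explain, with a reproducible artifact bundle.

#' Build an experiment configuration
#'
#' All defaults equal the reference training protocol for blood-panel NAM
#' classifiers: stratified 80/20 split, train-only Z-scoring, hidden sizes
#' [64, 32], dropout 0.2, Adam at 0.001 with weight decay 1e-5, at most 150
#' epochs with early stopping (patience 20) and a reduce-on-plateau schedule
#' (patience 10, factor 0.5), 1000 bootstrap iterations for test-set
#' confidence intervals, and 10 calibration bins.
#'
#' @param data input cohort: a `"nam_cohort"`, a data frame with a `label`
#'   column, a CSV path, or `NULL` to simulate from `spec`.
#' @param spec a `"cohort_spec"` used when `data` is `NULL` (default
#'   [hematology_spec()]).
#' @param test_fraction held-out fraction for the stratified split.
#' @param augment `"none"`, `"train"` (bootstrap-double the training split
#'   only; leakage-safe default when augmentation is requested), or
#'   `"pre-split"` (double the full table before splitting, the literal
#'   augment-then-model reading; resampled duplicates can then straddle the
#'   split, so a leakage warning is emitted).
#' @param n_boot bootstrap iterations for metric confidence intervals.
#' @param calibration_bins equal-width probability bins.
#' @param threshold classification threshold.
#' @param seed master seed; stage seeds are derived from it.
#' @param ... overrides passed to [nam()] (e.g. `hidden`, `max_epochs`,
#'   `monitor`).
#' @return A list of class `"nam_experiment_config"`.
#' @export
experiment_config <- function(data = NULL, spec = NULL, test_fraction = 0.2,
                              augment = c("none", "train", "pre-split"),
                              n_boot = 1000L, calibration_bins = 10L,
                              threshold = 0.5, seed = 1L, ...) {
  augment <- match.arg(augment)
  check_scalar(test_fraction, "test_fraction", 1e-9, 1 - 1e-9)
  structure(
    list(data = data, spec = spec, test_fraction = test_fraction,
         augment = augment, n_boot = as.integer(n_boot),
         calibration_bins = as.integer(calibration_bins),
         threshold = threshold, seed = as.integer(seed),
         nam_args = list(...)),
    class = "nam_experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields map directly to [experiment_config()] arguments; a `nam`
#' block holds overrides for [nam()]. The `data` field, if present, is a CSV
#' path.
#'
#' @param path YAML file.
#' @return A `"nam_experiment_config"`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  nam_args <- y$nam %||% list()
  if (!is.null(nam_args$hidden)) nam_args$hidden <- unlist(nam_args$hidden)
  do.call(experiment_config, c(
    list(data = y$data %||% NULL,
         test_fraction = y$test_fraction %||% 0.2,
         augment = y$augment %||% "none",
         n_boot = y$n_boot %||% 1000L,
         calibration_bins = y$calibration_bins %||% 10L,
         threshold = y$threshold %||% 0.5,
         seed = y$seed %||% 1L),
    nam_args
  ))
}

resolve_cohort <- function(config) {
  d <- config$data
  if (is.null(d)) {
    spec <- config$spec %||% hematology_spec(seed = config$seed)
    cohort <- generate_cohort(spec, seed = config$seed)
    return(cohort$data)
  }
  if (inherits(d, "nam_cohort")) return(d$data)
  if (is.character(d)) return(read_cohort(d))
  if (is.data.frame(d)) return(validate_cohort(d))
  stop("unsupported `data` in experiment config", call. = FALSE)
}

#' Run an end-to-end NAM experiment
#'
#' Executes the full protocol: obtain the cohort (simulate or load), derive
#' any missing ratio columns, stratified split, optional bootstrap
#' augmentation, NAM training with train-only standardization, test-set
#' evaluation with bootstrap confidence intervals, calibration analysis,
#' additive attributions with global/class-wise importance, and a logistic
#' baseline for sanity contrast. Identical configurations produce identical
#' bundles.
#'
#' @param config a `"nam_experiment_config"` from [experiment_config()] or
#'   [read_experiment_config()].
#' @param out_dir optional directory; when given, all reports are written
#'   there (JSON/CSV) together with a `manifest.json`.
#' @param verbose print stage progress.
#' @return An object of class `"nam_run_bundle"`: list with `fit`, `split`,
#'   `metrics`, `calibration`, `importance`, `intrinsic`, `classwise`,
#'   `attributions`, `trace`, `baseline`, `test_prob`, `test_labels`,
#'   `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "nam_experiment_config"))
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  say("stage: data")
  table <- derive_ratios(resolve_cohort(config))

  if (config$augment == "pre-split") {
    warning("pre-split augmentation lets resampled duplicates straddle the ",
            "train/test split (information leakage); use augment = \"train\" ",
            "for leakage-safe evaluation", call. = FALSE)
    table <- bootstrap_augment(table, seed = config$seed)
    say(sprintf("pre-split augmentation: modeling table has %d rows",
                nrow(table)))
  }

  say("stage: split")
  split <- stratified_split(table$label, config$test_fraction,
                            seed = config$seed)
  train_tab <- table[split$train, , drop = FALSE]
  test_tab <- table[split$test, , drop = FALSE]

  if (config$augment == "train") {
    train_tab <- bootstrap_augment(train_tab, seed = config$seed + 1L)
    say(sprintf("train-only augmentation: training table has %d rows",
                nrow(train_tab)))
  }

  say("stage: train")
  nam_args <- config$nam_args
  nam_args$seed <- nam_args$seed %||% config$seed
  fit <- do.call(nam, c(list(train_tab[setdiff(names(train_tab), "label")],
                             train_tab$label), nam_args))

  say("stage: evaluate")
  test_prob <- predict(fit, test_tab)
  metrics <- evaluate_predictions(test_prob, test_tab$label,
                                  threshold = config$threshold,
                                  n_boot = config$n_boot,
                                  seed = config$seed)
  calib <- calibration_report(test_prob, test_tab$label,
                              bins = config$calibration_bins)

  say("stage: explain")
  attrs <- attributions(fit, newdata = test_tab)
  importance <- global_importance(attrs, n_boot = config$n_boot,
                                  seed = config$seed)
  intrinsic <- intrinsic_importance(fit, newdata = test_tab)
  classwise <- classwise_summary(attrs, test_tab$label)

  say("stage: baseline")
  baseline <- logistic_baseline(train_tab, test_tab, fit$standardizer)

  bundle <- structure(
    list(fit = fit, split = split, metrics = metrics, calibration = calib,
         importance = importance, intrinsic = intrinsic,
         classwise = classwise, attributions = attrs, trace = fit$trace,
         baseline = baseline, test_prob = test_prob,
         test_labels = test_tab$label, config = config),
    class = "nam_run_bundle"
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Plain logistic regression on the standardized features; sanity contrast
# only, not a tuned benchmark.
logistic_baseline <- function(train_tab, test_tab, standardizer) {
  xtr <- as.data.frame(apply_standardizer(standardizer, train_tab))
  names(xtr) <- make.names(names(xtr))
  xte <- as.data.frame(apply_standardizer(standardizer, test_tab))
  names(xte) <- make.names(names(xte))
  xtr$label <- train_tab$label
  glm_fit <- suppressWarnings(
    stats::glm(label ~ ., data = xtr, family = stats::binomial()))
  prob <- as.numeric(stats::predict(glm_fit, newdata = xte,
                                    type = "response"))
  cm <- confusion_at_threshold(prob, test_tab$label)
  m <- compute_metrics(cm)
  list(accuracy = unname(m["accuracy"]),
       balanced_accuracy = unname(m["balanced_accuracy"]),
       roc_auc = roc_auc(prob, test_tab$label))
}

#' @export
print.nam_run_bundle <- function(x, ...) {
  cat("NAM experiment bundle\n")
  cat(sprintf("  train %d / test %d, augment = %s\n",
              length(x$split$train), length(x$split$test),
              x$config$augment))
  m <- x$metrics
  key <- m[m$metric %in% c("accuracy", "balanced_accuracy", "roc_auc"), ]
  for (i in seq_len(nrow(key))) {
    cat(sprintf("  %-17s %.3f (%.3f, %.3f)\n", key$metric[i],
                key$value[i], key$lower[i], key$upper[i]))
  }
  cat(sprintf("  calibration deviation %.4f, Brier %.4f\n",
              x$calibration$deviation, x$calibration$brier))
  cat(sprintf("  baseline logistic accuracy %.3f, AUC %.3f\n",
              x$baseline$accuracy, x$baseline$roc_auc))
  cat(sprintf("  top features: %s\n",
              paste(utils::head(x$importance$feature, 5), collapse = ", ")))
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  utils::write.csv(bundle$metrics, path("metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(deviation = bundle$calibration$deviation,
         brier = bundle$calibration$brier,
         weighted = bundle$calibration$weighted,
         bins = bundle$calibration$bins),
    path("calibration.json"), auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(bundle$importance, path("importance.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(feature = names(bundle$intrinsic),
                              importance = unname(bundle$intrinsic)),
                   path("intrinsic_importance.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$classwise), path("classwise.csv"),
                   row.names = FALSE)
  attr_df <- as.data.frame(bundle$attributions$phi)
  attr_df$base_value <- bundle$attributions$base_value
  attr_df$logit <- bundle$attributions$logit
  utils::write.csv(attr_df, path("attributions.csv"), row.names = FALSE)
  utils::write.csv(bundle$trace, path("training_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(prob = bundle$test_prob,
                              label = bundle$test_labels),
                   path("test_predictions.csv"), row.names = FALSE)
  save_nam(bundle$fit, path("model.json"))
  manifest <- list(
    files = c("metrics.csv", "calibration.json", "importance.csv",
              "intrinsic_importance.csv", "classwise.csv",
              "attributions.csv", "training_trace.csv",
              "test_predictions.csv", "model.json"),
    config = list(test_fraction = bundle$config$test_fraction,
                  augment = bundle$config$augment,
                  n_boot = bundle$config$n_boot,
                  calibration_bins = bundle$config$calibration_bins,
                  threshold = bundle$config$threshold,
                  seed = bundle$config$seed,
                  nam_args = bundle$config$nam_args)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
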