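# Diagnostic evaluation: threshold metrics, ROC AUC, percentile-bootstrap
# confidence intervals, and probability-calibration reports.

#' Confusion matrix at a probability threshold
#'
#' Predicted positive iff `prob >= threshold` (a score exactly at the
#' threshold counts positive).
#'
#' @param prob predicted probabilities.
#' @param labels binary outcomes (0/1).
#' @param threshold classification threshold (default 0.5).
#' @return An object of class `"confusion_matrix"`: list with `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion_at_threshold <- function(prob, labels, threshold = 0.5) {
  if (length(prob) == 0L) stop("empty input", call. = FALSE)
  if (length(prob) != length(labels)) {
    stop("`prob` and `labels` must have equal length", call. = FALSE)
  }
  pred <- prob >= threshold
  pos <- labels == 1
  structure(
    list(TP = sum(pred & pos), FP = sum(pred & !pos),
         FN = sum(!pred & pos), TN = sum(!pred & !pos)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("case", "control"),
                              predicted = c("case", "control")))
  print(m)
  invisible(x)
}

#' Threshold classification metrics from a confusion matrix
#'
#' Computes the standard diagnostic suite: sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, accuracy, balanced accuracy
#' `(sens+spec)/2`, PPV, NPV, F1 (harmonic mean of PPV and sensitivity),
#' Matthews correlation coefficient, and the likelihood ratios
#' `LR+ = sens/(1-spec)`, `LR- = (1-sens)/spec`. Undefined quotients (e.g.
#' LR+ when specificity is 1) are reported as `NA`, never coerced to 0 or
#' infinity.
#'
#' @param cm a `"confusion_matrix"`.
#' @return A named numeric vector of class `"metric_report"`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; FP <- cm$FP; FN <- cm$FN; TN <- cm$TN
  n <- TP + FP + FN + TN
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- sdiv(TP, TP + FN)
  spec <- sdiv(TN, TN + FP)
  ppv <- sdiv(TP, TP + FP)
  npv <- sdiv(TN, TN + FN)
  mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  out <- c(
    accuracy = (TP + TN) / n,
    balanced_accuracy = (sens + spec) / 2,
    f1 = if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_
         else 2 * ppv * sens / (ppv + sens),
    mcc = if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den,
    sensitivity = sens,
    specificity = spec,
    ppv = ppv,
    npv = npv,
    lr_plus = if (is.na(sens) || is.na(spec) || spec == 1) NA_real_
              else sens / (1 - spec),
    lr_minus = if (is.na(sens) || is.na(spec) || spec == 0) NA_real_
               else (1 - sens) / spec
  )
  class(out) <- c("metric_report", class(out))
  out
}

#' @export
print.metric_report <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' ROC area under the curve
#'
#' Rank-statistic (Mann-Whitney) formulation; tied scores contribute 1/2.
#'
#' @param prob predicted scores/probabilities.
#' @param labels binary outcomes (0/1); both classes must be present.
#' @return Scalar AUC.
#' @export
roc_auc <- function(prob, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(prob)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# metric identifier -> function(prob, labels, threshold) -> scalar (NA if
# undefined on that sample)
metric_value <- function(metric, prob, labels, threshold = 0.5) {
  if (metric == "roc_auc") {
    if (length(unique(labels)) < 2L) return(NA_real_)
    return(roc_auc(prob, labels))
  }
  if (metric == "brier") return(mean((prob - labels)^2))
  m <- compute_metrics(confusion_at_threshold(prob, labels, threshold))
  if (!metric %in% names(m)) stop("unknown metric: ", metric, call. = FALSE)
  unname(m[metric])
}

#' Percentile-bootstrap confidence interval for a classification metric
#'
#' Resamples (probability, label) pairs with replacement `n_boot` times and
#' takes percentile quantiles of the recomputed metric. Iterations where the
#' metric is undefined (e.g. a resample missing one class for AUC) are
#' dropped and counted.
#'
#' @param prob predicted probabilities.
#' @param labels binary outcomes (0/1).
#' @param metric one of `"accuracy"`, `"balanced_accuracy"`, `"f1"`,
#'   `"mcc"`, `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`,
#'   `"lr_plus"`, `"lr_minus"`, `"roc_auc"`, `"brier"`.
#' @param threshold classification threshold for threshold-based metrics.
#' @param n_boot bootstrap iterations (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return A list with `point`, `lower`, `upper`, `n_boot`, `n_dropped`.
#' @export
bootstrap_ci <- function(prob, labels, metric = "accuracy", threshold = 0.5,
                         n_boot = 1000L, level = 0.95, seed = 1L) {
  n <- length(prob)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  check_scalar(level, "level", 1e-9, 1 - 1e-9)
  point <- metric_value(metric, prob, labels, threshold)
  stats_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_value(metric, prob[idx], labels[idx], threshold)
    }, 0)
  })
  ok <- stats_boot[!is.na(stats_boot)]
  if (length(ok) == 0L) {
    stop("metric undefined in every bootstrap iteration", call. = FALSE)
  }
  qs <- stats::quantile(ok, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE, type = 7)
  list(point = point, lower = qs[1], upper = qs[2],
       n_boot = as.integer(n_boot), n_dropped = sum(is.na(stats_boot)))
}

#' Full metric report with bootstrap confidence intervals
#'
#' Computes the complete diagnostic suite (threshold metrics plus ROC AUC and
#' Brier score) with percentile-bootstrap confidence intervals for each.
#'
#' @inheritParams bootstrap_ci
#' @param metrics which metrics to report.
#' @return A data frame (class `"metric_ci_report"`) with columns `metric`,
#'   `value`, `lower`, `upper`.
#' @export
evaluate_predictions <- function(prob, labels, threshold = 0.5,
                                 n_boot = 1000L, level = 0.95, seed = 1L,
                                 metrics = c("accuracy", "balanced_accuracy",
                                             "f1", "mcc", "sensitivity",
                                             "specificity", "ppv", "npv",
                                             "lr_plus", "lr_minus",
                                             "roc_auc", "brier")) {
  rows <- lapply(seq_along(metrics), function(i) {
    ci <- bootstrap_ci(prob, labels, metrics[i], threshold = threshold,
                       n_boot = n_boot, level = level, seed = seed + i - 1L)
    data.frame(metric = metrics[i], value = ci$point,
               lower = ci$lower, upper = ci$upper)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_ci_report", class(out))
  attr(out, "n") <- length(prob)
  attr(out, "n_boot") <- n_boot
  attr(out, "level") <- level
  out
}

#' @export
print.metric_ci_report <- function(x, digits = 3, ...) {
  cat(sprintf("Diagnostic metrics (n = %d, %d bootstrap iterations, %.0f%% CI)\n",
              attr(x, "n"), attr(x, "n_boot"), 100 * attr(x, "level")))
  y <- as.data.frame(x)
  y$value <- round(y$value, digits)
  y$lower <- round(y$lower, digits)
  y$upper <- round(y$upper, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Probability calibration report
#'
#' Bins predictions into equal-width probability bins and compares mean
#' predicted probability with observed event frequency per bin. The
#' calibration deviation is the unweighted mean absolute gap over non-empty
#' bins; `weighted = TRUE` gives the count-weighted version (expected
#' calibration error). Also reports the Brier score `mean((p - y)^2)`.
#'
#' @param prob predicted probabilities.
#' @param labels binary outcomes (0/1).
#' @param bins number of equal-width bins on \[0, 1\] (default 10).
#' @param weighted count-weight the per-bin deviations (ECE) instead of the
#'   unweighted mean.
#' @return An object of class `"calibration_report"`: list with `bins` (data
#'   frame of bin edges, mean predicted, observed frequency, count),
#'   `deviation`, `brier`, `weighted`.
#' @export
calibration_report <- function(prob, labels, bins = 10L, weighted = FALSE) {
  stopifnot(length(prob) >= 1L, bins >= 2L)
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(findInterval(prob, edges, rightmost.closed = TRUE), bins)
  tab <- lapply(seq_len(bins), function(b) {
    sel <- idx == b
    data.frame(
      lower = edges[b], upper = edges[b + 1L], count = sum(sel),
      mean_pred = if (any(sel)) mean(prob[sel]) else NA_real_,
      obs_freq = if (any(sel)) mean(labels[sel]) else NA_real_
    )
  })
  tab <- do.call(rbind, tab)
  nonempty <- tab$count > 0L
  gaps <- abs(tab$mean_pred[nonempty] - tab$obs_freq[nonempty])
  deviation <- if (weighted) {
    sum(gaps * tab$count[nonempty]) / sum(tab$count[nonempty])
  } else {
    mean(gaps)
  }
  structure(
    list(bins = tab, deviation = deviation,
         brier = mean((prob - labels)^2), weighted = weighted),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration: %s deviation %.4f, Brier score %.4f\n",
              if (x$weighted) "count-weighted (ECE)" else "unweighted",
              x$deviation, x$brier))
  print(transform(x$bins, mean_pred = round(mean_pred, 3),
                  obs_freq = round(obs_freq, 3)), row.names = FALSE)
  invisible(x)
}
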