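# Explainability layer: exact additive attributions for the NAM, a
# brute-force Shapley oracle for verification, global and class-wise
# importance summaries, and per-subject contribution reports.
#
# Attributions live on the logit scale: a positive value pushes the
# prediction toward label 1 (case), a negative value toward label 0
# (control).

#' Exact additive feature attributions
#'
#' For an additive model the attribution of feature `i` is its centered shape
#' value: `phi_i(x) = f_i(x_i) - mean over the reference of f_i`. The base
#' value is `bias + sum_i mean reference f_i`, so
#' `base + sum_i phi_i = logit` holds exactly for every sample. The default
#' reference is the model's training set, matching the fit-on-training-only
#' hygiene of the standardizer.
#'
#' @param object a fitted `"nam"`.
#' @param newdata samples to explain (default: training data).
#' @param reference reference population (data frame/matrix on the raw
#'   scale, like `newdata`); default the stored training rows.
#' @return An object of class `"nam_attributions"`: list with `phi` (n x p
#'   matrix), `base_value`, `logit`, `prob`, `features`, and the raw
#'   (unstandardized is not kept) standardized sample values `z`.
#' @export
attributions <- function(object, newdata = NULL, reference = NULL) {
  stopifnot(inherits(object, "nam"))
  xs <- standardized_input(object, newdata)
  ref <- if (is.null(reference)) {
    if (is.null(object$x_train)) {
      stop("model carries no training data; supply `reference`",
           call. = FALSE)
    }
    object$x_train
  } else {
    standardized_input(object, reference)
  }
  if (nrow(ref) == 0L) stop("reference must be non-empty", call. = FALSE)

  fx <- nam_forward(object$params, xs)
  fref <- nam_forward(object$params, ref)
  ref_means <- colMeans(fref$contributions)
  phi <- sweep(fx$contributions, 2, ref_means)
  base_value <- object$params$bias + sum(ref_means)
  structure(
    list(phi = phi, base_value = base_value, logit = fx$logit,
         prob = fx$prob, features = object$feature_names, z = xs),
    class = "nam_attributions"
  )
}

#' @export
print.nam_attributions <- function(x, ...) {
  cat(sprintf("Additive attributions: %d samples x %d features (logit scale)\n",
              nrow(x$phi), ncol(x$phi)))
  cat(sprintf("  base value: %.4f; mean |phi| range: %.4f .. %.4f\n",
              x$base_value, min(colMeans(abs(x$phi))),
              max(colMeans(abs(x$phi)))))
  invisible(x)
}

#' Exact Shapley values by coalition enumeration
#'
#' Interventional Shapley values of a black-box scalar function, computed by
#' full enumeration over all `2^p` coalitions: features absent from a
#' coalition are replaced by background rows and the value function is the
#' mean prediction over the background. Satisfies efficiency:
#' `sum(phi) = f(row) - mean f(background)`. Intended as a testing oracle;
#' guarded against combinatorial blow-up by `p_max`.
#'
#' @param predict_fn function taking a numeric matrix and returning a numeric
#'   vector (one value per row), e.g. a logit.
#' @param row numeric vector: the sample to explain.
#' @param background numeric matrix of reference rows.
#' @param p_max maximum number of features allowed (default 10).
#' @return Numeric vector of Shapley values, one per feature.
#' @export
shapley_enumeration_oracle <- function(predict_fn, row, background,
                                       p_max = 10L) {
  background <- as.matrix(background)
  p <- length(row)
  if (p > p_max) {
    stop(sprintf("p = %d exceeds p_max = %d (2^p coalitions)", p, p_max),
         call. = FALSE)
  }
  nb <- nrow(background)
  n_coal <- 2L^p
  # value function for every coalition mask (bit i set = feature i present)
  v <- numeric(n_coal)
  for (mask in 0:(n_coal - 1L)) {
    present <- bitwAnd(bitwShiftR(mask, 0:(p - 1L)), 1L) == 1L
    x <- background
    if (any(present)) {
      x[, present] <- matrix(row[present], nb, sum(present), byrow = TRUE)
    }
    v[mask + 1L] <- mean(predict_fn(x))
  }
  fact <- factorial(0:p)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(n_coal - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(bitwAnd(bitwShiftR(mask, 0:(p - 1L)), 1L))
      w <- fact[s + 1L] * fact[p - s] / fact[p + 1L]
      phi[i] <- phi[i] + w * (v[bitwOr(mask, bit) + 1L] - v[mask + 1L])
    }
  }
  phi
}

#' Global feature importance with bootstrap confidence intervals
#'
#' Importance of a feature is the mean absolute attribution over samples;
#' confidence intervals come from resampling samples with replacement.
#' Features are ranked in descending order of importance.
#'
#' @param attrs a `"nam_attributions"` object.
#' @param n_boot bootstrap iterations (default 1000).
#' @param level confidence level.
#' @param seed integer seed.
#' @return A data frame with columns `feature`, `importance`, `lower`,
#'   `upper`, `rank`, ordered by rank.
#' @export
global_importance <- function(attrs, n_boot = 1000L, level = 0.95,
                              seed = 1L) {
  stopifnot(inherits(attrs, "nam_attributions"))
  phi <- attrs$phi
  n <- nrow(phi)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  point <- colMeans(abs(phi))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      colMeans(abs(phi[idx, , drop = FALSE]))
    }, numeric(ncol(phi)))
  })
  lower <- apply(boot, 1, stats::quantile, probs = (1 - level) / 2)
  upper <- apply(boot, 1, stats::quantile, probs = (1 + level) / 2)
  out <- data.frame(feature = attrs$features, importance = point,
                    lower = lower, upper = upper,
                    rank = rank(-point, ties.method = "first"),
                    row.names = NULL)
  out[order(out$rank), ]
}

#' NAM-intrinsic feature importance
#'
#' Mean absolute centered subnetwork output per feature,
#' `mean |f_i(x_i) - mean f_i|`, normalized to sum to one across features.
#' For a NAM this ranks features identically to mean-|phi| attribution
#' importance computed on the same rows (the two differ only by the common
#' normalization).
#'
#' @param object a fitted `"nam"`.
#' @param newdata rows to evaluate on (default: training data).
#' @return Named numeric vector summing to 1.
#' @export
intrinsic_importance <- function(object, newdata = NULL) {
  stopifnot(inherits(object, "nam"))
  xs <- standardized_input(object, newdata)
  fx <- nam_forward(object$params, xs)
  centered <- sweep(fx$contributions, 2, colMeans(fx$contributions))
  raw <- colMeans(abs(centered))
  total <- sum(raw)
  if (total < 1e-12) {
    warning("all subnetworks are constant; returning uniform importance")
    return(stats::setNames(rep(1 / length(raw), length(raw)),
                           object$feature_names))
  }
  stats::setNames(raw / total, object$feature_names)
}

#' Compare intrinsic and attribution-based importance
#'
#' @param object a fitted `"nam"`.
#' @param newdata rows to evaluate on (default: training data).
#' @return A data frame with both importance vectors, their ranks, and the
#'   Spearman rank concordance as attribute `"concordance"`.
#' @export
importance_comparison <- function(object, newdata = NULL) {
  intrinsic <- intrinsic_importance(object, newdata)
  attrs <- attributions(object, newdata)
  attr_imp <- colMeans(abs(attrs$phi))
  out <- data.frame(
    feature = object$feature_names,
    nam_importance = unname(intrinsic),
    attribution_importance = unname(attr_imp),
    nam_rank = rank(-intrinsic, ties.method = "first"),
    attribution_rank = rank(-attr_imp, ties.method = "first"),
    row.names = NULL
  )
  attr(out, "concordance") <- stats::cor(out$nam_rank, out$attribution_rank,
                                         method = "spearman")
  out[order(out$nam_rank), ]
}

#' Class-wise attribution summary
#'
#' Per feature and class: mean and standard deviation of attributions and of
#' the standardized feature values, quantifying how each feature pushes
#' predictions in cases versus controls.
#'
#' @param attrs a `"nam_attributions"` object.
#' @param labels binary outcomes aligned with the attributed samples.
#' @return A data frame (class `"classwise_report"`) with one row per
#'   feature x class.
#' @export
classwise_summary <- function(attrs, labels) {
  stopifnot(inherits(attrs, "nam_attributions"))
  if (length(labels) != nrow(attrs$phi)) {
    stop("labels do not align with attributions", call. = FALSE)
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  rows <- lapply(classes, function(cl) {
    sel <- labels == cl
    data.frame(
      feature = attrs$features,
      class = cl,
      mean_phi = colMeans(attrs$phi[sel, , drop = FALSE]),
      sd_phi = apply(attrs$phi[sel, , drop = FALSE], 2, stats::sd),
      mean_value = colMeans(attrs$z[sel, , drop = FALSE]),
      sd_value = apply(attrs$z[sel, , drop = FALSE], 2, stats::sd),
      row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("classwise_report", class(out))
  out
}

#' Per-subject contribution report
#'
#' Lists the per-feature contributions for one sample, ordered by decreasing
#' absolute value, annotated with the direction they push the prediction
#' (toward case or toward control). The listed contributions plus the base
#' value sum to the sample's logit.
#'
#' @param attrs a `"nam_attributions"` object.
#' @param sample sample index.
#' @param top_k how many features to list (default: all).
#' @return A data frame (class `"sample_report"`) with columns `feature`,
#'   `phi`, `value` (standardized feature value), `direction`; attributes
#'   `base_value`, `logit`, `prob`, `sample`.
#' @export
explain_sample <- function(attrs, sample, top_k = Inf) {
  stopifnot(inherits(attrs, "nam_attributions"))
  n <- nrow(attrs$phi)
  if (sample < 1 || sample > n) {
    stop("sample index out of range: ", sample, call. = FALSE)
  }
  phi <- attrs$phi[sample, ]
  ord <- order(-abs(phi))
  k <- min(top_k, length(phi))
  out <- data.frame(
    feature = attrs$features[ord][seq_len(k)],
    phi = unname(phi[ord])[seq_len(k)],
    value = unname(attrs$z[sample, ord])[seq_len(k)],
    direction = ifelse(phi[ord] >= 0, "toward case",
                       "toward control")[seq_len(k)],
    row.names = NULL
  )
  attr(out, "base_value") <- attrs$base_value
  attr(out, "logit") <- attrs$logit[sample]
  attr(out, "prob") <- attrs$prob[sample]
  attr(out, "sample") <- sample
  class(out) <- c("sample_report", class(out))
  out
}

#' @export
print.sample_report <- function(x, digits = 3, ...) {
  cat(sprintf("Sample %d: logit %.3f (base %.3f), P(case) = %.3f\n",
              attr(x, "sample"), attr(x, "logit"), attr(x, "base_value"),
              attr(x, "prob")))
  y <- as.data.frame(x)
  y$phi <- round(y$phi, digits)
  y$value <- round(y$value, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
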