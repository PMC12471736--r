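# Metric suite, ROC AUC, percentile bootstrap, calibration.

test_that("confusion matrix counts and tie rule", {
  cm <- confusion_at_threshold(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unclass(cm)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 0L, FN = 0L, TN = 1L), ignore_attr = TRUE)
  # scores exactly at the threshold count positive
  cm2 <- confusion_at_threshold(c(0.5, 0.49), c(1, 1), 0.5)
  expect_equal(cm2$TP, 1L)
  expect_equal(cm2$FN, 1L)

  # 10-row fixture against a hand tally
  p <- c(0.9, 0.8, 0.3, 0.6, 0.2, 0.7, 0.4, 0.55, 0.1, 0.5)
  y <- c(1,   1,   1,   0,   0,   1,   0,   1,    0,   0)
  cm3 <- confusion_at_threshold(p, y, 0.5)
  expect_equal(c(cm3$TP, cm3$FP, cm3$FN, cm3$TN), c(4L, 2L, 1L, 3L))

  expect_error(confusion_at_threshold(numeric(0), numeric(0)), "empty")
})

test_that("metric formulas match direct arithmetic", {
  perfect <- compute_metrics(confusion_at_threshold(c(rep(0.9, 5), rep(0.1, 5)),
                                                    rep(c(1, 0), each = 5)))
  expect_true(all(perfect[c("accuracy", "sensitivity", "specificity",
                            "f1", "mcc")] == 1))

  cm <- structure(list(TP = 90, FP = 20, FN = 10, TN = 80),
                  class = "confusion_matrix")
  m <- compute_metrics(cm)
  expect_equal(m[["sensitivity"]], 0.9)
  expect_equal(m[["specificity"]], 0.8)
  expect_equal(m[["accuracy"]], 0.85)
  expect_equal(m[["ppv"]], 0.818182, tolerance = 1e-6)
  expect_equal(m[["f1"]], 0.857143, tolerance = 1e-6)
  expect_equal(m[["mcc"]], 0.703526, tolerance = 1e-6)
  expect_equal(m[["lr_plus"]], 4.5)
  expect_equal(m[["lr_minus"]], 0.125)

  # balanced accuracy of (0.957, 0.928) prints as 0.942
  cm2 <- structure(list(TP = 957, FN = 43, TN = 928, FP = 72),
                   class = "confusion_matrix")
  m2 <- compute_metrics(cm2)
  expect_equal(m2[["balanced_accuracy"]], 0.9425)
  # agrees with the printed three-decimal value up to half an ulp of print
  expect_lt(abs(m2[["balanced_accuracy"]] - 0.942), 5.1e-4)
})

test_that("undefined metric quotients propagate as NA, not 0 or Inf", {
  cm <- structure(list(TP = 5, FP = 0, FN = 0, TN = 5),
                  class = "confusion_matrix")
  m <- compute_metrics(cm)
  expect_true(is.na(m[["lr_plus"]]))   # specificity 1
  cm2 <- structure(list(TP = 0, FP = 0, FN = 5, TN = 5),
                   class = "confusion_matrix")
  m2 <- compute_metrics(cm2)
  expect_true(is.na(m2[["ppv"]]))      # no predicted positives
})

test_that("metric identities hold on random confusion matrices", {
  hemanam:::with_seed(7, {
    for (i in 1:200) {
      cnt <- stats::rmultinom(1, size = sample(20:500, 1), prob = rep(1/4, 4))
      cm <- structure(list(TP = cnt[1], FP = cnt[2], FN = cnt[3], TN = cnt[4]),
                      class = "confusion_matrix")
      m <- compute_metrics(cm)
      if (!is.na(m[["balanced_accuracy"]])) {
        expect_equal(m[["balanced_accuracy"]],
                     (m[["sensitivity"]] + m[["specificity"]]) / 2)
      }
      if (!is.na(m[["lr_plus"]])) {
        expect_equal(m[["lr_plus"]] * (1 - m[["specificity"]]),
                     m[["sensitivity"]])
      }
      if (!is.na(m[["f1"]])) {
        expect_equal(m[["f1"]],
                     2 / (1 / m[["ppv"]] + 1 / m[["sensitivity"]]))
      }
      # MCC invariance under class swap; negation under prediction flip
      swap <- structure(list(TP = cm$TN, FP = cm$FN, FN = cm$FP, TN = cm$TP),
                        class = "confusion_matrix")
      flip <- structure(list(TP = cm$FN, FP = cm$TN, FN = cm$TP, TN = cm$FP),
                        class = "confusion_matrix")
      if (!is.na(m[["mcc"]])) {
        expect_equal(compute_metrics(swap)[["mcc"]], m[["mcc"]])
        expect_equal(compute_metrics(flip)[["mcc"]], -m[["mcc"]])
      }
    }
  })
})

test_that("rank-statistic AUC equals pair enumeration and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")

  pair_auc <- function(p, y) {   # exhaustive concordant-pair oracle
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  hemanam:::with_seed(9, {
    for (i in 1:20) {
      n <- sample(5:50, 1)
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
      p <- round(stats::runif(n), 2)   # rounding forces ties
      expect_equal(roc_auc(p, y), pair_auc(p, y))
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  hemanam:::with_seed(14, {
    y <- stats::rbinom(200, 1, 0.45)
    p <- stats::plogis(stats::rnorm(200) + y)
  })
  ref <- as.numeric(suppressMessages(pROC::auc(y, p)))
  expect_equal(roc_auc(p, y), ref, tolerance = 1e-12)
})

test_that("percentile bootstrap matches an independent seeded oracle", {
  hemanam:::with_seed(33, {
    y <- stats::rbinom(50, 1, 0.5)
    p <- stats::runif(50)
  })
  ci <- bootstrap_ci(p, y, "accuracy", n_boot = 200, seed = 77)
  # independent re-implementation with the same RNG contract
  oracle <- local({
    set.seed(77L)
    stats <- replicate(200, {
      idx <- sample.int(50, 50, replace = TRUE)
      mean((p[idx] >= 0.5) == (y[idx] == 1))
    })
    stats::quantile(stats, c(0.025, 0.975), names = FALSE)
  })
  expect_equal(c(ci$lower, ci$upper), oracle)
  expect_equal(ci$point, mean((p >= 0.5) == (y == 1)))
})

test_that("bootstrap interval brackets the point and degenerates correctly", {
  # all predictions correct -> CI [1, 1]
  ci <- bootstrap_ci(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), "accuracy",
                     n_boot = 100, seed = 1)
  expect_equal(c(ci$point, ci$lower, ci$upper), c(1, 1, 1))

  hemanam:::with_seed(55, {
    for (i in 1:50) {
      n <- sample(20:80, 1)
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
      p <- stats::runif(n)
      ci <- bootstrap_ci(p, y, "accuracy", n_boot = 100, seed = i)
      expect_lte(ci$lower, ci$point + 1e-12)
      expect_gte(ci$upper, ci$point - 1e-12)
    }
  })
})

test_that("bootstrap CI width shrinks with sample size", {
  width_at <- function(n, seed) {
    hemanam:::with_seed(seed, {
      y <- stats::rbinom(n, 1, 0.5)
      correct <- stats::rbinom(n, 1, 0.8) == 1
      pred <- ifelse(correct, y, 1 - y)
      p <- ifelse(pred == 1, 0.9, 0.1)
    })
    ci <- bootstrap_ci(p, y, "accuracy", n_boot = 300, seed = seed)
    ci$upper - ci$lower
  }
  w <- vapply(c(50, 500, 5000), width_at, 0, seed = 60)
  expect_true(w[1] > w[2] && w[2] > w[3])
})

test_that("iterations with undefined metrics are dropped and counted", {
  # tiny sample with a single positive: many resamples lack a class for AUC
  y <- c(1, 0, 0, 0, 0)
  p <- c(0.9, 0.2, 0.3, 0.1, 0.4)
  ci <- bootstrap_ci(p, y, "roc_auc", n_boot = 300, seed = 5)
  expect_gt(ci$n_dropped, 0)
  expect_lte(ci$upper, 1)
})

test_that("calibration report: analytic cases and hand-computed binning", {
  cal <- calibration_report(rep(0.5, 100), rep(c(0, 1), 50))
  expect_equal(cal$brier, 0.25)
  expect_equal(cal$deviation, 0)

  cal2 <- calibration_report(c(rep(1, 5), rep(0, 5)), rep(c(1, 0), each = 5))
  expect_equal(cal2$brier, 0)
  expect_equal(cal2$deviation, 0)

  # 20-point fixture with 4 bins vs hand-computed bin table
  p <- c(0.05, 0.10, 0.20, 0.24, 0.30, 0.40, 0.45, 0.49, 0.55, 0.60,
         0.65, 0.70, 0.74, 0.80, 0.85, 0.90, 0.95, 0.99, 0.15, 0.35)
  y <- c(0, 0, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 1, 1, 1, 1, 0, 0)
  cal3 <- calibration_report(p, y, bins = 4)
  bin_id <- cut(p, c(0, 0.25, 0.5, 0.75, 1), include.lowest = TRUE)
  hand_pred <- tapply(p, bin_id, mean)
  hand_obs <- tapply(y, bin_id, mean)
  expect_equal(cal3$bins$mean_pred, as.numeric(hand_pred))
  expect_equal(cal3$bins$obs_freq, as.numeric(hand_obs))
  expect_equal(cal3$deviation, mean(abs(hand_pred - hand_obs)))
  expect_equal(cal3$brier, mean((p - y)^2))

  # count-weighted variant (ECE)
  cal4 <- calibration_report(p, y, bins = 4, weighted = TRUE)
  counts <- as.numeric(table(bin_id))
  expect_equal(cal4$deviation,
               sum(abs(hand_pred - hand_obs) * counts) / sum(counts))
})

test_that("calibrated probabilities beat miscalibrated distortions on Brier score", {
  co <- default_cohort(seed = 202, n = 5000)
  y <- co$data$label
  p <- co$prob
  brier <- function(q) mean((q - y)^2)
  sharpen <- p^2 / (p^2 + (1 - p)^2)
  flatten <- 0.5 + 0.25 * (p - 0.5)
  shifted <- pmin(pmax(p + 0.15, 0), 1)
  expect_lt(brier(p), brier(sharpen))
  expect_lt(brier(p), brier(flatten))
  expect_lt(brier(p), brier(shifted))
})

test_that("evaluate_predictions assembles the full suite with CIs", {
  hemanam:::with_seed(70, {
    y <- stats::rbinom(120, 1, 0.5)
    p <- stats::plogis(stats::rnorm(120, mean = 2 * (y - 0.5)))
  })
  rep <- evaluate_predictions(p, y, n_boot = 100, seed = 3)
  expect_setequal(rep$metric,
                  c("accuracy", "balanced_accuracy", "f1", "mcc",
                    "sensitivity", "specificity", "ppv", "npv",
                    "lr_plus", "lr_minus", "roc_auc", "brier"))
  expect_true(all(rep$lower <= rep$value + 1e-12, na.rm = TRUE))
  expect_true(all(rep$upper >= rep$value - 1e-12, na.rm = TRUE))
})
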