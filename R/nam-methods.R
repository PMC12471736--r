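# S3 methods for fitted "nam" objects.

#' @export
print.nam <- function(x, ...) {
  cat("Neural additive model\n")
  cat("Call: "); print(x$call)
  cat(sprintf("  %d features, subnetworks [%s], dropout %.2f\n",
              length(x$feature_names), paste(x$hidden, collapse = ", "),
              x$control$dropout))
  cat(sprintf("  trained %d epochs (best epoch %d restored), monitor = %s\n",
              x$stop_epoch, x$best_epoch, x$control$monitor))
  cat(sprintf("  global bias: %.4f\n", x$params$bias))
  invisible(x)
}

#' @export
summary.nam <- function(object, ...) {
  imp <- intrinsic_importance(object)
  train_loss <- bce_loss(object$fitted_prob, object$y)
  train_acc <- mean((object$fitted_prob >= 0.5) == (object$y == 1))
  out <- list(
    call = object$call,
    p = length(object$feature_names),
    hidden = object$hidden,
    n = length(object$y),
    bias = object$params$bias,
    best_epoch = object$best_epoch,
    stop_epoch = object$stop_epoch,
    train_loss = train_loss,
    train_accuracy = train_acc,
    importance = sort(imp, decreasing = TRUE)
  )
  class(out) <- "summary.nam"
  out
}

#' @export
print.summary.nam <- function(x, ...) {
  cat("Neural additive model\n")
  cat("Call: "); print(x$call)
  cat(sprintf("  n = %d, p = %d, hidden [%s], bias %.4f\n",
              x$n, x$p, paste(x$hidden, collapse = ", "), x$bias))
  cat(sprintf("  epochs: stopped at %d, best %d; training loss %.4f, accuracy %.3f\n",
              x$stop_epoch, x$best_epoch, x$train_loss, x$train_accuracy))
  cat("  intrinsic feature importance (normalized mean |centered f_i|):\n")
  print(round(utils::head(x$importance, 10), 4))
  invisible(x)
}

#' @export
coef.nam <- function(object, ...) {
  c(`(bias)` = object$params$bias)
}

#' Predictions from a fitted NAM
#'
#' @param object a fitted `"nam"`.
#' @param newdata data frame or matrix with the model's feature columns (raw
#'   scale if the model stores a standardizer); default: the training data.
#' @param type `"response"` (probability), `"link"` (logit), `"class"`
#'   (0/1 at threshold 0.5), or `"contributions"` (n x p matrix of raw
#'   per-feature logit contributions `f_i(x_i)`, with the global bias as
#'   attribute `"bias"`).
#' @param ... unused.
#' @return Numeric vector, or matrix for `type = "contributions"`.
#' @export
predict.nam <- function(object, newdata = NULL,
                        type = c("response", "link", "class", "contributions"),
                        ...) {
  type <- match.arg(type)
  xs <- standardized_input(object, newdata)
  fwd <- nam_forward(object$params, xs)
  switch(type,
    response = fwd$prob,
    link = fwd$logit,
    class = as.integer(fwd$prob >= 0.5),
    contributions = structure(fwd$contributions, bias = object$params$bias)
  )
}

# Standardize `newdata` into the model's feature space, validating the schema.
standardized_input <- function(object, newdata = NULL) {
  if (is.null(newdata)) return(object$x_train)
  xm <- as_feature_matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(xm))
  if (length(missing)) {
    stop("newdata lacks feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  xm <- xm[, object$feature_names, drop = FALSE]
  if (!is.null(object$standardizer)) {
    apply_standardizer(object$standardizer, xm)
  } else {
    xm
  }
}

#' @export
fitted.nam <- function(object, ...) object$fitted_prob

#' @export
residuals.nam <- function(object,
                          type = c("deviance", "response", "pearson"), ...) {
  type <- match.arg(type)
  y <- object$y
  p <- pmin(pmax(object$fitted_prob, 1e-12), 1 - 1e-12)
  switch(type,
    response = y - p,
    pearson = (y - p) / sqrt(p * (1 - p)),
    deviance = sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
  )
}

#' Simulate outcomes from a fitted NAM
#'
#' Draws Bernoulli outcomes from the model's predicted probabilities.
#'
#' @param object a fitted `"nam"`.
#' @param nsim number of simulated outcome vectors.
#' @param seed integer seed.
#' @param newdata optional data to predict on (default: training data).
#' @param ... unused.
#' @return A data frame with `nsim` columns of simulated 0/1 outcomes.
#' @export
simulate.nam <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  prob <- predict(object, newdata = newdata, type = "response")
  draw <- function() stats::rbinom(length(prob), 1L, prob)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Learned shape functions on a grid
#'
#' Evaluates each subnetwork over a grid of standardized feature values,
#' giving the model's learned univariate shape functions.
#'
#' @param object a fitted `"nam"`.
#' @param grid numeric vector of standardized feature values (default: 101
#'   points on \[-3, 3\]).
#' @param features which features (names or indices; default all).
#' @return A data frame with columns `feature`, `z` (standardized value),
#'   `raw` (the value on the original scale, if a standardizer is stored)
#'   and `f` (logit contribution).
#' @export
shape_functions <- function(object, grid = seq(-3, 3, length.out = 101L),
                            features = object$feature_names) {
  stopifnot(inherits(object, "nam"))
  if (is.numeric(features)) features <- object$feature_names[features]
  out <- lapply(features, function(f) {
    i <- match(f, object$feature_names)
    fi <- subnet_forward(object$params$sub[[i]], grid)
    raw <- if (!is.null(object$standardizer)) {
      grid * object$standardizer$scale[[f]] + object$standardizer$center[[f]]
    } else {
      grid
    }
    data.frame(feature = f, z = grid, raw = raw, f = fi)
  })
  do.call(rbind, out)
}

#' Plot learned shape functions
#'
#' One panel per feature showing the learned logit contribution as a function
#' of the standardized feature value.
#'
#' @param x a fitted `"nam"`.
#' @param features features to plot (default: the 6 with highest intrinsic
#'   importance).
#' @param grid grid of standardized values.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nam <- function(x, features = NULL,
                     grid = seq(-3, 3, length.out = 101L), ...) {
  if (is.null(features)) {
    imp <- sort(intrinsic_importance(x), decreasing = TRUE)
    features <- names(utils::head(imp, 6L))
  }
  sf <- shape_functions(x, grid = grid, features = features)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(features)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (f in features) {
    d <- sf[sf$feature == f, ]
    graphics::plot(d$z, d$f, type = "l", xlab = "standardized value",
                   ylab = "logit contribution", main = f, ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Save / load a fitted NAM as JSON
#'
#' Serializes the configuration, all subnetwork weights, the global bias,
#' the feature schema and the standardizer to a single JSON checkpoint.
#'
#' @param object a fitted `"nam"`.
#' @param path output file.
#' @return `save_nam`: `path` invisibly. `load_nam`: a `"nam"` object (the
#'   training data and trace are not stored; attribution defaults then
#'   require an explicit reference).
#' @export
save_nam <- function(object, path) {
  stopifnot(inherits(object, "nam"))
  payload <- list(
    package = "hemanam", format = 1L,
    feature_names = object$feature_names,
    hidden = object$hidden,
    control = object$control,
    bias = object$params$bias,
    sub = lapply(object$params$sub, function(s) {
      lapply(s[TENSORS], function(t) {
        if (is.matrix(t)) list(dim = dim(t), data = as.numeric(t))
        else list(dim = length(t), data = as.numeric(t))
      })
    }),
    standardizer = if (is.null(object$standardizer)) NULL else
      unclass(object$standardizer),
    best_epoch = object$best_epoch,
    stop_epoch = object$stop_epoch
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_nam
#' @export
load_nam <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  sub <- lapply(j$sub, function(s) {
    out <- lapply(TENSORS, function(nm) {
      t <- s[[nm]]
      d <- unlist(t$dim)
      v <- as.numeric(unlist(t$data))
      if (length(d) == 2L) matrix(v, d[1], d[2]) else v
    })
    names(out) <- TENSORS
    out$b3 <- as.numeric(out$b3)
    out
  })
  params <- structure(list(sub = sub, bias = as.numeric(j$bias),
                           hidden = as.integer(j$hidden)),
                      class = "nam_params")
  feature_names <- unlist(j$feature_names)
  std <- NULL
  if (!is.null(j$standardizer)) {
    std <- structure(
      list(center = stats::setNames(unlist(j$standardizer$center),
                                    feature_names),
           scale = stats::setNames(unlist(j$standardizer$scale),
                                   feature_names),
           features = unlist(j$standardizer$features)),
      class = "standardizer")
  }
  structure(
    list(params = params, feature_names = feature_names,
         standardizer = std, control = lapply(j$control, unlist),
         hidden = as.integer(unlist(j$hidden)), trace = NULL,
         best_epoch = unlist(j$best_epoch), stop_epoch = unlist(j$stop_epoch),
         x_train = NULL, y = NULL, fitted_prob = NULL,
         call = quote(load_nam())),
    class = "nam"
  )
}
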