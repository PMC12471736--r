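# Core neural-additive-model machinery: one small feed-forward subnetwork
# per feature, summed with a global bias and squashed to a probability.
#
# Each subnetwork maps a single standardized feature value through two hidden
# ReLU layers (defaults 64 and 32 units) with optional inverted dropout, to a
# scalar logit contribution f_i(x_i). The model logit is
# bias + sum_i f_i(x_i), computed literally in that form so the additivity
# identity holds to the last bit.

#' Initialize NAM parameters
#'
#' He-style initialization: weights drawn N(0, 2/fan-in) (appropriate for
#' ReLU units), all offsets zero, global bias zero. Reproducible under
#' `seed`.
#'
#' @param p number of features (one subnetwork each).
#' @param hidden two hidden-layer widths.
#' @param seed integer seed.
#' @return An object of class `"nam_params"`: a list with `sub` (a list of
#'   `p` subnetworks, each with `W1`, `b1`, `W2`, `b2`, `W3`, `b3`) and
#'   scalar `bias`.
#' @export
init_nam <- function(p, hidden = c(64L, 32L), seed = 1L) {
  stopifnot(p >= 1, length(hidden) == 2L, all(hidden >= 1))
  h1 <- as.integer(hidden[1]); h2 <- as.integer(hidden[2])
  with_seed(seed, {
    sub <- lapply(seq_len(p), function(i) {
      list(
        W1 = matrix(stats::rnorm(h1, sd = sqrt(2 / 1)), 1L, h1),
        b1 = numeric(h1),
        W2 = matrix(stats::rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2),
        b2 = numeric(h2),
        W3 = matrix(stats::rnorm(h2, sd = sqrt(2 / h2)), h2, 1L),
        b3 = 0
      )
    })
    structure(list(sub = sub, bias = 0, hidden = c(h1, h2)),
              class = "nam_params")
  })
}

n_subnet_params <- function(hidden) {
  h1 <- hidden[1]; h2 <- hidden[2]
  (h1 + h1) + (h1 * h2 + h2) + (h2 + 1)
}

# Forward pass of one subnetwork on a batch of scalar inputs.
# In training mode, inverted dropout is applied after each hidden ReLU:
# kept units are scaled by 1/(1-rate) so evaluation needs no rescaling.
# `masks` (list of two 0/keep-scaled matrices) can be supplied for testing;
# otherwise they are drawn from the current RNG.
subnet_forward <- function(subnet, x, dropout = 0, training = FALSE,
                           masks = NULL, cache = FALSE) {
  B <- length(x)
  h1 <- length(subnet$b1); h2 <- length(subnet$b2)
  Z1 <- outer(x, drop(subnet$W1)) +
    matrix(subnet$b1, B, h1, byrow = TRUE)
  H1 <- relu(Z1)
  if (training && dropout > 0) {
    if (is.null(masks)) {
      keep <- 1 - dropout
      M1 <- matrix((stats::runif(B * h1) < keep) / keep, B, h1)
      M2 <- matrix((stats::runif(B * h2) < keep) / keep, B, h2)
    } else {
      M1 <- masks[[1]]; M2 <- masks[[2]]
      if (!all(dim(M1) == c(B, h1)) || !all(dim(M2) == c(B, h2))) {
        stop("dropout mask shape mismatch", call. = FALSE)
      }
    }
    H1 <- H1 * M1
  } else {
    M1 <- M2 <- NULL
  }
  Z2 <- H1 %*% subnet$W2 + matrix(subnet$b2, B, h2, byrow = TRUE)
  H2 <- relu(Z2)
  if (!is.null(M2)) H2 <- H2 * M2
  out <- drop(H2 %*% subnet$W3) + subnet$b3
  if (!cache) return(out)
  list(out = out, x = x, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2,
       M1 = M1, M2 = M2)
}

#' Forward pass of a NAM
#'
#' Evaluates every subnetwork on its feature column and assembles the
#' additive prediction. Evaluation mode (`training = FALSE`, the default) is
#' deterministic and dropout-free.
#'
#' @param params a `"nam_params"` object.
#' @param x numeric matrix (rows = samples, one column per subnetwork) or a
#'   single row vector of length `p`.
#' @param training logical; apply dropout masks drawn from the current RNG.
#' @param dropout dropout rate used when `training = TRUE`.
#' @return A list with `contributions` (n x p matrix of `f_i(x_i)`), `logit`
#'   (`bias + rowSums(contributions)`, exactly) and `prob`
#'   (`sigmoid(logit)`).
#' @export
nam_forward <- function(params, x, training = FALSE, dropout = 0) {
  stopifnot(inherits(params, "nam_params"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  p <- length(params$sub)
  if (ncol(x) != p) {
    stop(sprintf("input has %d columns but model has %d subnetworks",
                 ncol(x), p), call. = FALSE)
  }
  contrib <- matrix(NA_real_, nrow(x), p, dimnames = dimnames(x))
  for (i in seq_len(p)) {
    contrib[, i] <- subnet_forward(params$sub[[i]], x[, i],
                                   dropout = dropout, training = training)
  }
  logit <- params$bias + rowSums(contrib)
  list(contributions = contrib, logit = logit, prob = sigmoid(logit))
}
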