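# Explanation layer: exact additive attributions, Shapley enumeration
# oracle, importance reports, class-wise summaries, per-sample reports.

test_that("attributions of an all-zero network are zero with base = bias", {
  x <- rand_mat(10, 3, seed = 1)
  fit <- make_fit(replicate(3, constant_subnet(0, 2, 2), simplify = FALSE),
                  bias = 0.7, x_train = x)
  at <- attributions(fit)
  expect_true(all(at$phi == 0))
  expect_equal(at$base_value, 0.7)
  expect_equal(unname(at$logit), rep(0.7, 10))
})

test_that("identity subnetwork with zero-mean reference attributes phi = z", {
  x <- rand_mat(50, 1, seed = 2)
  x[, 1] <- x[, 1] - mean(x[, 1])
  fit <- make_fit(list(identity_subnet()), bias = 0, x_train = x)
  at <- attributions(fit)
  expect_equal(unname(at$phi[, 1]), unname(x[, 1]))
  expect_equal(at$base_value, 0)
})

test_that("attributions equal a direct recomputation of centered shape values", {
  params <- random_params(3, seed = 21)
  ref <- rand_mat(5, 3, seed = 3)
  new <- rand_mat(8, 3, seed = 4)
  fit <- make_fit(params$sub, bias = params$bias, x_train = ref)
  at <- attributions(fit, newdata = new)
  direct <- nam_forward(params, new)$contributions
  ref_means <- colMeans(nam_forward(params, ref)$contributions)
  expect_equal(at$phi, sweep(direct, 2, ref_means), tolerance = 1e-12)
  # efficiency: base + sum(phi) = logit, for every sample
  expect_equal(unname(at$base_value + rowSums(at$phi)), unname(at$logit),
               tolerance = 1e-12)
})

test_that("Shapley enumeration oracle: efficiency and degenerate models", {
  bg <- rand_mat(15, 1, seed = 5)
  f1 <- function(m) 2 * m[, 1] + 1
  phi <- shapley_enumeration_oracle(f1, row = 3, background = bg)
  expect_equal(phi, f1(matrix(3)) - mean(f1(bg)))

  fconst <- function(m) rep(4.2, nrow(m))
  bg3 <- rand_mat(10, 3, seed = 6)
  expect_equal(shapley_enumeration_oracle(fconst, c(1, 2, 3), bg3),
               rep(0, 3))

  expect_error(
    shapley_enumeration_oracle(fconst, rep(0, 12), rand_mat(5, 12, seed = 1)),
    "p_max")
})

test_that("for additive models the Shapley oracle equals centered attributions", {
  for (p in c(3L, 6L)) {
    params <- random_params(p, seed = 30 + p)
    bg <- rand_mat(20, p, seed = 40 + p)
    row <- rand_mat(1, p, seed = 50 + p)[1, ]
    fit <- make_fit(params$sub, bias = params$bias, x_train = bg)
    at <- attributions(fit, newdata = matrix(row, 1,
                                             dimnames = list(NULL, names(row))))
    predict_fn <- function(m) nam_forward(params, m)$logit
    phi <- shapley_enumeration_oracle(predict_fn, row, bg, p_max = 6)
    expect_equal(unname(at$phi[1, ]), phi, tolerance = 1e-9)
    # efficiency of the oracle itself
    expect_equal(sum(phi), predict_fn(matrix(row, 1)) - mean(predict_fn(bg)),
                 tolerance = 1e-9)
  }
})

test_that("symmetric features receive identical attributions", {
  s <- identity_subnet(1.5)
  x <- cbind(a = c(1, -2, 0.5), b = c(1, -2, 0.5))
  fit <- make_fit(list(s, s), bias = 0, x_train = x)
  at <- attributions(fit)
  expect_identical(at$phi[, 1], at$phi[, 2])
})

test_that("global importance ranks by mean |phi| with valid bootstrap intervals", {
  params <- random_params(4, seed = 8)
  x <- rand_mat(60, 4, seed = 9)
  fit <- make_fit(params$sub, bias = 0, x_train = x)
  at <- attributions(fit)
  gi <- global_importance(at, n_boot = 100, seed = 2)
  expect_equal(sort(gi$rank), 1:4)
  expect_equal(gi$importance, sort(colMeans(abs(at$phi)), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_true(all(gi$lower <= gi$importance & gi$importance <= gi$upper))

  # duplicating every sample leaves point importances unchanged
  at2 <- attributions(fit, newdata = x[rep(1:60, 2), ])
  gi2 <- global_importance(at2, n_boot = 50, seed = 2)
  expect_equal(gi2$importance[order(gi2$feature)],
               gi$importance[order(gi$feature)])

  zero_fit <- make_fit(replicate(2, constant_subnet(1, 2, 2),
                                 simplify = FALSE),
                       bias = 0, x_train = rand_mat(10, 2, seed = 1))
  gi0 <- global_importance(attributions(zero_fit), n_boot = 20, seed = 1)
  expect_true(all(gi0$importance == 0))
})

test_that("intrinsic importance normalizes to one and matches analytic ratios", {
  # two linear subnetworks with slopes 2 and 1 reading the same values:
  # importances exactly (2/3, 1/3)
  x <- rand_mat(200, 2, seed = 12)
  x[, 2] <- x[, 1]
  fit <- make_fit(list(identity_subnet(2), identity_subnet(1)), bias = 0,
                  x_train = x)
  imp <- intrinsic_importance(fit)
  expect_equal(sum(imp), 1)
  expect_equal(unname(imp), c(2 / 3, 1 / 3), tolerance = 1e-12)

  # a dead subnetwork gets zero importance
  fit2 <- make_fit(list(identity_subnet(1), constant_subnet(5, 2, 2)),
                   bias = 0, x_train = x)
  expect_equal(unname(intrinsic_importance(fit2))[2], 0)

  # degenerate all-constant model: uniform with a warning
  fit3 <- make_fit(replicate(3, constant_subnet(1, 2, 2), simplify = FALSE),
                   bias = 0, x_train = rand_mat(10, 3, seed = 2))
  expect_warning(u <- intrinsic_importance(fit3), "constant")
  expect_equal(unname(u), rep(1 / 3, 3))
})

test_that("intrinsic and attribution-based importance rank features identically", {
  params <- random_params(5, seed = 77)
  x <- rand_mat(80, 5, seed = 78)
  fit <- make_fit(params$sub, bias = 0.3, x_train = x)
  cmp <- importance_comparison(fit)
  expect_identical(cmp$nam_rank, cmp$attribution_rank)
  expect_equal(attr(cmp, "concordance"), 1)
})

test_that("class-wise summaries partition samples and match direct group means", {
  params <- random_params(3, seed = 15)
  x <- rand_mat(40, 3, seed = 16)
  y <- rep(c(0, 1), 20)
  fit <- make_fit(params$sub, bias = 0, x_train = x, y = y)
  at <- attributions(fit)
  cw <- classwise_summary(at, y)
  expect_equal(nrow(cw), 6L)
  direct <- colMeans(at$phi[y == 1, ])
  expect_equal(cw$mean_phi[cw$class == 1], unname(direct))
  expect_error(classwise_summary(at, rep(1, 40)), "both classes")
  expect_error(classwise_summary(at, y[1:10]), "align")
})

test_that("per-sample reports order by magnitude and satisfy the sum rule", {
  s <- list(identity_subnet(1), identity_subnet(1), identity_subnet(1))
  x <- rbind(c(0.5, -2, 0.1), c(1, 1, 1))
  colnames(x) <- c("a", "b", "c")
  fit <- make_fit(s, bias = 0.25, x_train = x)
  at <- attributions(fit)
  rep1 <- explain_sample(at, 1)
  # phi for sample 1 = x1 - colMeans = (-0.25, -1.5, -0.45)
  expect_equal(rep1$feature, c("b", "c", "a"))
  expect_equal(attr(rep1, "base_value") + sum(rep1$phi),
               attr(rep1, "logit"), tolerance = 1e-12)
  expect_equal(nrow(explain_sample(at, 1, top_k = 99)), 3L)
  expect_equal(nrow(explain_sample(at, 1, top_k = 2)), 2L)
  expect_error(explain_sample(at, 7), "out of range")

  # directions are annotated by sign
  expect_true(all(rep1$direction[rep1$phi < 0] == "toward control"))
})

test_that("a fixed 3-feature attribution vector is ordered as a hand sort", {
  # phi = (0.5, -2, 0.1) must list as -2, 0.5, 0.1 (decreasing |value|)
  at <- structure(
    list(phi = matrix(c(0.5, -2, 0.1), 1,
                      dimnames = list(NULL, c("f1", "f2", "f3"))),
         base_value = 1, logit = 1 + 0.5 - 2 + 0.1, prob = 0.4,
         features = c("f1", "f2", "f3"),
         z = matrix(0, 1, 3, dimnames = list(NULL, c("f1", "f2", "f3")))),
    class = "nam_attributions")
  r <- explain_sample(at, 1)
  expect_equal(r$phi, c(-2, 0.5, 0.1))
})
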