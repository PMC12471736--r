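# Shared fixtures. Heavy objects (trained models) are built lazily and
# cached for the whole test session.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# ---- hand-built subnetworks ------------------------------------------------

# subnet with all-zero weights and a constant output offset
constant_subnet <- function(c0 = 0, h1 = 2L, h2 = 2L) {
  list(W1 = matrix(0, 1, h1), b1 = numeric(h1),
       W2 = matrix(0, h1, h2), b2 = numeric(h2),
       W3 = matrix(0, h2, 1), b3 = c0)
}

# f(x) = scale * x, via ReLU(x) - ReLU(-x) passed through identity layers
identity_subnet <- function(scale = 1) {
  list(W1 = matrix(c(1, -1), 1, 2), b1 = c(0, 0),
       W2 = diag(2), b2 = c(0, 0),
       W3 = matrix(c(scale, -scale), 2, 1), b3 = 0)
}

# f(x) = ReLU(x), single unit per layer
relu_subnet <- function() {
  list(W1 = matrix(1, 1, 1), b1 = 0,
       W2 = matrix(1, 1, 1), b2 = 0,
       W3 = matrix(1, 1, 1), b3 = 0)
}

# assemble a nam_params object from a list of subnets
make_params <- function(subnets, bias = 0) {
  h <- c(length(subnets[[1]]$b1), length(subnets[[1]]$b2))
  structure(list(sub = subnets, bias = bias, hidden = h),
            class = "nam_params")
}

# a fitted-model shell around hand-built params (no standardizer), so the
# explanation layer can be driven with exactly known shape functions
make_fit <- function(subnets, bias = 0, x_train, y = NULL) {
  params <- make_params(subnets, bias)
  fwd <- nam_forward(params, x_train)
  structure(
    list(params = params,
         feature_names = colnames(x_train),
         standardizer = NULL, control = list(dropout = 0, monitor = "val_loss"),
         hidden = params$hidden, trace = NULL, best_epoch = 0L, stop_epoch = 0L,
         x_train = x_train, y = y, fitted_prob = fwd$prob,
         call = quote(make_fit())),
    class = "nam"
  )
}

random_params <- function(p, hidden = c(6L, 4L), seed = 1) {
  init_nam(p, hidden = hidden, seed = seed)
}

rand_mat <- function(n, p, seed = 1) {
  hemanam:::with_seed(seed, matrix(stats::rnorm(n * p), n, p,
                                   dimnames = list(NULL, paste0("x", 1:p))))
}

# ---- cohorts and trained models -------------------------------------------

default_cohort <- function(seed = 101, n = 2000) {
  get_fixture(sprintf("cohort_%d_%d", seed, n), function() {
    generate_cohort(hematology_spec(seed = 1), n = n, seed = seed)
  })
}

# Full planted-signal experiment at the default study conditions: generate
# n = 2000, stratified 80/20 split, train with default protocol, measure
# test metrics, shape-recovery correlations and importance ranks.
recovery_run <- function(seed) {
  get_fixture(sprintf("recovery_%d", seed), function() {
    cohort <- generate_cohort(hematology_spec(seed = 1), n = 2000,
                              seed = seed)
    split <- stratified_split(cohort$data$label, 0.2, seed = seed)
    train <- cohort$data[split$train, ]
    test <- cohort$data[split$test, ]
    fit <- nam(label ~ ., train, seed = seed)
    prob <- predict(fit, test)
    metrics <- compute_metrics(confusion_at_threshold(prob, test$label))

    gt <- cohort$ground_truth
    corr <- vapply(gt$active, function(f) {
      fs <- cohort$spec$features[[f]]
      mom <- hemanam:::feature_moments(fs)
      qs <- stats::quantile(cohort$data[[f]], c(0.01, 0.99))
      raw <- seq(qs[1], qs[2], length.out = 101)
      g <- true_shape_values(gt, f, (raw - mom$mean) / mom$sd)
      zm <- (raw - fit$standardizer$center[[f]]) /
        fit$standardizer$scale[[f]]
      i <- match(f, fit$feature_names)
      stats::cor(hemanam:::subnet_forward(fit$params$sub[[i]], zm), g)
    }, 0)

    attrs <- attributions(fit, newdata = test)
    imp <- global_importance(attrs, n_boot = 200, seed = seed)
    list(fit = fit, cohort = cohort, test = test, prob = prob,
         metrics = metrics, shape_corr = corr,
         top5 = utils::head(imp$feature, 5), importance = imp)
  })
}

# small 1-D cohort that is perfectly separated at x = 0
separated_1d <- function(n = 500, seed = 3) {
  hemanam:::with_seed(seed, {
    x <- matrix(stats::rnorm(n), ncol = 1, dimnames = list(NULL, "x1"))
    list(x = x, y = as.numeric(x[, 1] > 0))
  })
}

# small fit used for trace/scheduler assertions
small_trace_fit <- function() {
  get_fixture("small_trace_fit", function() {
    d <- separated_1d(400, seed = 3)
    nam(d$x, d$y, hidden = c(8L, 4L), max_epochs = 40L, patience = 12L,
        scheduler_patience = 3L, batch_size = 64L, seed = 7, dropout = 0.1)
  })
}
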