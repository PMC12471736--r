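# Cohort table I/O, validation, ratio derivation, stratified splitting and
# train-only Z-score standardization.

#' Read and validate a cohort CSV
#'
#' Reads a one-row-per-subject CSV with a header, validates that the label
#' column is present and binary (0 = control, 1 = case), that every predictor
#' is numeric, and that there are no missing values. Missing or non-numeric
#' cells are a hard error naming the offending row and column; no imputation
#' is performed.
#'
#' @param path CSV file path.
#' @param label_column name of the outcome column (default `"label"`).
#' @return A validated data frame (predictors plus the label column).
#' @export
read_cohort <- function(path, label_column = "label") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  validate_cohort(df, label_column)
}

#' @rdname read_cohort
#' @param table a data frame to validate in place of a file.
#' @export
validate_cohort <- function(table, label_column = "label") {
  stopifnot(is.data.frame(table))
  if (!label_column %in% names(table)) {
    stop("label column `", label_column, "` not found", call. = FALSE)
  }
  if (anyDuplicated(names(table))) {
    stop("duplicated column names in cohort table", call. = FALSE)
  }
  lab <- table[[label_column]]
  if (!all(lab %in% c(0, 1))) {
    stop("labels must be 0 (control) or 1 (case)", call. = FALSE)
  }
  for (col in setdiff(names(table), label_column)) {
    v <- table[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric predictor cell: column `%s`, row %s",
                   col, bad %||% "?"), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value: column `%s`, row %d", col,
                   which(is.na(v))[1]), call. = FALSE)
    }
  }
  if (anyNA(lab)) {
    stop("missing value in label column, row ", which(is.na(lab))[1],
         call. = FALSE)
  }
  table
}

#' Derive ratio columns
#'
#' Adds any absent derived index (NEU/LY, PLT/LY, MPV/LY, LY/MO) as the exact
#' elementwise quotient of its component columns. Ratio columns already
#' present are left untouched.
#'
#' @param table a cohort data frame containing the component columns.
#' @return The table with all four ratio columns present.
#' @export
derive_ratios <- function(table) {
  stopifnot(is.data.frame(table))
  for (r in names(RATIO_DEFS)) {
    if (r %in% names(table)) next
    parts <- RATIO_DEFS[[r]]
    missing <- setdiff(parts, names(table))
    if (length(missing)) {
      stop("cannot derive `", r, "`: missing column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    den <- table[[parts[2]]]
    if (any(den == 0)) {
      stop("zero denominator for `", r, "` in row(s) ",
           paste(utils::head(which(den == 0), 5), collapse = ", "),
           call. = FALSE)
    }
    table[[r]] <- table[[parts[1]]] / den
  }
  table
}

#' Stratified train/test split
#'
#' Splits row indices into train and test sets, preserving class balance.
#' Per-class test-set sizes follow largest-remainder apportionment of
#' `test_fraction` (total test size `round(n * test_fraction)`; each class
#' gets the floor of its quota, and leftover seats go to the classes with the
#' largest fractional remainders, larger class first on ties). Within-class
#' selection is uniform at random under `seed`.
#'
#' @param labels binary vector of class labels (0/1).
#' @param test_fraction fraction of rows assigned to the test set.
#' @param seed integer seed.
#' @return An object of class `"split_assignment"`: list with integer vectors
#'   `train` and `test`, plus `seed` and `test_fraction`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  check_scalar(test_fraction, "test_fraction", lower = 1e-12, upper = 1 - 1e-12)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("both classes must be present to stratify", call. = FALSE)
  }
  n_c <- vapply(classes, function(cl) sum(labels == cl), 0L)
  if (any(n_c == 0L)) stop("empty class in split", call. = FALSE)

  quota <- n_c * test_fraction
  total <- round(sum(quota))
  take <- floor(quota)
  remainder <- quota - take
  leftover <- total - sum(take)
  if (leftover > 0) {
    pick <- order(-remainder, -n_c)[seq_len(leftover)]
    take[pick] <- take[pick] + 1
  }
  test <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      idx <- which(labels == classes[i])
      if (take[i] == 0) integer(0) else idx[sample.int(length(idx), take[i])]
    }), use.names = FALSE)
  })
  test <- sort(test)
  structure(
    list(train = setdiff(seq_along(labels), test), test = test,
         seed = as.integer(seed), test_fraction = test_fraction),
    class = "split_assignment"
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("Stratified split: %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train), length(x$test), x$test_fraction, x$seed))
  invisible(x)
}

#' Z-score standardization fitted on training rows only
#'
#' `fit_standardizer()` estimates per-feature means and population standard
#' deviations (divisor n, the convention of common machine-learning scalers)
#' on the training rows only, so no information from held-out rows leaks into
#' preprocessing. `apply_standardizer()` applies the fitted transform to any
#' table with the same feature columns.
#'
#' @param table a data frame or numeric matrix of predictors (a `label`
#'   column, if present, is ignored).
#' @param rows integer indices of the training rows (default: all rows).
#' @return `fit_standardizer()`: an object of class `"standardizer"` with
#'   `center`, `scale` and `features`. `apply_standardizer()`: a numeric
#'   matrix of standardized features in the standardizer's column order.
#' @export
fit_standardizer <- function(table, rows = seq_len(nrow(table))) {
  x <- as_feature_matrix(table)
  x <- x[rows, , drop = FALSE]
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  if (any(scale < 1e-12)) {
    stop("constant training column(s): ",
         paste(colnames(x)[scale < 1e-12], collapse = ", "), call. = FALSE)
  }
  structure(list(center = center, scale = scale, features = colnames(x)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param standardizer a fitted `"standardizer"`.
#' @export
apply_standardizer <- function(standardizer, table) {
  stopifnot(inherits(standardizer, "standardizer"))
  x <- as_feature_matrix(table)
  missing <- setdiff(standardizer$features, colnames(x))
  if (length(missing)) {
    stop("table lacks feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, standardizer$features, drop = FALSE]
  scale(x, center = standardizer$center, scale = standardizer$scale)[, ,
    drop = FALSE]
}

# Invert a standardizer (used in tests and for shape-function grids).
destandardize <- function(standardizer, z) {
  sweep(sweep(z, 2, standardizer$scale[colnames(z)], "*"),
        2, standardizer$center[colnames(z)], "+")
}

as_feature_matrix <- function(table, label_column = "label") {
  if (is.matrix(table)) {
    storage.mode(table) <- "double"
    if (is.null(colnames(table))) {
      colnames(table) <- paste0("x", seq_len(ncol(table)))
    }
    return(table)
  }
  stopifnot(is.data.frame(table))
  table <- table[setdiff(names(table), label_column)]
  as.matrix(table)
}
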