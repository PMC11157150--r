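## Gradient-boosted behaviour classification: train/test split, 5-fold
## cross-validated confusion report, and prediction on unlabelled bursts.
## The boosting backend is xgboost, restricted to the selected features.

#' Default boosting hyperparameters
#'
#' `(nrounds = 10, max_depth = 6, eta = 0.3, gamma = 0,
#' colsample_bytree = 1, min_child_weight = 1, subsample = 1)` — the
#' stock gradient-boosted-tree settings used for collar behaviour
#' classification.
#'
#' @return Named list of hyperparameters.
#' @export
default_hyperparams <- function() {
  list(nrounds = 10L, max_depth = 6L, eta = 0.3, gamma = 0,
       colsample_bytree = 1, min_child_weight = 1, subsample = 1)
}

## Stratified fold assignment: within each class, shuffle then deal out
## fold ids round-robin so every fold sees every class where possible.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      warn(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                   cl, length(idx), k))
    }
    fold[idx] <- (sample(seq_along(idx)) - 1L) %% k + 1L
  }
  fold
}

#' Stratified train/test split of a labelled feature set
#'
#' Partitions the rows into disjoint, exhaustive train and test sets,
#' stratified by behaviour so each class appears in both sets in
#' proportion. A class with fewer than 2 members is kept whole in the
#' training set with a warning.
#'
#' @param features Labelled feature tibble (must contain `behaviour`).
#' @param train_fraction Fraction assigned to training; default 0.75
#'   (75/25 split).
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(features, train_fraction = 0.75, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!"behaviour" %in% names(features)) abort("features must carry `behaviour`")
  set.seed(seed)
  in_train <- logical(nrow(features))
  cls <- unique(features$behaviour)
  sizes <- vapply(cls, function(cl) sum(features$behaviour == cl), integer(1))
  small <- sizes < 2L
  if (any(small)) {
    warn(sprintf("class(es) %s have < 2 members; kept whole in training set",
                 paste(cls[small], collapse = ", ")))
    in_train[features$behaviour %in% cls[small]] <- TRUE
  }
  # largest-remainder allocation so the overall train size matches
  # round(n * fraction) exactly while staying stratified
  cls <- cls[!small]; sizes <- sizes[!small]
  target <- sizes * train_fraction
  n_cl <- pmin(pmax(floor(target), 1L), sizes - 1L)
  short <- round(sum(sizes) * train_fraction) - sum(n_cl)
  if (short > 0) {
    ord <- order(target - floor(target), decreasing = TRUE)
    for (i in ord) {
      if (short == 0L) break
      if (n_cl[i] < sizes[i] - 1L) { n_cl[i] <- n_cl[i] + 1L; short <- short - 1L }
    }
  }
  for (i in seq_along(cls)) {
    idx <- which(features$behaviour == cls[i])
    in_train[sample(idx, n_cl[i])] <- TRUE
  }
  list(train = features[in_train, ], test = features[!in_train, ])
}

feature_submatrix <- function(features, cols) {
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0L) {
    abort(paste0("feature columns absent: ", paste(missing_cols, collapse = ", ")))
  }
  as.matrix(features[, cols, drop = FALSE])
}

xgb_fit <- function(mat, y_int, n_class, hp, seed) {
  params <- list(objective = "multi:softprob", num_class = n_class,
                 max_depth = hp$max_depth, eta = hp$eta, gamma = hp$gamma,
                 colsample_bytree = hp$colsample_bytree,
                 min_child_weight = hp$min_child_weight,
                 subsample = hp$subsample, nthread = 1L,
                 tree_method = "exact",  # midpoint splits; burst sets are small
                 seed = as.integer(seed))
  dtrain <- xgboost::xgb.DMatrix(mat, label = y_int, nthread = 1L)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = hp$nrounds, verbose = 0)
}

xgb_predict_class <- function(booster, mat, classes) {
  prob <- predict(booster, xgboost::xgb.DMatrix(mat, nthread = 1L))
  if (is.null(dim(prob))) {
    prob <- matrix(prob, ncol = length(classes), byrow = TRUE)
  }
  classes[max.col(prob, ties.method = "first")]
}

#' Train the behaviour classifier
#'
#' Fits a multiclass gradient-boosted tree model on the selected feature
#' columns only. Training is deterministic given the seed (single
#' thread).
#'
#' @param features Labelled feature tibble.
#' @param selected Character vector of feature column names to use.
#' @param hp Hyperparameters, see [default_hyperparams()].
#' @param seed Integer seed.
#' @return An object of class `"behaviour_model"` holding the booster,
#'   the feature names, the class vocabulary, `hp` and `seed`.
#' @export
train_classifier <- function(features, selected, hp = default_hyperparams(),
                             seed = 1L) {
  if (!"behaviour" %in% names(features)) abort("features must carry `behaviour`")
  classes <- sort(unique(features$behaviour))
  if (length(classes) < 2L) abort("training needs at least 2 behaviour classes")
  mat <- feature_submatrix(features, selected)
  y <- match(features$behaviour, classes) - 1L
  booster <- xgb_fit(mat, y, length(classes), hp, seed)
  structure(list(booster = booster, features = selected, classes = classes,
                 hp = hp, seed = as.integer(seed)),
            class = "behaviour_model")
}

#' @export
print.behaviour_model <- function(x, ...) {
  cat("Gradient-boosted behaviour classifier\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat("  classes: ", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  nrounds = %d, max_depth = %d, eta = %g\n",
              x$hp$nrounds, x$hp$max_depth, x$hp$eta))
  invisible(x)
}

#' Predict behaviour labels for unlabelled feature rows
#'
#' @param model A `"behaviour_model"` from [train_classifier()].
#' @param features Feature tibble containing the model's feature columns.
#' @return Character vector of predicted behaviour labels, one per row.
#' @export
predict_behaviour <- function(model, features) {
  stopifnot(inherits(model, "behaviour_model"))
  if (nrow(features) == 0L) return(character())
  mat <- feature_submatrix(features, model$features)
  xgb_predict_class(model$booster, mat, model$classes)
}

#' Build a confusion report from observed and predicted labels
#'
#' The count matrix has observed behaviours in columns and predicted
#' behaviours in rows, so correct predictions fall on the diagonal.
#' Precision is the per-class fraction of predictions that were correct
#' (diagonal / row sum), recall the per-class fraction of observations
#' recovered (diagonal / column sum). Overall accuracy carries a 95%
#' Wilson score interval.
#'
#' @param observed,predicted Character vectors of equal length.
#' @param labels Optional class vocabulary fixing the matrix order.
#' @return An object of class `"confusion_report"`.
#' @export
confusion_report <- function(observed, predicted, labels = NULL) {
  stopifnot(length(observed) == length(predicted))
  if (is.null(labels)) labels <- sort(unique(c(observed, predicted)))
  m <- table(factor(predicted, levels = labels),
             factor(observed, levels = labels))
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(predicted = labels, observed = labels))
  correct <- sum(diag(m)); total <- sum(m)
  acc <- correct / total
  structure(
    list(labels = labels, matrix = m,
         precision = ifelse(rowSums(m) > 0, diag(m) / rowSums(m), NA_real_),
         recall = ifelse(colSums(m) > 0, diag(m) / colSums(m), NA_real_),
         accuracy = acc, ci = wilson_ci(correct, total), n = total),
    class = "confusion_report"
  )
}

## Wilson score interval for a binomial proportion at 95% coverage.
wilson_ci <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("Confusion report on %d predictions\n", x$n))
  cat(sprintf("  accuracy %.1f%%, 95%% CI [%.1f%%, %.1f%%]\n",
              100 * x$accuracy, 100 * x$ci["lower"], 100 * x$ci["upper"]))
  tab <- data.frame(precision = round(x$precision, 3),
                    recall = round(x$recall, 3))
  print(tab)
  invisible(x)
}

#' Cross-validated confusion report
#'
#' Partitions the labelled set into `folds` stratified parts, trains the
#' model `folds` times leaving one part out, predicts each burst exactly
#' once (when it sits in the validation fold) and pools all predictions
#' into a single confusion report.
#'
#' @param features Labelled feature tibble.
#' @param selected Feature columns to use.
#' @param hp Hyperparameters.
#' @param folds Number of folds, default 5.
#' @param seed Integer seed for fold assignment and training.
#' @return A `"confusion_report"`.
#' @export
cross_validate <- function(features, selected, hp = default_hyperparams(),
                           folds = 5L, seed = 1L) {
  if (folds < 2L) abort("folds must be >= 2")
  if (!"behaviour" %in% names(features)) abort("features must carry `behaviour`")
  classes <- sort(unique(features$behaviour))
  fold <- stratified_folds(features$behaviour, folds, seed)
  predicted <- character(nrow(features))
  mat <- feature_submatrix(features, selected)
  y <- match(features$behaviour, classes) - 1L
  for (f in seq_len(folds)) {
    hold <- fold == f
    booster <- xgb_fit(mat[!hold, , drop = FALSE], y[!hold],
                       length(classes), hp, seed + f)
    predicted[hold] <- xgb_predict_class(booster, mat[hold, , drop = FALSE],
                                         classes)
  }
  confusion_report(features$behaviour, predicted, labels = classes)
}

#' Write a confusion report as delimited text
#'
#' @param report A `"confusion_report"`.
#' @param path Output path; the count matrix is written with predicted
#'   classes in rows and observed classes in columns, followed by
#'   precision/recall columns.
#' @return `path`, invisibly.
#' @export
write_confusion_report <- function(report, path) {
  df <- as.data.frame(report$matrix)
  df <- cbind(predicted = rownames(report$matrix), df,
              precision = report$precision, recall = report$recall)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
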