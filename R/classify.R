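#' Random-forest hyperparameter pair
#'
#' The two-dimensional search point the optimizer tunes: number of trees in
#' the forest and number of candidate features considered at each split.
#'
#' @param n_trees integer >= 1.
#' @param n_features_per_split integer >= 1 (must not exceed the band count
#'   at training time).
#' @return Object of class `RfHyperparams`.
#' @export
rf_hyperparams <- function(n_trees, n_features_per_split) {
  n_trees <- as.integer(round(n_trees))
  n_features_per_split <- as.integer(round(n_features_per_split))
  if (n_trees < 1L || n_features_per_split < 1L)
    stop_input("hyperparameters must be integers >= 1")
  structure(list(n_trees = n_trees,
                 n_features_per_split = n_features_per_split),
            class = "RfHyperparams")
}

# Deterministic stratified fold assignment: shuffle within class under the
# given seed, deal round-robin. Errors if any class is rarer than the fold
# count (its recall would be undefined in some folds).
stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      if (length(idx) < k)
        stop_input("class '", cl, "' has ", length(idx),
                   " members, fewer than cv_folds = ", k)
      folds[idx] <- (seq_along(idx) %% k) + 1L
      folds[idx] <- folds[idx][sample.int(length(idx))]
    }
  })
  folds
}

cv_accuracy <- function(X, y, params, cv_folds, seed) {
  folds <- stratified_folds(y, cv_folds, seed)
  correct <- 0L
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    fit <- rf_fit(X[tr, , drop = FALSE], y[tr],
                  n_trees = params$n_trees,
                  mtry = params$n_features_per_split,
                  seed = seed + f)
    pred <- rf_predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  correct / length(y)
}

#' Optimizer fitness of a continuous hyperparameter position
#'
#' Rounds a continuous 2-vector `(n_trees, n_features_per_split)` to valid
#' integers (nearest integer, clamped to `bounds`) and returns
#' `1 - mean stratified cross-validated accuracy` of a random forest with
#' those hyperparameters — the "adaptation degree" the sparrow search
#' minimizes (lower is better). Deterministic given `(position, inner_seed)`.
#'
#' @param position numeric length-2 vector from the optimizer's continuous
#'   relaxation.
#' @param X numeric matrix of spectra (rows = seeds).
#' @param y class labels (>= 2 classes, each with >= `cv_folds` members).
#' @param cv_folds stratified CV folds (default 5).
#' @param inner_seed integer seed fixing folds and forest RNG.
#' @param bounds 2x2 matrix `rbind(lower, upper)` for the two dimensions;
#'   default trees in `[1, 100]`, features in `[1, ncol(X)]`.
#' @return Scalar fitness in `[0, 1]`.
#' @export
fitness_from_position <- function(position, X, y, cv_folds = 5L,
                                  inner_seed = 1L, bounds = NULL) {
  X <- as.matrix(X)
  if (length(position) != 2L)
    stop_input("position must have length 2 (n_trees, n_features_per_split)")
  if (is.null(bounds)) bounds <- rbind(c(1, 1), c(100, ncol(X)))
  p <- pmin(pmax(round(position), bounds[1, ]), bounds[2, ])
  params <- rf_hyperparams(p[1], min(p[2], ncol(X)))
  1 - cv_accuracy(X, y, params, cv_folds, inner_seed)
}

#' Train the final random-forest model
#'
#' @param Xtr training spectra matrix.
#' @param ytr training labels (>= 2 classes).
#' @param params an [rf_hyperparams()] (tuned, or the plain-RF baseline
#'   `rf_hyperparams(5, 3)`).
#' @param seed integer RNG seed.
#' @return A fitted [rf_fit()] classifier.
#' @export
train_final <- function(Xtr, ytr, params, seed = 1L) {
  stopifnot(inherits(params, "RfHyperparams"))
  Xtr <- as.matrix(Xtr)
  if (params$n_features_per_split > ncol(Xtr))
    stop_input("n_features_per_split (", params$n_features_per_split,
               ") exceeds band count (", ncol(Xtr), ")")
  rf_fit(Xtr, ytr, n_trees = params$n_trees,
         mtry = params$n_features_per_split, seed = seed)
}

#' Classification evaluation report
#'
#' Confusion matrix with per-class precision and recall and overall
#' accuracy. Recall of class n is `diag(n) / row-total(n)` (correctly
#' recovered fraction of truly-n seeds); precision is
#' `diag(n) / column-total(n)`, defined as 0 (and flagged) when the class
#' was never predicted; accuracy is `trace / total`.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels (same length).
#' @return Object of class `EvaluationReport`: `confusion`, `precision`,
#'   `recall`, `support`, `accuracy`, `undefined_precision`.
#' @examples
#' evaluate_predictions(c(0, 0, 1, 1), c(0, 1, 1, 1))$accuracy  # 0.75
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_input("y_true and y_pred lengths differ")
  lev <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  tf <- factor(as.character(y_true), levels = lev)
  pf <- factor(as.character(y_pred), levels = lev)
  cm <- table(true = tf, predicted = pf)
  cm <- matrix(as.integer(cm), nrow = length(lev),
               dimnames = list(true = lev, predicted = lev))
  diagv <- diag(cm)
  rowt <- rowSums(cm)
  colt <- colSums(cm)
  precision <- ifelse(colt > 0, diagv / colt, 0)
  recall <- ifelse(rowt > 0, diagv / rowt, NA_real_)
  structure(list(confusion = cm,
                 precision = precision,
                 recall = recall,
                 support = rowt,
                 accuracy = sum(diagv) / length(y_true),
                 undefined_precision = lev[colt == 0]),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: accuracy %.4f over %d observations\n",
              x$accuracy, sum(x$support)))
  df <- data.frame(class = rownames(x$confusion),
                   precision = round(x$precision, 4),
                   recall = round(x$recall, 4),
                   n = as.integer(x$support))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Stratified train/test split
#'
#' @param y labels to stratify on.
#' @param train_fraction proportion of each class assigned to training
#'   (default 0.8).
#' @param seed integer seed.
#' @return Logical vector, `TRUE` = training row.
#' @export
stratified_split <- function(y, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_input("train_fraction must be in (0, 1)")
  y <- as.character(y)
  train <- logical(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      n_tr <- max(1L, round(length(idx) * train_fraction))
      train[sample(idx, n_tr)] <- TRUE
    }
  })
  train
}
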