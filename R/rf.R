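#' Random-forest classifier
#'
#' Bagged CART trees grown to purity with Gini impurity, sampling `mtry`
#' candidate features at every split (the "feature subset" hyperparameter
#' the optimizer tunes, alongside `n_trees`). Implemented in compiled code
#' with a self-contained RNG so a fit is bit-reproducible from `seed` alone.
#'
#' @param X numeric matrix, observations x features.
#' @param y class labels (factor, integer or character); >= 2 classes.
#' @param n_trees number of trees (>= 1).
#' @param mtry features sampled per split; default `floor(sqrt(ncol(X)))`.
#' @param seed integer RNG seed for bootstrap and feature sampling.
#' @param min_split smallest node size still considered for splitting.
#' @return Object of class `moldseed_rf` with `$importance` (impurity
#'   importances over features, summing to 1) and a [predict][rf_predict]
#'   method.
#' @export
rf_fit <- function(X, y, n_trees, mtry = NULL, seed = 1L, min_split = 2L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  lev <- sort(unique(as.character(y)))
  if (length(lev) < 2)
    stop_input("random forest needs >= 2 classes; got ", length(lev))
  yi <- match(as.character(y), lev) - 1L
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  mtry <- as.integer(min(max(1L, mtry), ncol(X)))
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop_input("n_trees must be >= 1")
  fit <- .rf_fit_cpp(X, yi, length(lev), n_trees, mtry,
                     as.integer(min_split), as.integer(seed))
  structure(list(forest = fit, levels = lev, n_trees = n_trees,
                 mtry = mtry, importance = as.numeric(fit$importance)),
            class = "moldseed_rf")
}

#' Predict classes with a fitted random forest
#'
#' Majority vote over trees; ties break toward the lowest class level.
#'
#' @param object a [rf_fit()] model.
#' @param X matrix of new observations.
#' @return Vector of predicted labels on the original label scale.
#' @export
rf_predict <- function(object, X) {
  stopifnot(inherits(object, "moldseed_rf"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  idx <- .rf_predict_cpp(object$forest, X) + 1L
  out <- object$levels[idx]
  # restore integer type when the training labels were integer-like
  if (!anyNA(suppressWarnings(as.integer(object$levels))))
    out <- as.integer(out)
  out
}

#' @export
predict.moldseed_rf <- function(object, newdata, ...) rf_predict(object, newdata)
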