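#' Fit a bagged regression forest
#'
#' Plain CART regression forest (bootstrap aggregation, variance-reduction
#' splits, `mtry` random candidate features per node). It is the fixed-effect
#' learner used by [fit_merf()], the importance engine inside
#' [boruta_select()], and the baseline model in calibration tests.
#'
#' @param X numeric matrix (samples x features). Column names are kept.
#' @param y numeric response.
#' @param n_trees number of trees (default 300).
#' @param mtry candidate features per split; default `max(1, floor(p / 3))`,
#'   the usual regression-forest rule.
#' @param min_leaf minimum samples per leaf (default 5).
#' @param seed optional integer; when given, `set.seed(seed)` is called so the
#'   fit is reproducible.
#' @return object of class `gc_rf` with elements `trees`, `inbag`, `oob_pred`
#'   (out-of-bag predictions, `NA` for samples in every bootstrap),
#'   `feature_names`, `n_trees`, `mtry`, `min_leaf`.
#' @export
rf_fit <- function(X, y, n_trees = 300L, mtry = NULL, min_leaf = 5L,
                   seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported; impute first")
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  mtry <- min(as.integer(mtry), ncol(X))
  if (!is.null(seed)) set.seed(seed)
  fit <- cpp_rf_fit(X, as.numeric(y), as.integer(n_trees), mtry,
                    as.integer(min_leaf))
  structure(list(trees = fit$trees, inbag = fit$inbag,
                 oob_pred = as.numeric(fit$oob_pred),
                 feature_names = colnames(X), n_trees = as.integer(n_trees),
                 mtry = mtry, min_leaf = as.integer(min_leaf)),
            class = "gc_rf")
}

#' Predict from a bagged regression forest
#'
#' @param object a `gc_rf` fit.
#' @param newdata numeric matrix with the training columns (matched by name
#'   when both sides are named).
#' @param ... unused.
#' @return numeric vector of predictions (mean over trees).
#' @export
predict.gc_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    if (!all(object$feature_names %in% colnames(newdata)))
      stop("newdata is missing training features")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (length(object$feature_names) != ncol(newdata)) {
    stop("newdata has the wrong number of columns")
  }
  as.numeric(cpp_rf_predict(object$trees, newdata))
}

#' Out-of-bag permutation importance of a forest
#'
#' For each tree and feature, the increase in out-of-bag mean squared error
#' when that feature is shuffled among the tree's out-of-bag samples.
#'
#' @param object a `gc_rf` fit.
#' @param X,y the training data the forest was fitted on.
#' @param seed optional integer seed for the shuffles.
#' @return list with `mean` (per-feature mean over trees), `z` (mean divided
#'   by its standard error over trees, the Boruta Z-score) and `per_tree`
#'   (`n_trees` x p matrix).
#' @export
rf_importance <- function(object, X, y, seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!is.null(seed)) set.seed(seed)
  per_tree <- cpp_rf_oob_importance(object$trees, object$inbag, X,
                                    as.numeric(y))
  colnames(per_tree) <- colnames(X)
  m <- colMeans(per_tree)
  s <- apply(per_tree, 2, sd)
  z <- ifelse(s > 0, m / (s / sqrt(nrow(per_tree))), 0)
  list(mean = m, z = z, per_tree = per_tree)
}

#' @method print gc_rf
#' @export
print.gc_rf <- function(x, ...) {
  cat("Bagged regression forest:", x$n_trees, "trees,",
      length(x$feature_names), "features, mtry =", x$mtry, "\n")
  invisible(x)
}
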