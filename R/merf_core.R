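# Mixed-effects random forest with subject random intercepts: EM-style
# alternation between a bagged regression forest on the fixed part and
# closed-form random-effect / variance-component updates.

#' MERF configuration
#'
#' @param n_trees trees per forest refit (default 300).
#' @param max_em_iterations EM iteration cap (default 50). The generalized
#'   log-likelihood stopping rule cannot fire while `sigma2_b` is still
#'   collapsing toward zero (its `log sigma2_b` term keeps drifting), so in
#'   degenerate no-cluster-effect data the cap governs how completely the
#'   variance collapses; 30 iterations leave it visibly incomplete.
#' @param gll_tolerance relative change in generalized log-likelihood below
#'   which the alternation stops (default 1e-4).
#' @param mtry candidate features per split (default `floor(p/3)`).
#' @param min_leaf minimum samples per leaf (default 5).
#' @param use_oob_for_fixed_part use out-of-bag forest predictions as the
#'   fixed-part estimate during EM (default TRUE; reduces overfitting-driven
#'   collapse of the residual variance). FALSE switches to in-bag.
#' @param seed integer seed for all forest randomness.
#' @return list of class `merf_config`.
#' @export
merf_config <- function(n_trees = 300L, max_em_iterations = 50L,
                        gll_tolerance = 1e-4, mtry = NULL, min_leaf = 5L,
                        use_oob_for_fixed_part = TRUE, seed = 1L) {
  stopifnot(n_trees >= 1, gll_tolerance > 0, max_em_iterations >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_em_iterations = as.integer(max_em_iterations),
                 gll_tolerance = gll_tolerance, mtry = mtry,
                 min_leaf = as.integer(min_leaf),
                 use_oob_for_fixed_part = isTRUE(use_oob_for_fixed_part),
                 seed = as.integer(seed)),
            class = "merf_config")
}

#' Fit a mixed-effects random forest (random intercept per cluster)
#'
#' Model: `y_ij = f(x_ij) + b_i + e_ij`, with `f` a regression forest,
#' `b_i ~ N(0, sigma2_b)` per cluster, `e_ij ~ N(0, sigma2_e)`. The EM-style
#' alternation per iteration: (i) subtract current `b_i` from `y`; (ii) refit
#' the forest on the de-biased outcome; (iii) update each `b_i` by the
#' random-intercept closed form
#' `b_i = n_i * sigma2_b / (n_i * sigma2_b + sigma2_e) * mean(residual_i)`;
#' (iv) update `sigma2_e` and `sigma2_b` by the moment/EM formulas for the
#' intercept-only design; (v) track the generalized log-likelihood and stop
#' when its relative change drops below tolerance.
#'
#' @param X numeric matrix (samples x features), no missing values.
#' @param y numeric outcome.
#' @param clusters vector of cluster (subject) ids, one per sample.
#' @param config a [merf_config()].
#' @return object of class `merf_model`: `forest` (`gc_rf`), `b` (named
#'   per-cluster intercepts), `sigma2_b`, `sigma2_e`, `gll_trace`,
#'   `converged`, `feature_names`, `config`.
#' @export
fit_merf <- function(X, y, clusters, config = merf_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n != length(y) || n != length(clusters))
    stop("X, y and clusters must have matching lengths")
  if (n < 10) stop("at least 10 samples are required")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  clusters <- as.character(clusters)
  ids <- unique(clusters)
  m <- length(ids)
  if (m < 2) stop("at least 2 clusters are required")
  cl_index <- split(seq_len(n), factor(clusters, levels = ids))
  n_i <- unname(vapply(cl_index, length, integer(1)))

  b <- setNames(rep(0, m), ids)
  sigma2_e <- max(var(y), 1e-8)
  sigma2_b <- sigma2_e / 2
  gll_trace <- numeric(0)
  converged <- FALSE
  forest <- NULL
  f_hat <- NULL

  for (it in seq_len(config$max_em_iterations)) {
    ystar <- y - b[clusters]
    forest <- rf_fit(X, ystar, n_trees = config$n_trees, mtry = config$mtry,
                     min_leaf = config$min_leaf,
                     seed = derive_seed(config$seed, it))
    if (config$use_oob_for_fixed_part) {
      f_hat <- forest$oob_pred
      miss <- is.na(f_hat)
      if (any(miss)) f_hat[miss] <- predict(forest, X[miss, , drop = FALSE])
    } else {
      f_hat <- predict(forest, X)
    }

    resid <- y - f_hat
    new_e <- 0; new_b <- 0; gll <- 0
    for (k in seq_len(m)) {
      idx <- cl_index[[k]]
      nk <- n_i[k]
      shrink <- nk * sigma2_b / (nk * sigma2_b + sigma2_e)
      bk <- shrink * mean(resid[idx])
      b[k] <- bk
      eps <- resid[idx] - bk
      # V_i = sigma2_b J + sigma2_e I; trace(V^-1) and 1'V^-1 1 in closed form
      tr_vinv <- (nk - nk * sigma2_b / (sigma2_e + nk * sigma2_b)) / sigma2_e
      one_vinv_one <- nk / (sigma2_e + nk * sigma2_b)
      new_e <- new_e + sum(eps^2) + sigma2_e * (nk - sigma2_e * tr_vinv)
      new_b <- new_b + bk^2 + sigma2_b - sigma2_b^2 * one_vinv_one
      gll <- gll + sum(eps^2) / sigma2_e + bk^2 / sigma2_b +
        log(sigma2_b) + nk * log(sigma2_e)
    }
    sigma2_e <- new_e / n
    sigma2_b <- new_b / m
    if (sigma2_e < 1e-8) { warning("sigma2_e floored at 1e-8"); sigma2_e <- 1e-8 }
    if (sigma2_b < 1e-8) { sigma2_b <- 1e-8 }
    gll_trace <- c(gll_trace, gll)
    if (it > 1) {
      delta <- abs(gll - gll_trace[it - 1]) / max(1, abs(gll_trace[it - 1]))
      if (delta < config$gll_tolerance) { converged <- TRUE; break }
    }
  }

  structure(list(forest = forest, b = b, sigma2_b = sigma2_b,
                 sigma2_e = sigma2_e, gll_trace = gll_trace,
                 converged = converged, feature_names = colnames(X),
                 config = config),
            class = "merf_model")
}

#' Predict from a mixed-effects random forest
#'
#' `f(x) + b_cluster` for clusters seen in training ("personalized"
#' prediction leveraging the subject's accumulated history), `f(x)` alone for
#' unseen clusters.
#'
#' @param object a `merf_model`.
#' @param newdata feature matrix with the training columns.
#' @param clusters cluster ids, one per row of `newdata`.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.merf_model <- function(object, newdata, clusters, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    if (!all(object$feature_names %in% colnames(newdata)))
      stop("newdata is missing training features")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != length(object$feature_names)) {
    stop("feature mismatch")
  }
  f <- predict(object$forest, newdata)
  badd <- object$b[as.character(clusters)]
  badd[is.na(badd)] <- 0
  as.numeric(f + badd)
}

#' @method print merf_model
#' @export
print.merf_model <- function(x, ...) {
  cat(sprintf(
    "MERF: %d clusters, %d features | sigma2_b = %.4g, sigma2_e = %.4g\n",
    length(x$b), length(x$feature_names), x$sigma2_b, x$sigma2_e))
  cat(sprintf("  %d EM iterations (%s)\n", length(x$gll_trace),
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' Serialize a MERF model to a versioned JSON archive
#'
#' Stores the forest, per-cluster intercepts, variance components and the
#' convergence trace as plain JSON, reloadable with [read_merf()].
#'
#' @param model a `merf_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_merf <- function(model, path) {
  payload <- list(
    schema = "gutcog-merf-1",
    feature_names = model$feature_names,
    b = as.list(model$b), sigma2_b = model$sigma2_b,
    sigma2_e = model$sigma2_e, gll_trace = model$gll_trace,
    converged = model$converged,
    forest = list(n_trees = model$forest$n_trees, mtry = model$forest$mtry,
                  min_leaf = model$forest$min_leaf,
                  trees = model$forest$trees))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a MERF model written by [write_merf()]
#'
#' @param path JSON archive path.
#' @return a `merf_model` (without in-bag bookkeeping; prediction only).
#' @export
read_merf <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$schema, "gutcog-merf-1")) stop("unknown archive schema")
  trees <- lapply(p$forest$trees, function(t)
    list(feature = as.integer(unlist(t$feature)),
         threshold = as.numeric(unlist(t$threshold)),
         left = as.integer(unlist(t$left)),
         right = as.integer(unlist(t$right)),
         value = as.numeric(unlist(t$value))))
  fn <- as.character(unlist(p$feature_names))
  forest <- structure(list(trees = trees, inbag = NULL, oob_pred = NULL,
                           feature_names = fn,
                           n_trees = as.integer(p$forest$n_trees),
                           mtry = as.integer(p$forest$mtry),
                           min_leaf = as.integer(p$forest$min_leaf)),
                      class = "gc_rf")
  structure(list(forest = forest, b = unlist(p$b),
                 sigma2_b = as.numeric(p$sigma2_b),
                 sigma2_e = as.numeric(p$sigma2_e),
                 gll_trace = as.numeric(unlist(p$gll_trace)),
                 converged = isTRUE(p$converged), feature_names = fn,
                 config = NULL),
            class = "merf_model")
}
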