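# Permutation variable importance with empirical-null significance,
# Spearman/FDR feature annotation with the strength flags used in reporting,
# and KEGG-ortholog enrichment.

#' Cross-validated permutation importance of a fitted MERF
#'
#' Samples are split into `holdout_folds` folds that keep whole clusters
#' together (so repeated measures of a subject never straddle a fold). For
#' each fold, the fixed-part forest is refitted on the remaining folds
#' (outcome de-biased by the supplied model's cluster intercepts) and
#' evaluated on the held-out fold; the importance of a feature is the
#' increase in held-out squared error when its column is permuted within the
#' fold, averaged over `n_repeats` permutations and all folds. The held-out
#' refits keep the importance of uninformative features symmetric around
#' zero -- evaluating a model on its own training data would bias every used
#' feature positive and starve the mirrored null of
#' [importance_pvalues()].
#'
#' @param model a fitted `merf_model` (supplies the cluster intercepts,
#'   variance structure and forest hyperparameters).
#' @param X,y,clusters the data the model was fitted on.
#' @param n_repeats permutations per fold/feature (default 5).
#' @param holdout_folds number of cluster-grouped folds (default 3; must
#'   not exceed the number of clusters). Few, large folds are deliberate:
#'   permuting within a small held-out fold couples the permuted column
#'   with the fold's own empirical distribution and inflates the right
#'   tail of null importances (bias roughly inversely proportional to fold
#'   size), degrading the mirrored-null calibration.
#' @param seed integer seed.
#' @return named numeric vector of raw importances (one per feature).
#' @export
permutation_importance <- function(model, X, y, clusters, n_repeats = 5L,
                                   holdout_folds = 3L, seed = 1L) {
  X <- as.matrix(X)
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  clusters <- as.character(clusters)
  ids <- unique(clusters)
  if (holdout_folds > length(ids))
    stop("holdout_folds exceeds the number of clusters")
  set.seed(derive_seed(seed, 0L))
  fold_of_cluster <- setNames(
    rep_len(seq_len(holdout_folds), length(ids))[sample(length(ids))], ids)
  fold <- fold_of_cluster[clusters]
  p <- ncol(X)
  imp <- setNames(numeric(p), colnames(X))
  fo <- model$forest
  badd <- model$b[clusters]
  badd[is.na(badd)] <- 0

  for (k in seq_len(holdout_folds)) {
    idx <- which(fold == k)
    if (!length(idx)) next
    refit <- rf_fit(X[-idx, , drop = FALSE], (y - badd)[-idx],
                    n_trees = fo$n_trees, mtry = fo$mtry,
                    min_leaf = fo$min_leaf, seed = derive_seed(seed, k))
    Xk <- X[idx, , drop = FALSE]
    # held-out error of the fixed part against the raw outcome: the cluster
    # intercept is feature-independent and cancels from the error increase,
    # while using fold intercepts (which depend on fold outcomes) would
    # couple the error with the forest and bias every importance upward
    base <- predict(refit, Xk)
    base_err <- mean((y[idx] - base)^2)
    for (j in seq_len(p)) {
      acc <- 0
      for (r in seq_len(n_repeats)) {
        Xp <- Xk
        Xp[, j] <- Xk[sample(length(idx)), j]
        pred <- predict(refit, Xp)
        acc <- acc + mean((y[idx] - pred)^2) - base_err
      }
      imp[j] <- imp[j] + acc / n_repeats
    }
  }
  imp / holdout_folds
}

#' Empirical p-values for permutation importances (mirrored null)
#'
#' Builds an empirical null by reflecting the non-positive importances about
#' zero (a feature unrelated to the outcome is equally likely to land either
#' side of zero), then assigns each feature the upper-tail probability of its
#' observed importance under this null; Benjamini-Hochberg q-values are
#' attached. Requires at least 10 non-positive importances; with fewer,
#' supply `null_importances` from [altmann_null_importances()].
#'
#' @param importances named numeric vector of raw importances.
#' @param null_importances optional matrix (permutations x features) of
#'   importances computed under outcome permutation; when given, per-feature
#'   empirical p-values use that null instead of the mirrored one.
#' @param pool_null when a `null_importances` matrix is supplied, pool its
#'   draws across features into one empirical null (finer p-value
#'   granularity at small permutation counts; assumes comparable importance
#'   scales across features). Default FALSE (per-feature null).
#' @return data.frame `feature`, `importance`, `p`, `q`.
#' @export
importance_pvalues <- function(importances, null_importances = NULL,
                               pool_null = FALSE) {
  obs <- importances
  if (is.null(null_importances)) {
    nonpos <- obs[obs <= 0]
    if (length(nonpos) < 10)
      stop("fewer than 10 non-positive importances; use the Altmann ",
           "outcome-permutation fallback (altmann_null_importances)")
    null <- c(nonpos, -nonpos)
    # unsmoothed empirical tail (as in the reference implementation): a
    # feature clearly outside the null gets p = 0 rather than 1/(N+1), so
    # BH q-values can actually reach small thresholds
    p <- vapply(obs, function(v) sum(null >= v) / length(null), numeric(1))
  } else {
    if (!all(names(obs) %in% colnames(null_importances)))
      stop("null_importances must cover all features")
    if (pool_null) {
      nl <- as.numeric(null_importances)
      p <- vapply(obs, function(v) (sum(nl >= v) + 1) / (length(nl) + 1),
                  numeric(1))
    } else {
      p <- vapply(names(obs), function(f) {
        nl <- null_importances[, f]
        (sum(nl >= obs[f]) + 1) / (length(nl) + 1)
      }, numeric(1))
    }
  }
  data.frame(feature = names(obs), importance = unname(obs),
             p = unname(p), q = bh_fdr(unname(p)),
             stringsAsFactors = FALSE)
}

#' Altmann-style outcome-permutation importance null
#'
#' Refits the forest (fixed part only, intercepts dropped) on permuted
#' outcomes and recomputes cross-validated permutation importance, yielding a
#' per-feature null distribution for [importance_pvalues()]. Intended for
#' small models (e.g. the per-species clinical covariate screen) where the
#' mirrored null has too few non-positive importances.
#'
#' @param X,y,clusters data of the model being tested.
#' @param config `merf_config` used for the refits (use a small `n_trees`).
#' @param n_perm number of outcome permutations (default 50).
#' @param n_repeats,holdout_folds forwarded to [permutation_importance()].
#' @param seed integer seed.
#' @return matrix (`n_perm` x features) of null importances.
#' @export
altmann_null_importances <- function(X, y, clusters, config = merf_config(),
                                     n_perm = 50L, n_repeats = 2L,
                                     holdout_folds = 3L, seed = 1L) {
  X <- as.matrix(X)
  out <- matrix(NA_real_, n_perm, ncol(X),
                dimnames = list(NULL, colnames(X)))
  for (r in seq_len(n_perm)) {
    set.seed(derive_seed(seed, r))
    yp <- y[sample(length(y))]
    cfg <- config
    cfg$seed <- derive_seed(seed, r + n_perm)
    cfg$max_em_iterations <- 2L
    fit <- fit_merf(X, yp, clusters, cfg)
    out[r, ] <- permutation_importance(fit, X, yp, clusters,
                                       n_repeats = n_repeats,
                                       holdout_folds = holdout_folds,
                                       seed = derive_seed(seed, r + 2L * n_perm))
  }
  out
}

#' Spearman correlation of each feature with the outcome, with BH FDR
#'
#' Spearman rho with average ranks for ties; two-sided p from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom; Benjamini-Hochberg q-values across the tested set. Constant
#' columns have undefined rho: they are flagged and excluded from the FDR
#' set.
#'
#' @param X numeric matrix (samples x features).
#' @param y outcome vector.
#' @return data.frame `feature`, `rho`, `p`, `q`, `n` (`rho` = NA for
#'   constant columns).
#' @export
spearman_with_fdr <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("at least 3 paired observations are required")
  res <- data.frame(feature = colnames(X), rho = NA_real_, p = NA_real_,
                    q = NA_real_, n = nrow(X), stringsAsFactors = FALSE)
  ry <- rank(y)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (length(unique(x)) < 2) next # constant: rho undefined
    rho <- cor(rank(x), ry)
    res$rho[j] <- rho
    if (abs(rho) >= 1) { res$p[j] <- 0; next }
    tt <- rho * sqrt((nrow(X) - 2) / (1 - rho^2))
    res$p[j] <- 2 * pt(-abs(tt), df = nrow(X) - 2)
  }
  ok <- !is.na(res$p)
  res$q[ok] <- bh_fdr(res$p[ok])
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j` over the sorted p-values, mapped back
#' to input order; monotone in p-rank and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' KEGG-ortholog pathway enrichment (hypergeometric)
#'
#' One-sided hypergeometric upper-tail test of the overlap between a selected
#' KO set (e.g. the combined top predictors across cognitive outcomes) and
#' each pathway, against the background of all KO terms that entered the
#' model space. KO terms without a pathway mapping are counted out of both
#' background and selection.
#'
#' @param selected character vector of selected KO ids (must be a subset of
#'   `background`, non-empty).
#' @param background character vector of background KO ids.
#' @param ko_to_pathway data.frame with columns `ko` and `pathway` (a KO may
#'   map to several pathways).
#' @return data.frame `pathway`, `overlap`, `pathway_size`, `selection_size`,
#'   `background_size`, `p`, `q`, sorted by p.
#' @export
ko_enrichment <- function(selected, background, ko_to_pathway) {
  if (!length(selected)) stop("empty selection")
  if (!all(selected %in% background))
    stop("selection is not contained in background")
  if (!all(c("ko", "pathway") %in% names(ko_to_pathway)))
    stop("ko_to_pathway needs columns 'ko' and 'pathway'")
  map <- ko_to_pathway[ko_to_pathway$ko %in% background, , drop = FALSE]
  mapped <- unique(map$ko)
  bg <- intersect(unique(background), mapped)
  sel <- intersect(unique(selected), mapped)
  N <- length(bg); n <- length(sel)
  pathways <- unique(map$pathway)
  rows <- lapply(pathways, function(pw) {
    members <- intersect(unique(map$ko[map$pathway == pw]), bg)
    K <- length(members)
    k <- length(intersect(members, sel))
    pval <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = k, pathway_size = K,
               selection_size = n, background_size = N, p = pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Read a two-column KO -> pathway mapping TSV
#'
#' @param path TSV with columns `ko`, `pathway` (header optional; two
#'   unnamed columns are accepted in that order).
#' @return data.frame `ko`, `pathway`.
#' @export
read_ko_map <- function(path) {
  df <- read_tsv(path)
  if (!all(c("ko", "pathway") %in% names(df))) {
    if (ncol(df) >= 2) {
      df <- df[, 1:2]
      names(df) <- c("ko", "pathway")
    } else stop("expected two columns (ko, pathway)")
  }
  df
}
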