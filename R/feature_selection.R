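# Boruta all-relevant feature selection: real features compete against
# shuffled "shadow" copies of themselves inside a random forest; binomial
# tests on hit counts decide confirmed / rejected.

#' Boruta all-relevant feature selection
#'
#' Per iteration: a shuffled shadow copy of every still-undecided feature is
#' appended to the design, a regression forest is fitted, per-feature
#' out-of-bag permutation-importance Z-scores are computed, and an undecided
#' feature scores a "hit" when its Z exceeds the maximum shadow Z. After each
#' iteration, two-sided binomial tests (p = 0.5) on the hit counts with a
#' Bonferroni-style correction over the initial feature count mark features
#' confirmed (significantly more hits than chance) or rejected (significantly
#' fewer). The loop ends when all features are decided or after `max_runs`
#' iterations; survivors are tentative (and, by default policy downstream,
#' not selected).
#'
#' @param X numeric matrix (samples x features).
#' @param y numeric outcome (must not be constant).
#' @param max_runs maximum iterations (default 100).
#' @param alpha significance level for the binomial decisions (default 0.01).
#' @param n_trees forest size per iteration (default 150).
#' @param min_leaf forest leaf size (default 5).
#' @param seed integer seed; fixes shuffles and forests.
#' @return object of class `boruta_result`: `status` (named factor
#'   confirmed/tentative/rejected), `hits` (named integer), `n_iterations`,
#'   `importance_history` (iterations x features matrix of Z-scores, NA once
#'   a feature is decided), `seed`.
#' @export
boruta_select <- function(X, y, max_runs = 100L, alpha = 0.01,
                          n_trees = 150L, min_leaf = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (!ncol(X)) stop("zero features")
  if (max_runs < 1) stop("max_runs must be >= 1")
  if (length(unique(y)) < 2) stop("constant outcome")
  if (nrow(X) < 20) stop("at least 20 samples are required")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  feats <- colnames(X)
  status <- setNames(rep("tentative", p), feats)
  hits <- setNames(integer(p), feats)
  tested <- setNames(integer(p), feats) # iterations each feature competed in
  history <- matrix(NA_real_, max_runs, p, dimnames = list(NULL, feats))

  it <- 0L
  while (it < max_runs && any(status == "tentative")) {
    it <- it + 1L
    set.seed(derive_seed(seed, it))
    undecided <- feats[status == "tentative"]
    live <- feats[status != "rejected"]
    # shuffled shadow copy of every undecided feature, padded to a floor of
    # five shadows (as in the source algorithm) so the max-shadow reference
    # does not collapse when few features remain undecided
    shadow_src <- undecided
    while (length(shadow_src) < 5L)
      shadow_src <- c(shadow_src, live[sample(length(live), 1L)])
    shadows <- apply(X[, shadow_src, drop = FALSE], 2, sample)
    colnames(shadows) <- paste0(".shadow.", seq_along(shadow_src))
    design <- cbind(X[, live, drop = FALSE], shadows)
    fit <- rf_fit(design, y, n_trees = n_trees, min_leaf = min_leaf)
    imp <- rf_importance(fit, design, y)
    z <- imp$z
    history[it, live] <- z[live]
    zmax_shadow <- max(z[colnames(shadows)])
    hit_now <- z[undecided] > zmax_shadow
    hits[undecided] <- hits[undecided] + as.integer(hit_now)
    tested[undecided] <- tested[undecided] + 1L

    # two-sided binomial decisions, Bonferroni over the initial feature set
    thr <- alpha / p
    for (f in undecided) {
      k <- hits[f]; nt <- tested[f]
      p_more <- pbinom(k - 1L, nt, 0.5, lower.tail = FALSE)
      p_less <- pbinom(k, nt, 0.5)
      if (2 * p_more <= thr) status[f] <- "confirmed"
      else if (2 * p_less <= thr) status[f] <- "rejected"
    }
  }

  structure(list(
    status = factor(status, levels = c("confirmed", "tentative", "rejected")),
    hits = hits, n_iterations = it,
    importance_history = history[seq_len(it), , drop = FALSE],
    seed = as.integer(seed)),
    class = "boruta_result")
}

#' Selected (confirmed) features of a Boruta run
#'
#' @param result a `boruta_result`.
#' @param include_tentative also return tentative features (default FALSE;
#'   the conservative policy).
#' @return character vector of feature names.
#' @export
boruta_selected <- function(result, include_tentative = FALSE) {
  keep <- result$status == "confirmed"
  if (include_tentative) keep <- keep | result$status == "tentative"
  names(result$status)[keep]
}

#' @method print boruta_result
#' @export
print.boruta_result <- function(x, ...) {
  tb <- table(x$status)
  cat(sprintf("Boruta: %d confirmed, %d tentative, %d rejected after %d iterations\n",
              tb["confirmed"], tb["tentative"], tb["rejected"],
              x$n_iterations))
  invisible(x)
}

#' Write a Boruta report TSV (feature, status, hits, iterations)
#'
#' @param result a `boruta_result`.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_boruta_report <- function(result, path) {
  write_tsv(data.frame(feature = names(result$status),
                       status = as.character(result$status),
                       hits = as.integer(result$hits),
                       iterations = result$n_iterations,
                       stringsAsFactors = FALSE), path)
}
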