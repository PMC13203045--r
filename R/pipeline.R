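# End-to-end orchestration: longitudinal train/test splitting, the per-seed
# Boruta+MERF cognitive pipeline with a final union model and annotated
# importance ranking, the per-species clinical covariate screen, and
# cross-outcome rank comparison.

MINIMAL_COVARIATES <- c("sex_male", "age", "antibiotics_6mo",
                        "hospitalized_6mo", "mis", "cfs", "polypharmacy",
                        "education_years")

#' Leave-one-sample-per-subject train/test split
#'
#' For every subject with at least two samples, one sample (uniformly chosen)
#' is held out for the test set; subjects with a single sample stay entirely
#' in training. Deterministic under `seed`.
#'
#' @param records visit-record data.frame; only rows with a non-missing
#'   `sample_id` take part.
#' @param seed integer seed.
#' @return list of class `split_plan`: `seed`, `test_sample_ids`,
#'   `train_sample_ids`.
#' @export
longitudinal_split <- function(records, seed = 1L) {
  rec <- records[!is.na(records$sample_id), , drop = FALSE]
  if (!nrow(rec)) stop("empty cohort: no samples")
  set.seed(seed)
  test <- character(0)
  for (s in unique(rec$subject_id)) {
    ids <- rec$sample_id[rec$subject_id == s]
    if (length(ids) >= 2) test <- c(test, ids[sample(length(ids), 1)])
  }
  structure(list(seed = as.integer(seed), test_sample_ids = test,
                 train_sample_ids = setdiff(rec$sample_id, test)),
            class = "split_plan")
}

# design matrix of the 8 minimal clinical covariates (medications are
# deliberately excluded from the cognitive pipeline to avoid outcome leakage)
minimal_covariate_matrix <- function(records) {
  m <- cbind(sex_male = as.numeric(records$sex == "male"),
             age = records$age,
             antibiotics_6mo = as.numeric(records$antibiotics_6mo),
             hospitalized_6mo = as.numeric(records$hospitalized_6mo),
             mis = records$mis, cfs = records$cfs,
             polypharmacy = as.numeric(records$polypharmacy),
             education_years = records$education_years)
  rownames(m) <- records$sample_id
  m
}

# full covariate matrix for the per-species screen: demographics, clinical
# scores, comorbid exposures AND per-class medication indicators
screen_covariate_matrix <- function(records) {
  base <- minimal_covariate_matrix(records)
  extra <- cbind(cdr = records$cdr)
  med_lists <- strsplit(ifelse(is.na(records$medications), "",
                               records$medications), ";", fixed = TRUE)
  classes <- sort(unique(unlist(med_lists)))
  classes <- classes[classes != ""]
  med <- vapply(classes, function(cl)
    vapply(med_lists, function(v) as.numeric(cl %in% v), numeric(1)),
    numeric(nrow(records)))
  if (length(classes)) {
    colnames(med) <- paste0("med_", classes)
    m <- cbind(base, extra, med)
  } else m <- cbind(base, extra)
  rownames(m) <- records$sample_id
  m
}

covariate_category <- function(covariate) {
  ifelse(startsWith(covariate, "med_"), "medication",
         ifelse(covariate %in% c("sex_male", "age", "education_years"),
                "demographic", "clinical"))
}

# outcome vector per visit record row; composite z-scores are standardized
# across ALL subjects at each visit before any group subsetting
outcome_vector <- function(records, outcome) {
  switch(outcome,
    adas_cog_13 = records$adas_total,
    memory_z = {
      z <- composite_zscore(records, "memory", on_undefined = "drop")
      z$z[match(paste(records$subject_id, records$visit_index),
                paste(z$subject_id, z$visit_index))]
    },
    ef_z = {
      z <- composite_zscore(records, "executive_function",
                            on_undefined = "drop")
      z$z[match(paste(records$subject_id, records$visit_index),
                paste(z$subject_id, z$visit_index))]
    },
    stop("unknown outcome: ", outcome))
}

#' Cognitive-outcome MERF pipeline for one group / outcome / feature kind
#'
#' Per seed: leave-one-sample-per-subject split, Boruta all-relevant
#' selection on the training samples (microbiome features competing with the
#' 8 minimal clinical covariates; medications never enter), MERF fit on the
#' training samples with a subject random intercept, and the actual-vs-
#' predicted correlation on the held-out samples. A final model is then
#' fitted on all samples using the union of Boruta selections across seeds,
#' and annotated with cross-validated permutation importance, empirical-null
#' importance p/q-values, and per-feature Spearman rho/p/q with strength
#' (`|rho| >= strong_threshold`) and significance (`p <= p_max` and
#' `q < fdr_max`) flags.
#'
#' @param feature_table [abundance_table] of species, pathways or KO terms.
#' @param records visit-record data.frame for the whole cohort.
#' @param status data.frame from [classify_subjects()] (or equivalent).
#' @param group `"HC"`, `"MCI"` or `"AD"`.
#' @param outcome `"adas_cog_13"`, `"memory_z"` or `"ef_z"`.
#' @param n_seeds number of split/selection/fit repetitions (default 10).
#' @param seed master seed; every stage's seed derives from it.
#' @param prevalence_min prevalence filter applied to the group's samples.
#' @param top_k size of the annotated ranking (default 15).
#' @param merf a [merf_config()] (its seed field is overridden per stage).
#' @param boruta_max_runs,boruta_alpha,boruta_n_trees Boruta settings.
#' @param n_repeats,holdout_folds permutation-importance settings.
#' @param strong_threshold,p_max,fdr_max annotation thresholds
#'   (defaults 0.4, 0.05, 0.1).
#' @return object of class `pipeline_report`.
#' @export
run_cognitive_pipeline <- function(feature_table, records, status, group,
                                   outcome = c("adas_cog_13", "memory_z",
                                               "ef_z"),
                                   n_seeds = 10L, seed = 1L,
                                   prevalence_min = 0.1, top_k = 15L,
                                   merf = merf_config(n_trees = 150L),
                                   boruta_max_runs = 50L,
                                   boruta_alpha = 0.01,
                                   boruta_n_trees = 100L,
                                   n_repeats = 5L, holdout_folds = 3L,
                                   strong_threshold = 0.4, p_max = 0.05,
                                   fdr_max = 0.1) {
  outcome <- match.arg(outcome)
  subjects <- status$subject_id[status$status == group]
  if (length(subjects) < 10)
    warning("group ", group, " has fewer than 10 subjects")
  y_all <- outcome_vector(records, outcome)
  rec <- records[records$subject_id %in% subjects &
                   !is.na(records$sample_id) &
                   records$sample_id %in% feature_table$sample_ids &
                   !is.na(y_all), , drop = FALSE]
  y <- y_all[match(rownames(rec), rownames(records))]
  if (!nrow(rec)) stop("no usable samples for group ", group)
  tab <- prevalence_filter(subset_table(feature_table,
                                        samples = rec$sample_id),
                           prevalence_min)
  X <- cbind(tab$values, minimal_covariate_matrix(rec))
  clusters <- rec$subject_id

  per_seed <- vector("list", n_seeds)
  selections <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    split <- longitudinal_split(rec, derive_seed(seed, 100L + s))
    tr <- rec$sample_id %in% split$train_sample_ids
    te <- rec$sample_id %in% split$test_sample_ids
    bo <- boruta_select(X[tr, , drop = FALSE], y[tr],
                        max_runs = boruta_max_runs, alpha = boruta_alpha,
                        n_trees = boruta_n_trees,
                        seed = derive_seed(seed, 200L + s))
    sel <- boruta_selected(bo)
    selections[[s]] <- sel
    feats <- if (length(sel)) sel else MINIMAL_COVARIATES
    cfg <- merf
    cfg$seed <- derive_seed(seed, 300L + s)
    fit <- fit_merf(X[tr, feats, drop = FALSE], y[tr], clusters[tr], cfg)
    pred <- predict(fit, X[te, feats, drop = FALSE], clusters[te])
    per_seed[[s]] <- data.frame(
      seed = derive_seed(seed, 100L + s), n_train = sum(tr),
      n_test = sum(te), n_selected = length(sel),
      pearson = cor(y[te], pred),
      spearman = cor(y[te], pred, method = "spearman"))
  }
  per_seed <- do.call(rbind, per_seed)

  final_features <- sort(unique(unlist(selections)))
  covariate_only <- !length(final_features)
  if (covariate_only) final_features <- MINIMAL_COVARIATES
  cfg <- merf
  cfg$seed <- derive_seed(seed, 400L)
  Xf <- X[, final_features, drop = FALSE]
  final_fit <- fit_merf(Xf, y, clusters, cfg)
  raw_imp <- permutation_importance(final_fit, Xf, y, clusters,
                                    n_repeats = n_repeats,
                                    holdout_folds =
                                      min(holdout_folds,
                                          length(unique(clusters))),
                                    seed = derive_seed(seed, 500L))
  pv <- tryCatch(importance_pvalues(raw_imp), error = function(e) {
    null <- altmann_null_importances(
      Xf, y, clusters,
      config = merf_config(n_trees = 50L, max_em_iterations = 2L),
      n_perm = 50L, seed = derive_seed(seed, 600L))
    importance_pvalues(raw_imp, null_importances = null)
  })
  sp <- spearman_with_fdr(Xf, y)
  imp <- merge(pv, sp, by = "feature", suffixes = c("", "_spearman"))
  names(imp)[names(imp) == "p_spearman"] <- "spearman_p"
  names(imp)[names(imp) == "q_spearman"] <- "spearman_q"
  names(imp)[names(imp) == "rho"] <- "spearman_rho"
  imp <- imp[order(-imp$importance), , drop = FALSE]
  imp$rank <- seq_len(nrow(imp))
  imp$strong <- !is.na(imp$spearman_rho) &
    abs(imp$spearman_rho) >= strong_threshold
  imp$significant <- !is.na(imp$spearman_p) & imp$spearman_p <= p_max &
    !is.na(imp$spearman_q) & imp$spearman_q < fdr_max
  rownames(imp) <- NULL

  structure(list(
    group = group, outcome = outcome,
    feature_kind = feature_table$feature_kind,
    feature_universe = colnames(X),
    per_seed = per_seed,
    cor_mean = mean(per_seed$pearson), cor_sd = sd(per_seed$pearson),
    final_features = final_features, covariate_only = covariate_only,
    final_model = final_fit,
    importance = imp, top = head(imp, top_k), top_k = as.integer(top_k),
    thresholds = c(strong = strong_threshold, p = p_max, fdr = fdr_max),
    seed = as.integer(seed)),
    class = "pipeline_report")
}

#' @method print pipeline_report
#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Cognitive pipeline [%s / %s / %s]\n", x$group, x$outcome,
              x$feature_kind))
  cat(sprintf("  test correlation (Pearson): %.3f +/- %.3f over %d seeds\n",
              x$cor_mean, x$cor_sd, nrow(x$per_seed)))
  cat(sprintf("  final model: %d features%s\n", length(x$final_features),
              if (x$covariate_only) " (covariate-only: no Boruta hits)" else ""))
  print(head(x$top[, c("rank", "feature", "importance", "p", "q",
                       "spearman_rho", "strong", "significant")], 10),
        digits = 3)
  invisible(x)
}

#' Per-species clinical-covariate screen
#'
#' For each species passing the prevalence filter, a MERF predicts its
#' relative abundance from the full clinical covariate set -- demographics,
#' clinical scores, exposures, and one indicator per medication class (this
#' screen deliberately includes medications, unlike the cognitive pipeline)
#' -- with the subject as random effect. Covariate significance comes from
#' cross-validated permutation importance with an outcome-permutation
#' (Altmann) null, FDR-adjusted within each species model.
#'
#' @param species_table species [abundance_table].
#' @param records visit-record data.frame.
#' @param prevalence_min prevalence filter (default 0.1).
#' @param fdr_max within-model significance cutoff on q (default 0.05).
#' @param merf `merf_config` for the per-species fits (small by default).
#' @param n_perm Altmann permutations per species (default 30).
#' @param seed master seed.
#' @return object of class `covariate_screen`: `results` (long data.frame
#'   species, covariate, category, importance, p, q, significant),
#'   `frequency` (per-covariate share of models where significant),
#'   `category_share` (share of significant predictors by category),
#'   `n_models`.
#' @export
covariate_screen <- function(species_table, records, prevalence_min = 0.1,
                             fdr_max = 0.05,
                             merf = merf_config(n_trees = 100L,
                                                max_em_iterations = 3L),
                             n_perm = 30L, seed = 1L) {
  rec <- records[!is.na(records$sample_id) &
                   records$sample_id %in% species_table$sample_ids, ,
                 drop = FALSE]
  tab <- prevalence_filter(subset_table(species_table,
                                        samples = rec$sample_id),
                           prevalence_min)
  X <- screen_covariate_matrix(rec)
  clusters <- rec$subject_id
  rows <- list()
  skipped <- character(0)
  for (i in seq_along(tab$feature_ids)) {
    spf <- tab$feature_ids[i]
    yab <- tab$values[, spf]
    if (var(yab) == 0) { skipped <- c(skipped, spf); next }
    cfg <- merf
    cfg$seed <- derive_seed(seed, 10L * i)
    fit <- fit_merf(X, yab, clusters, cfg)
    folds <- min(3L, length(unique(clusters)))
    raw <- permutation_importance(fit, X, yab, clusters, n_repeats = 3L,
                                  holdout_folds = folds,
                                  seed = derive_seed(seed, 10L * i + 1L))
    null <- altmann_null_importances(
      X, yab, clusters,
      config = merf_config(n_trees = merf$n_trees, max_em_iterations = 2L),
      n_perm = n_perm, holdout_folds = folds,
      seed = derive_seed(seed, 10L * i + 2L))
    pv <- importance_pvalues(raw, null_importances = null, pool_null = TRUE)
    pv$species <- spf
    rows[[spf]] <- pv
  }
  if (!length(rows)) stop("no species with non-zero variance")
  res <- do.call(rbind, rows)
  res$category <- covariate_category(res$feature)
  res$significant <- res$q < fdr_max
  names(res)[names(res) == "feature"] <- "covariate"
  res <- res[, c("species", "covariate", "category", "importance", "p", "q",
                 "significant")]
  rownames(res) <- NULL
  n_models <- length(unique(res$species))
  freq <- tapply(res$significant, res$covariate, mean)
  freq <- sort(freq, decreasing = TRUE)
  sig <- res[res$significant, , drop = FALSE]
  cat_share <- if (nrow(sig)) table(sig$category) / nrow(sig) else
    table(factor(character(0),
                 levels = c("clinical", "demographic", "medication")))
  structure(list(results = res,
                 frequency = data.frame(covariate = names(freq),
                                        share_significant = as.numeric(freq),
                                        row.names = NULL),
                 category_share = cat_share, n_models = n_models,
                 skipped = skipped, seed = as.integer(seed)),
            class = "covariate_screen")
}

#' @method print covariate_screen
#' @export
print.covariate_screen <- function(x, ...) {
  cat(sprintf("Covariate screen: %d species models (%d skipped)\n",
              x$n_models, length(x$skipped)))
  print(head(x$frequency, 10), digits = 3)
  invisible(x)
}

#' Cross-outcome comparison of top-ranked features
#'
#' Union of the top-k features across two or more pipeline reports, with each
#' feature's importance rank and Spearman rho per report (NA where a feature
#' is not in that report's top-k).
#'
#' @param reports list of >= 2 `pipeline_report`s sharing a feature universe.
#' @return data.frame `feature`, then `rank_<outcome>` and `rho_<outcome>`
#'   per report.
#' @export
compare_rankings <- function(reports) {
  if (length(reports) < 2) stop("need at least two reports")
  uni <- lapply(reports, `[[`, "feature_universe")
  for (u in uni[-1])
    if (!setequal(u, uni[[1]])) stop("mismatched feature universes")
  labels <- vapply(reports, `[[`, character(1), "outcome")
  if (anyDuplicated(labels))
    labels <- paste0(labels, "_", seq_along(labels))
  feats <- sort(unique(unlist(lapply(reports, function(r) r$top$feature))))
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (i in seq_along(reports)) {
    top <- reports[[i]]$top
    out[[paste0("rank_", labels[i])]] <- top$rank[match(feats, top$feature)]
    out[[paste0("rho_", labels[i])]] <-
      top$spearman_rho[match(feats, top$feature)]
  }
  out
}

#' Write the annotated importance table of a report as TSV
#'
#' @param report a `pipeline_report`.
#' @param path output TSV.
#' @param top_only write only the annotated top-k rows (default FALSE).
#' @return invisibly, `path`.
#' @export
write_pipeline_report <- function(report, path, top_only = FALSE) {
  write_tsv(if (top_only) report$top else report$importance, path)
}
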