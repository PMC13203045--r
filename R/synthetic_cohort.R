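# Synthetic longitudinal cohort generator: group-structured clinical
# covariates (Table-1-style defaults), compositional feature tables with
# subject-level latent offsets, and cognitive outcomes driven by planted
# microbial features plus subject random intercepts -- with full ground-truth
# bookkeeping for recovery tests.

DRUG_CLASSES <- c("antihypertensive", "psychoactive", "statin", "ppi",
                  "antidiabetic", "nsaid", "anticoagulant", "thyroid")

default_covariate_params <- function() {
  list(
    HC  = list(age_mean = 70.2, age_sd = 7.46, female = 0.690,
               polypharmacy = 0.272, antibiotics = 0.177, hospital = 0.082,
               cfs_mean = 2.07, cfs_sd = 1.02, mis_mean = 1.21, mis_sd = 0.470,
               adas_mean = 9.01, adas_sd = 4.42,
               education_mean = 14, education_sd = 3),
    MCI = list(age_mean = 75.1, age_sd = 7.22, female = 0.525,
               polypharmacy = 0.400, antibiotics = 0.225, hospital = 0.100,
               cfs_mean = 2.54, cfs_sd = 0.942, mis_mean = 1.28, mis_sd = 0.510,
               adas_mean = 21.0, adas_sd = 12.8,
               education_mean = 14, education_sd = 3),
    AD  = list(age_mean = 73.9, age_sd = 5.75, female = 0.480,
               polypharmacy = 0.680, antibiotics = 0.080, hospital = 0.040,
               cfs_mean = 3.52, cfs_sd = 1.53, mis_mean = 1.68, mis_sd = 0.627,
               adas_mean = 32.3, adas_sd = 20.1,
               education_mean = 14, education_sd = 3))
}

#' A planted feature effect on the cognitive outcome
#'
#' Effects act on the per-feature z-scored arcsine-square-root abundance `t`
#' (bounded-leverage transform): `linear` adds `effect_size * t`;
#' `threshold` adds `effect_size * (t > 0)`; `interaction` adds
#' `effect_size * t * t_partner`.
#'
#' @param feature_id id in the generated table of `feature_kind`.
#' @param feature_kind `"species"`, `"pathway"` or `"ko"`.
#' @param effect_size signed coefficient, in latent-outcome SD units.
#' @param shape `"linear"`, `"threshold"` or `"interaction"`.
#' @param partner partner feature id (interaction shape only).
#' @return list of class `planted_effect`.
#' @export
planted_effect <- function(feature_id, feature_kind = "species",
                           effect_size = 1,
                           shape = c("linear", "threshold", "interaction"),
                           partner = NULL) {
  shape <- match.arg(shape)
  if (shape == "interaction" && is.null(partner))
    stop("interaction shape needs a partner feature")
  structure(list(feature_id = feature_id, feature_kind = feature_kind,
                 effect_size = effect_size, shape = shape, partner = partner),
            class = "planted_effect")
}

#' Synthetic-cohort configuration
#'
#' Defaults reproduce the study cohort's stated structure: 158/40/25 subjects
#' in HC/MCI/AD, repeated visits every 90 days with an overdispersed mean of
#' 3.8 (SD 2.4) samples per subject, and Table-1 group distributions for age,
#' sex, polypharmacy, antibiotics, hospital exposure, frailty, malnutrition
#' and ADAS-Cog-13 (education is not tabulated; 14 +/- 3 years is assumed).
#'
#' @param n_per_group named counts for HC, MCI, AD.
#' @param visits_mean,visits_sd mean/SD of samples per subject (truncated
#'   negative binomial, minimum 1).
#' @param visit_spacing_days days between visits (90).
#' @param n_species,n_pathways,n_ko feature counts per table.
#' @param planted list of [planted_effect()]s driving the outcome.
#' @param sigma_b SD of the subject random intercept on the latent outcome.
#' @param sigma_e residual SD of the latent outcome.
#' @param subject_tau SD of the subject-level latent abundance offset (drives
#'   within-subject autocorrelation of the microbiome).
#' @param feature_mu_sd spread of per-feature log-mean abundances.
#' @param feature_sigma per-visit log-abundance noise SD.
#' @param prevalence_range range the per-feature presence probabilities are
#'   drawn from (planted features are forced to prevalence 1).
#' @param missing_sample_rate fraction of visits without a fecal sample
#'   (cognitive-only visits).
#' @param covariate_params per-group parameter list; see
#'   `gutcog:::default_covariate_params()`.
#' @param seed master seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_per_group = c(HC = 158, MCI = 40, AD = 25),
                              visits_mean = 3.8, visits_sd = 2.4,
                              visit_spacing_days = 90, n_species = 150,
                              n_pathways = 60, n_ko = 100, planted = list(),
                              sigma_b = 1, sigma_e = 1, subject_tau = 0.5,
                              feature_mu_sd = 1.5, feature_sigma = 1,
                              prevalence_range = c(0.3, 1),
                              missing_sample_rate = 0.05,
                              covariate_params = default_covariate_params(),
                              seed = 1L) {
  n_per_group <- unlist(n_per_group)
  if (is.null(names(n_per_group)) && length(n_per_group) == 3)
    names(n_per_group) <- c("HC", "MCI", "AD") # YAML sequences drop names
  stopifnot(all(n_per_group >= 1), sigma_b >= 0, sigma_e >= 0,
            visits_mean >= 1, !is.null(names(n_per_group)))
  structure(list(n_per_group = n_per_group, visits_mean = visits_mean,
                 visits_sd = visits_sd,
                 visit_spacing_days = visit_spacing_days,
                 n_species = n_species, n_pathways = n_pathways, n_ko = n_ko,
                 planted = planted, sigma_b = sigma_b, sigma_e = sigma_e,
                 subject_tau = subject_tau, feature_mu_sd = feature_mu_sd,
                 feature_sigma = feature_sigma,
                 prevalence_range = prevalence_range,
                 missing_sample_rate = missing_sample_rate,
                 covariate_params = covariate_params,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# truncated negative binomial (min 1) with target mean/sd on the untruncated
# scale; rejection sampling
rvisits <- function(n, mean, sd) {
  v <- sd^2
  draw <- if (v > mean) {
    size <- mean^2 / (v - mean)
    function(k) rnbinom(k, size = size, mu = mean)
  } else {
    function(k) stats::rpois(k, mean)
  }
  out <- draw(n)
  while (any(out < 1)) out[out < 1] <- draw(sum(out < 1))
  out
}

# moment-matched truncated normal on [lo, hi]: find latent (mu, sigma) whose
# truncated moments equal (m, s), then map u in (0,1) through its quantile
trunc_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (stats::dnorm(a) - stats::dnorm(b)) / Z
  v <- sigma^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z -
                    ((stats::dnorm(a) - stats::dnorm(b)) / Z)^2)
  c(m, sqrt(v))
}

match_truncnorm <- function(m, s, lo = 0, hi = 85) {
  obj <- function(par) {
    mm <- trunc_moments(par[1], exp(par[2]), lo, hi)
    (mm[1] - m)^2 + (mm[2] - s)^2
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

qtruncnorm <- function(u, mu, sigma, lo = 0, hi = 85) {
  pa <- pnorm(lo, mu, sigma); pb <- pnorm(hi, mu, sigma)
  stats::qnorm(pa + u * (pb - pa), mu, sigma)
}

# fixed proportions used to split the simulated ADAS-Cog-13 total into the
# itemized subtests (the remaining ~18% stands for the non-itemized tasks);
# arbitrary but fixed, documented in the methods vignette
ADAS_SPLIT <- c(adas_word_recall = 0.18, adas_word_recognition = 0.16,
                adas_orientation = 0.10, adas_remember_instructions = 0.06,
                adas_delayed_recall = 0.14, adas_maze_time = 0.12,
                adas_maze_mistakes = 0.06)

simulate_feature_table <- function(kind, feature_ids, subjects, sample_ids,
                                   subj_of_sample, cfg, planted_ids) {
  nf <- length(feature_ids); ns <- length(sample_ids)
  mu <- rnorm(nf, 0, cfg$feature_mu_sd)
  prev <- runif(nf, cfg$prevalence_range[1], cfg$prevalence_range[2])
  names(prev) <- feature_ids
  prev[planted_ids] <- 1
  offs <- matrix(rnorm(length(subjects) * nf, 0, cfg$subject_tau),
                 length(subjects), nf, dimnames = list(subjects, NULL))
  present <- matrix(rbinom(length(subjects) * nf, 1, rep(prev, each = length(subjects))),
                    length(subjects), nf, dimnames = list(subjects, NULL))
  lat <- matrix(rnorm(ns * nf, 0, cfg$feature_sigma), ns, nf)
  lat <- sweep(lat, 2, mu, `+`) + offs[subj_of_sample, , drop = FALSE]
  vals <- exp(lat) * present[subj_of_sample, , drop = FALSE]
  # every sample must carry something: force the first planted (or first)
  # feature on for samples that lost everything
  dead <- rowSums(vals) == 0
  if (any(dead)) vals[dead, 1] <- exp(lat[dead, 1])
  dimnames(vals) <- list(sample_ids, feature_ids)
  list(table = abundance_table(vals, kind), prevalence = prev)
}

#' Simulate a longitudinal cohort with planted microbiome-cognition effects
#'
#' Generates per-visit clinical metadata with group-structured covariates,
#' compositional species/pathway/KO tables with subject latent offsets, and a
#' cognitive outcome `latent = fixed(planted features) + b_subject + noise`
#' mapped monotonically onto the ADAS-Cog-13 scale (per-group moment-matched
#' truncated normal on `[0, 85]`, so the configured group means/SDs hold under
#' the bounded support) and decomposed into subtests consistent with the
#' composite-score recipes. Baseline delayed-recall scores are nudged to make
#' the HC/MCI/AD classification rules recover the generating groups.
#'
#' @param config a [simulation_config()].
#' @return list with `records` (visit data.frame), `species`, `pathways`,
#'   `ko` ([abundance_table]s), and `truth` (planted effects, per-subject
#'   intercepts `b`, per-visit `fixed` and `latent`, feature prevalences,
#'   `null` flag, seed).
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n_subj <- length(groups)
  subjects <- sprintf("SUBJ%04d", seq_len(n_subj))

  nvis <- rvisits(n_subj, cfg$visits_mean, cfg$visits_sd)
  subj_of_visit <- rep(subjects, nvis)
  group_of_visit <- rep(groups, nvis)
  visit_index <- unlist(lapply(nvis, seq_len), use.names = FALSE)
  n_visits <- length(visit_index)
  jitter <- ifelse(visit_index == 1, 0, round(runif(n_visits, -7, 7)))
  days <- (visit_index - 1) * cfg$visit_spacing_days + jitter

  cp <- cfg$covariate_params
  gpar <- function(field) vapply(groups, function(g) cp[[g]][[field]],
                                 numeric(1))
  age0 <- rnorm(n_subj, gpar("age_mean"), gpar("age_sd"))
  sex <- ifelse(runif(n_subj) < gpar("female"), "female", "male")
  education <- pmax(6, round(rnorm(n_subj, gpar("education_mean"),
                                   gpar("education_sd"))))
  poly <- runif(n_subj) < gpar("polypharmacy")
  meds <- vapply(seq_len(n_subj), function(i) {
    k <- if (poly[i]) sample(5:8, 1) else sample(0:4, 1)
    paste(sample(DRUG_CLASSES, k), collapse = ";")
  }, character(1))
  cfs_base <- rnorm(n_subj, gpar("cfs_mean"), gpar("cfs_sd"))
  mis_base <- rnorm(n_subj, gpar("mis_mean"), gpar("mis_sd"))
  cdr <- ifelse(groups == "AD", sample(c(1, 2), n_subj, TRUE, c(0.6, 0.4)),
                ifelse(groups == "MCI", 0.5, 0))

  i_s <- match(subj_of_visit, subjects)
  sample_id <- sprintf("%s_V%02d", subj_of_visit, visit_index)
  sample_id[runif(n_visits) < cfg$missing_sample_rate] <- NA
  # baseline visits always have a sample (keeps every subject modellable)
  sample_id[visit_index == 1] <- sprintf("%s_V01",
                                         subj_of_visit[visit_index == 1])

  has_sample <- !is.na(sample_id)
  samp_ids <- sample_id[has_sample]
  subj_of_sample <- subj_of_visit[has_sample]

  species_ids <- sprintf("s__Species_%03d", seq_len(cfg$n_species))
  pathway_ids <- sprintf("PWY-6%03d: synthetic pathway %d",
                         seq_len(cfg$n_pathways), seq_len(cfg$n_pathways))
  ko_ids <- sprintf("K%05d", seq_len(cfg$n_ko))
  planted_by_kind <- split(
    vapply(cfg$planted, `[[`, character(1), "feature_id"),
    vapply(cfg$planted, `[[`, character(1), "feature_kind"))
  ids_of_kind <- list(species = species_ids, pathway = pathway_ids,
                      ko = ko_ids)
  for (kind in names(planted_by_kind)) {
    bad <- setdiff(planted_by_kind[[kind]], ids_of_kind[[kind]])
    if (length(bad))
      stop("planted feature(s) not in generated ", kind, " table: ",
           paste(bad, collapse = ", "))
  }
  sp <- simulate_feature_table("species", species_ids, subjects, samp_ids,
                               subj_of_sample, cfg,
                               planted_by_kind[["species"]] %||% character(0))
  pw <- simulate_feature_table("pathway", pathway_ids, subjects, samp_ids,
                               subj_of_sample, cfg,
                               planted_by_kind[["pathway"]] %||% character(0))
  ko <- simulate_feature_table("ko", ko_ids, subjects, samp_ids,
                               subj_of_sample, cfg,
                               planted_by_kind[["ko"]] %||% character(0))
  tables <- list(species = sp$table, pathway = pw$table, ko = ko$table)

  # fixed part of the outcome from planted effects (z-scored arcsine-sqrt
  # abundance transform); visits without a sample contribute 0
  fixed <- numeric(n_visits)
  tf <- function(kind, id) {
    a <- tables[[kind]]$values[, id]
    t <- asin(sqrt(pmin(1, a)))
    as.numeric(scale(t))
  }
  for (pl in cfg$planted) {
    t1 <- tf(pl$feature_kind, pl$feature_id)
    contrib <- switch(pl$shape,
      linear = pl$effect_size * t1,
      threshold = pl$effect_size * (t1 > 0),
      interaction = pl$effect_size * t1 * tf(pl$feature_kind, pl$partner))
    fixed[has_sample] <- fixed[has_sample] + contrib
  }

  b <- setNames(rnorm(n_subj, 0, cfg$sigma_b), subjects)
  eps <- rnorm(n_visits, 0, cfg$sigma_e)
  latent <- fixed + b[i_s] + eps

  # monotone map of the latent outcome onto the ADAS-Cog-13 scale, per group
  adas <- numeric(n_visits)
  for (g in unique(groups)) {
    gi <- group_of_visit == g
    pars <- match_truncnorm(cp[[g]]$adas_mean, cp[[g]]$adas_sd, 0, 85)
    l <- latent[gi]
    u <- pnorm(l, mean(l), max(sd(l), 1e-8))
    u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
    adas[gi] <- qtruncnorm(u, pars["mu"], pars["sigma"], 0, 85)
  }
  adas <- pmin(pmax(adas, 0), 85)

  sub <- sapply(names(ADAS_SPLIT), function(s)
    pmax(0, ADAS_SPLIT[[s]] * adas + rnorm(n_visits, 0, 0.5)))
  sub <- as.data.frame(sub)
  sub$adas_delayed_recall <- pmin(sub$adas_delayed_recall, 10)
  # classification consistency at baseline
  base1 <- visit_index == 1
  mci1 <- base1 & group_of_visit == "MCI"
  hc1 <- base1 & group_of_visit == "HC"
  sub$adas_delayed_recall[mci1] <- pmax(sub$adas_delayed_recall[mci1], 4)
  sub$adas_delayed_recall[hc1] <- pmin(sub$adas_delayed_recall[hc1], 3.5)

  lstd <- as.numeric(scale(latent))
  tb_card <- 105 - 8 * lstd + rnorm(n_visits, 0, 3)
  tb_pat <- 100 - 10 * lstd + rnorm(n_visits, 0, 5)

  records <- data.frame(
    subject_id = subj_of_visit, visit_index = visit_index,
    days_since_enrollment = days, sample_id = sample_id,
    sex = sex[i_s], age = round(age0[i_s] + days / 365.25, 1),
    education_years = education[i_s],
    antibiotics_6mo = runif(n_visits) < gpar("antibiotics")[i_s],
    hospitalized_6mo = runif(n_visits) < gpar("hospital")[i_s],
    polypharmacy = poly[i_s], medications = meds[i_s],
    cfs = pmin(7, pmax(1, round(cfs_base[i_s] + rnorm(n_visits, 0, 0.3)))),
    mis = round(pmax(0, mis_base[i_s] + rnorm(n_visits, 0, 0.1)), 2),
    cdr = cdr[i_s],
    dementia_diagnosis = groups[i_s] == "AD",
    normal_daily_function = groups[i_s] != "AD",
    stringsAsFactors = FALSE)
  records <- cbind(records, round(sub, 1),
                   tb_card_sort = round(tb_card, 1),
                   tb_pattern_comparison = round(tb_pat, 1),
                   adas_total = round(adas, 1))
  records <- validate_visit_records(records)

  ord <- order(subj_of_visit, visit_index) # same ordering validate applies
  truth <- list(planted = cfg$planted, b = b,
                group = setNames(groups, subjects),
                fixed = fixed[ord], latent = latent[ord],
                prevalence = list(species = sp$prevalence,
                                  pathway = pw$prevalence,
                                  ko = ko$prevalence),
                null = FALSE, seed = cfg$seed)
  list(records = records, species = sp$table, pathways = pw$table,
       ko = ko$table, truth = truth)
}

#' Negative-control cohort: identical tables, permuted outcomes
#'
#' Runs [simulate_cohort()] and then permutes the outcome block (ADAS total,
#' all subtests, both Toolbox scores, jointly) across all visits with a seed
#' derived from the master seed. Planted effects are thereby disconnected
#' from the outcome while every table is byte-identical to the signal
#' cohort's.
#'
#' @param config a [simulation_config()].
#' @return same shape as [simulate_cohort()]; `truth$null` is TRUE and
#'   `truth$permutation` stores the applied permutation.
#' @export
null_cohort <- function(config) {
  sim <- simulate_cohort(config)
  set.seed(derive_seed(config$seed, 104729L))
  perm <- sample(nrow(sim$records))
  cols <- c(names(ADAS_SPLIT), "tb_card_sort", "tb_pattern_comparison",
            "adas_total")
  sim$records[, cols] <- sim$records[perm, cols]
  sim$truth$null <- TRUE
  sim$truth$permutation <- perm
  sim
}
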