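# fixture builders shared across test files; everything is generated in code

# clustered regression data y = fixed_fun(X) + b_cluster + noise
make_clustered <- function(m = 30, ni = 4, p = 5, sigma_b = 1, sigma_e = 1,
                           fixed_fun = function(X) 4 * sin(2 * pi * X[, 1]) +
                             2 * X[, 2],
                           seed = 1) {
  set.seed(seed)
  n <- m * ni
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  cl <- rep(sprintf("c%03d", 1:m), each = ni)
  b <- rnorm(m, 0, sigma_b)
  y <- fixed_fun(X) + b[rep(1:m, each = ni)] + rnorm(n, 0, sigma_e)
  list(X = X, y = y, clusters = cl, b = b)
}

# write a tiny MetaPhlAn-style profile file; ab = named percents
write_profile <- function(path, ab, extra_lines = character(0)) {
  con <- file(path, "w")
  writeLines("#mpa_v4_toy", con)
  writeLines("#clade_name\trelative_abundance", con)
  writeLines(extra_lines, con)
  writeLines(sprintf("%s\t%g", names(ab), ab), con)
  close(con)
  path
}

# minimal visit-record data.frame with all columns the package uses
make_records <- function(n_subj = 6, n_visits = 3, seed = 1) {
  set.seed(seed)
  df <- expand.grid(visit_index = seq_len(n_visits),
                    subject_id = sprintf("S%02d", seq_len(n_subj)),
                    stringsAsFactors = FALSE)[, c(2, 1)]
  n <- nrow(df)
  df$days_since_enrollment <- (df$visit_index - 1) * 90
  df$sample_id <- sprintf("%s_V%d", df$subject_id, df$visit_index)
  df$sex <- rep(c("female", "male"), length.out = n)
  df$age <- round(runif(n, 60, 90), 1)
  df$education_years <- sample(10:20, n, TRUE)
  df$antibiotics_6mo <- runif(n) < 0.2
  df$hospitalized_6mo <- runif(n) < 0.1
  df$polypharmacy <- rep(runif(n_subj) < 0.3, each = n_visits)
  df$medications <- "statin;ppi"
  df$cfs <- sample(1:5, n, TRUE)
  df$mis <- round(runif(n, 0.5, 2.5), 2)
  df$cdr <- 0
  df$dementia_diagnosis <- FALSE
  df$normal_daily_function <- TRUE
  for (s in c("adas_word_recall", "adas_word_recognition",
              "adas_orientation", "adas_remember_instructions",
              "adas_delayed_recall", "adas_maze_time", "adas_maze_mistakes"))
    df[[s]] <- round(runif(n, 0, 5), 1)
  df$tb_card_sort <- round(runif(n, 80, 120), 1)
  df$tb_pattern_comparison <- round(runif(n, 70, 110), 1)
  df$adas_total <- round(runif(n, 2, 50), 1)
  validate_visit_records(df)
}

# literal-definition O(m^2) BH oracle: q_i = min over j with p_j >= p_i of
# p_(j) * m / rank(p_(j)), walking the step-up definition directly
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(ord == i) # rank of p_i
    cand <- Inf
    for (j in seq_len(m)) {
      rj <- which(ord == j)
      if (rj >= ri) cand <- min(cand, min(1, p[j] * m / rj))
    }
    q[i] <- cand
  }
  q
}

# exhaustive hypergeometric enrichment oracle: enumerate all selections of
# size n from the background, count those with overlap >= k
hyper_oracle <- function(k, K, N, n) {
  sel <- utils::combn(N, n)
  hits <- 0
  for (j in seq_len(ncol(sel)))
    if (sum(sel[, j] <= K) >= k) hits <- hits + 1
  hits / ncol(sel)
}

# Spearman rho by the no-ties rank formula 1 - 6*sum(d^2)/(n(n^2-1))
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# small planted-cohort config used by pipeline tests
planted_config <- function(n_mci = 30, n_species = 40, effect = 1,
                           seed = 1) {
  simulation_config(
    n_per_group = c(HC = 4, MCI = n_mci, AD = 4), n_species = n_species,
    n_pathways = 10, n_ko = 10,
    planted = lapply(sprintf("s__Species_%03d", 1:5), planted_effect,
                     effect_size = effect),
    seed = seed)
}
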