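test_that("default configuration reproduces the cohort structure", {
  sim <- simulate_cohort(simulation_config(seed = 3))
  st <- classify_subjects(sim$records)
  expect_equal(as.vector(table(st$status)), c(158, 40, 25))
  expect_equal(length(unique(sim$records$subject_id)), 223)
  # every status label matches the generating group
  expect_identical(as.character(st$status),
                   unname(sim$truth$group[st$subject_id]))
  # closure on all three tables
  for (tb in list(sim$species, sim$pathways, sim$ko))
    expect_true(all(abs(rowSums(tb$values) - 1) < 1e-6))
  # prevalence is reported and in range
  expect_true(all(sim$truth$prevalence$species >= 0 &
                    sim$truth$prevalence$species <= 1))
})

test_that("sigma_b = 0 and no planted effects give pure-noise outcome", {
  cfg <- simulation_config(n_per_group = c(HC = 10, MCI = 5, AD = 5),
                           n_species = 10, n_pathways = 4, n_ko = 4,
                           sigma_b = 0, seed = 4)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$b == 0))
  expect_true(all(sim$truth$fixed == 0))
})

test_that("same seed gives identical cohorts; planted ids are checked", {
  cfg <- simulation_config(n_per_group = c(HC = 5, MCI = 5, AD = 5),
                           n_species = 10, n_pathways = 4, n_ko = 4,
                           seed = 9)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  bad <- cfg
  bad$planted <- list(planted_effect("s__NotThere"))
  expect_error(simulate_cohort(bad), "not in generated")
})

test_that("null cohort permutes the outcome but nothing else", {
  cfg <- planted_config(n_mci = 15, seed = 21)
  sim <- simulate_cohort(cfg)
  nul <- null_cohort(cfg)
  expect_true(nul$truth$null)
  expect_identical(nul$species$values, sim$species$values)
  # outcome multiset preserved, order changed
  expect_equal(sort(nul$records$adas_total), sort(sim$records$adas_total))
  expect_false(identical(nul$records$adas_total, sim$records$adas_total))
  # reproducible
  expect_identical(null_cohort(cfg), null_cohort(cfg))
})

test_that("group moments converge to configured values at 10x n", {
  # spec-scale convergence check: 10x the default cohort
  cfg <- simulation_config(n_per_group = c(HC = 1580, MCI = 400, AD = 250),
                           n_species = 5, n_pathways = 2, n_ko = 2,
                           seed = 12)
  sim <- simulate_cohort(cfg)
  rec <- sim$records
  cp <- cfg$covariate_params
  for (g in c("HC", "MCI", "AD")) {
    subj <- names(sim$truth$group)[sim$truth$group == g]
    a <- rec$adas_total[rec$subject_id %in% subj]
    expect_lt(abs(mean(a) / cp[[g]]$adas_mean - 1), 0.02)
    # SD tolerance = 2% plus 3 Monte-Carlo standard errors of a sample SD
    # (1/sqrt(2n)); at n = 250 subjects the pure-2% band is below noise
    expect_lt(abs(sd(a) / cp[[g]]$adas_sd - 1),
              0.02 + 3 / sqrt(2 * length(a)))
    age <- rec$age[rec$subject_id %in% subj & rec$visit_index == 1]
    expect_lt(abs(mean(age) / cp[[g]]$age_mean - 1), 0.02)
    expect_lt(abs(sd(age) / cp[[g]]$age_sd - 1),
              0.02 + 3 / sqrt(2 * length(age)))
  }
})

test_that("outcome variance decomposition matches sigma_b / sigma_e", {
  cfg <- simulation_config(sigma_b = 1, sigma_e = 1, n_species = 5,
                           n_pathways = 2, n_ko = 2, seed = 13)
  sim <- simulate_cohort(cfg)
  rec <- sim$records
  b_of_visit <- sim$truth$b[rec$subject_id]
  eps <- sim$truth$latent - sim$truth$fixed - b_of_visit
  ratio <- var(sim$truth$b) / (var(sim$truth$b) + var(eps))
  expect_lt(abs(ratio - 0.5), 0.05) # sigma_b^2/(sigma_b^2+sigma_e^2) = 0.5
})

test_that("visit counts are overdispersed around the configured mean", {
  cfg <- simulation_config(n_per_group = c(HC = 500, MCI = 10, AD = 10),
                           n_species = 3, n_pathways = 2, n_ko = 2,
                           seed = 14)
  sim <- simulate_cohort(cfg)
  nv <- table(sim$records$subject_id)
  expect_gt(mean(nv), 3.4)
  expect_lt(mean(nv), 4.4)
  expect_gt(sd(nv), 1.8)
  expect_true(all(nv >= 1))
})
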