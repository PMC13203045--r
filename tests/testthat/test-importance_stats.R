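test_that("bh_fdr matches worked examples and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})

test_that("bh_fdr agrees with the literal-definition oracle", {
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(3:25, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("spearman_with_fdr: worked examples, ties and rank invariance", {
  X <- cbind(a = c(1, 2, 3), b = c(3, 1, 2))
  res <- spearman_with_fdr(X, c(10, 20, 30))
  expect_equal(res$rho, c(1, -0.5))
  # monotone transform of the outcome leaves rho unchanged
  X2 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(20)
  r1 <- spearman_with_fdr(X2, y)
  r2 <- spearman_with_fdr(X2, exp(y))
  expect_equal(r1$rho, r2$rho)
  # constant column flagged and excluded from the FDR set
  X3 <- cbind(X2, konst = 1)
  r3 <- spearman_with_fdr(X3, y)
  expect_true(is.na(r3$rho[r3$feature == "konst"]))
  expect_equal(r3$q[r3$feature != "konst"],
               bh_fdr(r3$p[r3$feature != "konst"]))
  # p-values follow the t-approximation
  rho <- r1$rho[1]
  tt <- rho * sqrt((20 - 2) / (1 - rho^2))
  expect_equal(r1$p[1], 2 * pt(-abs(tt), 18))
})

test_that("ko_enrichment: closed-form examples and validation", {
  map <- data.frame(ko = c("K1", "K2", "K3", "K4", "K5"),
                    pathway = c("pwA", "pwA", "pwB", "pwB", "pwB"))
  bg <- paste0("K", 1:5)
  res <- ko_enrichment(c("K1", "K2"), bg, map)
  expect_equal(res$p[res$pathway == "pwA"], 0.1) # C(2,2)C(3,0)/C(5,2)
  expect_equal(res$p[res$pathway == "pwB"], 1)   # zero overlap
  expect_error(ko_enrichment(character(0), bg, map), "empty")
  expect_error(ko_enrichment("K9", bg, map), "not contained")
  expect_true(all(res$overlap <= pmin(res$pathway_size, res$selection_size)))
})

test_that("enrichment p agrees with exhaustive enumeration (background <= 12)", {
  set.seed(42)
  for (i in 1:5) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    bg <- paste0("K", 1:N)
    map <- data.frame(ko = bg,
                      pathway = c(rep("pw", K), rep("other", N - K)))
    sel <- sample(bg, n)
    res <- ko_enrichment(sel, bg, map)
    k <- sum(sel %in% bg[1:K])
    expect_equal(res$p[res$pathway == "pw"], hyper_oracle(k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("permutation importance: constant feature is exactly 0, folds validated", {
  dat <- make_clustered(m = 12, ni = 3, p = 4, seed = 43)
  X <- cbind(dat$X, konst = 1)
  fit <- fit_merf(X, dat$y, dat$clusters,
                  merf_config(n_trees = 40, max_em_iterations = 3, seed = 1))
  imp <- permutation_importance(fit, X, dat$y, dat$clusters,
                                n_repeats = 2, holdout_folds = 3, seed = 2)
  expect_identical(unname(imp["konst"]), 0)
  expect_error(permutation_importance(fit, X, dat$y, dat$clusters,
                                      holdout_folds = 50),
               "exceeds")
  # informative feature dominates
  expect_gt(imp["x1"], max(imp[c("x3", "x4", "konst")]))
})

test_that("permutation importance is stable under more repeats", {
  dat <- make_clustered(m = 20, ni = 3, p = 4, seed = 44)
  fit <- fit_merf(dat$X, dat$y, dat$clusters,
                  merf_config(n_trees = 60, max_em_iterations = 3, seed = 1))
  i1 <- permutation_importance(fit, dat$X, dat$y, dat$clusters,
                               n_repeats = 4, holdout_folds = 4, seed = 5)
  i2 <- permutation_importance(fit, dat$X, dat$y, dat$clusters,
                               n_repeats = 8, holdout_folds = 4, seed = 6)
  # the informative features keep their order
  expect_identical(names(sort(i1[1:2], decreasing = TRUE)),
                   names(sort(i2[1:2], decreasing = TRUE)))
})

test_that("importance_pvalues: mirrored null needs 10 non-positives, altmann works", {
  imp <- setNames(c(2, rep(-0.1, 4)), paste0("f", 1:5))
  expect_error(importance_pvalues(imp), "Altmann|fewer than 10")
  # mirrored-null route
  set.seed(45)
  imp2 <- setNames(c(3, rnorm(30, 0, 0.3)), paste0("f", 1:31))
  pv <- importance_pvalues(imp2)
  expect_equal(pv$feature[which.min(pv$p)], "f1")
  expect_true(all(pv$p >= 0 & pv$p <= 1))
  expect_equal(pv$p[pv$feature == "f1"], 0) # clearly outside the null
  expect_equal(pv$q, bh_fdr(pv$p))
  # explicit null matrix route
  null <- matrix(rnorm(31 * 20, 0, 0.3), 20, 31,
                 dimnames = list(NULL, paste0("f", 1:31)))
  pv2 <- importance_pvalues(imp2, null_importances = null)
  expect_lt(pv2$p[pv2$feature == "f1"], 0.1)
})
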