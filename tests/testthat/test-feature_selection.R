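test_that("input validation", {
  X <- matrix(rnorm(600), 30, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rnorm(30)
  expect_error(boruta_select(X, y, max_runs = 0), "max_runs")
  expect_error(boruta_select(X[, 0], y), "zero features")
  expect_error(boruta_select(X, rep(1, 30)), "constant")
  expect_error(boruta_select(X[1:10, ], y[1:10]), "20 samples")
})

test_that("a strongly planted feature is confirmed; statuses partition", {
  set.seed(31)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- 5 * X[, 1] + rnorm(n)
  res <- boruta_select(X, y, n_trees = 80, seed = 1)
  expect_identical(as.character(res$status[["f1"]]), "confirmed")
  # statuses partition the real feature set; no shadow appears
  expect_setequal(names(res$status), colnames(X))
  expect_false(any(grepl("shadow", names(res$status))))
  expect_true(all(res$hits <= res$n_iterations))
  # the importance history only covers iterations actually run
  expect_equal(nrow(res$importance_history), res$n_iterations)
})

test_that("selection is deterministic under a fixed seed", {
  set.seed(32)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- 2 * X[, 2] + rnorm(n)
  r1 <- boruta_select(X, y, n_trees = 50, seed = 7)
  r2 <- boruta_select(X, y, n_trees = 50, seed = 7)
  expect_identical(r1$status, r2$status)
  expect_identical(r1$hits, r2$hits)
})

test_that("confirmation frequency is monotone in effect size", {
  # scaled-down version of the module property (3 effect sizes x 3 seeds;
  # the acceptance suite runs the full planted/noise recovery at 10 seeds)
  freq <- vapply(c(0, 1.5, 5), function(beta) {
    conf <- 0
    for (s in 1:3) {
      set.seed(330 + s)
      n <- 100
      X <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("f", 1:10)))
      y <- beta * X[, 1] + rnorm(n)
      res <- boruta_select(X, y, n_trees = 60, max_runs = 40,
                           seed = 100 + s)
      conf <- conf + (res$status[["f1"]] == "confirmed")
    }
    conf / 3
  }, numeric(1))
  expect_true(all(diff(freq) >= 0))
  expect_equal(freq[3], 1)
})

test_that("boruta report TSV round-trips the statuses", {
  set.seed(34)
  X <- matrix(rnorm(600), 30, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- 3 * X[, 1] + rnorm(30)
  res <- boruta_select(X, y, n_trees = 40, max_runs = 25, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_boruta_report(res, f)
  back <- read.delim(f)
  expect_identical(back$feature, names(res$status))
  expect_identical(back$status, as.character(res$status))
})
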