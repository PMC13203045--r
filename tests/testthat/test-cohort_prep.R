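test_that("classification follows the baseline rules", {
  rec <- make_records(4, 2)
  rec$dementia_diagnosis[rec$subject_id == "S01"] <- TRUE
  # S02: CDR 0.5, normal function, delayed recall exactly at the threshold
  rec$cdr[rec$subject_id == "S02"] <- 0.5
  rec$adas_delayed_recall[rec$subject_id == "S02" & rec$visit_index == 1] <- 4
  # S03: no diagnosis, delayed recall below threshold -> HC
  rec$adas_delayed_recall[rec$subject_id == "S03" & rec$visit_index == 1] <- 3
  # S04: good recall but impaired daily function -> fails MCI rule -> HC
  rec$adas_delayed_recall[rec$subject_id == "S04" & rec$visit_index == 1] <- 6
  rec$normal_daily_function[rec$subject_id == "S04"] <- FALSE
  st <- classify_subjects(rec)
  expect_identical(as.character(st$status[match(paste0("S0", 1:4),
                                                st$subject_id)]),
                   c("AD", "MCI", "HC", "HC"))
  # partition: exactly one label per subject
  expect_identical(sort(st$subject_id), sort(unique(rec$subject_id)))

  # missing baseline errors
  rec2 <- rec[rec$visit_index > 1 | rec$subject_id != "S01", ]
  expect_error(classify_subjects(rec2), "baseline")
})

test_that("composite scores: sums, directions and visit standardization", {
  rec <- make_records(3, 1)
  mem_cols <- c("adas_word_recall", "adas_word_recognition",
                "adas_orientation", "adas_remember_instructions",
                "adas_delayed_recall")
  rec[1, mem_cols] <- c(3, 2, 1, 0, 4)
  mem <- composite_zscore(rec, "memory")
  expect_equal(mem$raw_sum[mem$subject_id == rec$subject_id[1]], 10)

  # visit group raw sums {2, 4, 6} standardize to {-1, 0, 1} with sample SD
  rec2 <- make_records(3, 1)
  rec2$adas_word_recall <- c(2, 4, 6)
  rec2$adas_word_recognition <- 0
  rec2$adas_orientation <- 0
  rec2$adas_remember_instructions <- 0
  rec2$adas_delayed_recall <- 0
  z <- composite_zscore(rec2, "memory")
  expect_equal(z$z, c(-1, 0, 1))

  # zero-SD visit group errors (and can be dropped)
  rec3 <- rec2
  rec3$adas_word_recall <- 5
  expect_error(composite_zscore(rec3, "memory"), "zero standard deviation")
  expect_equal(nrow(composite_zscore(rec3, "memory", on_undefined = "drop")),
               0)

  # executive function: higher-is-better Toolbox components are sign-flipped
  rec4 <- make_records(2, 1)
  rec4$adas_maze_time <- c(1, 2)
  rec4$adas_maze_mistakes <- c(1, 1)
  rec4$tb_card_sort <- c(10, 5)
  rec4$tb_pattern_comparison <- c(8, 4)
  ef <- composite_zscore(rec4, "executive_function")
  expect_equal(ef$raw_sum, c(1 + 1 - 10 - 8, 2 + 1 - 5 - 4))
  expect_gt(ef$z[2], ef$z[1]) # worse performance => higher z
})

test_that("inverse Simpson: closed form, permutation invariance, bounds", {
  expect_equal(inverse_simpson(rep(0.25, 4)), 4)
  expect_equal(inverse_simpson(1), 1)
  expect_equal(inverse_simpson(c(0.5, 0.3, 0.2)), 1 / 0.38)
  set.seed(5)
  for (i in 1:10) {
    p <- rexp(8); p <- p / sum(p)
    expect_equal(inverse_simpson(p), inverse_simpson(sample(p)))
    expect_lte(inverse_simpson(p), sum(p > 0))
  }
  expect_error(inverse_simpson(numeric(0)), "empty")
  expect_error(inverse_simpson(c(0.5, 0.2)), "closed")
})

test_that("LMM with zero cluster variance reproduces OLS", {
  # balanced design with identical cluster means: residuals are centered
  # within cluster, so the REML boundary estimate of sigma2_b is exactly 0
  # and the mixed fit collapses to OLS
  set.seed(6)
  d <- data.frame(id = rep(sprintf("c%02d", 1:20), each = 4),
                  x = rnorm(80), t = rep(0:3, 20))
  e <- rnorm(80, 0, 0.5)
  e <- e - stats::ave(e, d$id)
  d$y <- 1 + 0.5 * d$x - 0.2 * d$t + e
  fit <- fit_random_intercept_lmm(d, "y", c("x", "t"), "id")
  ols <- lm(y ~ x + t, d)
  expect_lt(max(abs(fit$fixed$estimate - coef(ols))), 1e-6)
  expect_lt(fit$sigma2_b, 1e-6)
})

test_that("LMM input validation", {
  d <- data.frame(id = "c1", y = rnorm(5), x = rnorm(5))
  expect_error(fit_random_intercept_lmm(d, "y", "x", "id"), "2 clusters")
  d2 <- data.frame(id = rep(c("a", "b"), 5), y = rnorm(10), x = rnorm(10))
  d2$x2 <- d2$x # aliased column
  expect_error(fit_random_intercept_lmm(d2, "y", c("x", "x2"), "id"),
               "rank deficient")
})

test_that("LMM recovers variance components and slopes (scaled-down check)", {
  # 10 replicates here; the acceptance suite runs the full 50
  hits <- 0; vb <- numeric(10)
  for (r in 1:10) {
    set.seed(100 + r)
    m <- 100; ni <- 4
    d <- data.frame(id = rep(sprintf("c%03d", 1:m), each = ni),
                    t = rep(seq(0, 3), m))
    d$y <- 0.5 * d$t + rep(rnorm(m), each = ni) + rnorm(m * ni)
    fit <- fit_random_intercept_lmm(d, "y", "t", "id")
    est <- fit$fixed[fit$fixed$term == "t", ]
    if (abs(est$estimate - 0.5) <= 2 * est$se) hits <- hits + 1
    vb[r] <- fit$sigma2_b
  }
  expect_gte(hits, 8)
  expect_lt(abs(mean(vb) - 1), 0.15)
})
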