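test_that("paired Wilcoxon is exact for small untied samples", {
  r <- paired_wilcoxon(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_equal(r$p_value, 0.0625)  # 2 / 2^5, the extreme rank-sum twice
  expect_equal(r$n, 5L)
  expect_equal(r$direction, "y_lower")
})

test_that("identical series give a flagged degenerate result, not an error", {
  r <- paired_wilcoxon(1:10, 1:10)
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
  expect_equal(r$n, 0L)
})

test_that("swapping the series flips the direction but not the p-value", {
  x <- c(5, 9, 1, 7, 12, 3, 8)
  y <- c(4, 2, 2, 6, 10, 1, 5)
  a <- paired_wilcoxon(x, y)
  b <- paired_wilcoxon(y, x)
  expect_equal(a$p_value, b$p_value)
  expect_true(a$direction != b$direction)
})

test_that("exact and approximate Wilcoxon p-values agree at n = 25", {
  set.seed(88)
  for (rep in 1:5) {
    d <- round(rnorm(25, 0.3, 1), 6)  # untied with probability 1
    x <- abs(d) + d
    y <- abs(d)
    r_exact <- paired_wilcoxon(x, y)                     # exact path (n = 25)
    wt <- suppressWarnings(stats::wilcox.test(x - y, exact = FALSE, correct = TRUE))
    expect_lt(abs(r_exact$p_value - wt$p.value), 0.01)
  }
})

test_that("win rate counts strict wins only", {
  expect_equal(win_rate(c(1, 1, 1), c(2, 2, 2)), 100)
  expect_equal(win_rate(c(2, 2), c(2, 2)), 0)       # ties are not wins
  expect_equal(win_rate(c(1, 3), c(2, 2)), 50)
  expect_error(win_rate(numeric(0), numeric(0)), "empty")
  # complementarity with equality iff no ties
  a <- c(1, 5, 3, 3)
  b <- c(2, 4, 3, 1)
  expect_lte(win_rate(a, b) + win_rate(b, a), 100)
  a2 <- c(1, 5)
  b2 <- c(2, 4)
  expect_equal(win_rate(a2, b2) + win_rate(b2, a2), 100)
})

test_that("group comparisons: identity, separation and degeneracy", {
  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)), "t_test")
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)
  sep <- compare_groups(list(a = c(0, 0.01, 0, 0.02), b = c(10, 10.01, 10, 9.99)),
                        "t_test")
  expect_lt(sep$p_value, 0.001)
  expect_equal(sep$direction, "a")
  deg <- compare_groups(list(a = c(1, 1), b = c(1, 1)), "t_test")
  expect_true(deg$degenerate)
  three <- compare_groups(list(a = rnorm(5), b = rnorm(5), c = rnorm(5)), "anova")
  expect_equal(three$test, "anova")
  expect_true(three$p_value >= 0 && three$p_value <= 1)
})

test_that("one-way ANOVA holds its nominal type-I error under the null", {
  set.seed(202)
  reject <- replicate(1000, {
    g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
    compare_groups(g, "anova")$p_value < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("rendered tables round-trip through CSV", {
  sim <- simulation_config(weeks = 2L, arms = c("two_stage", "mean"),
                           waitlist_sizes = 150L, granularities = 15L,
                           master_seed = 77L)
  res <- run_simulation(sim)
  out <- tempfile()
  paths <- render_tables(res, out)
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "report.txt")))
  back <- utils::read.csv(file.path(out, "weekly_metrics.csv"))
  expect_equal(back$objective_min, res$weekly$objective_min)
  expect_equal(nrow(utils::read.csv(file.path(out, "win_rates.csv"))), 1L)
})
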