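test_that("within-environment correlations follow the sampling formula", {
  # perfect fit: r = 1 and V = 0 exactly; the infinite weight then
  # excludes the entry from the weighted mean
  df <- data.frame(env = "e1", observed = 1:10, predicted = 1:10)
  ec <- env_correlations(df)
  expect_equal(ec$correlations$r, 1)
  expect_equal(ec$correlations$V, 0)
  expect_error(weighted_mean_correlation(ec), "eligible")

  # n = 2 is outside the formula domain
  df <- data.frame(env = "e1", observed = c(1, 2), predicted = c(2, 1))
  ec <- env_correlations(df)
  expect_match(ec$skipped$reason, "fewer than 3")

  # hand example: obs (1,2,3,4) vs pred (2,1,4,3) -> r = 0.6
  df <- data.frame(env = "e1", observed = 1:4, predicted = c(2, 1, 4, 3))
  ec <- env_correlations(df)
  expect_equal(ec$correlations$r, 0.6)
  expect_equal(ec$correlations$V, (1 - 0.36) / 2)

  # zero-variance environments are excluded
  df <- data.frame(env = rep(c("e1", "e2"), each = 3),
                   observed = c(1, 2, 3, 5, 5, 5),
                   predicted = c(1.1, 2.2, 2.9, 1, 2, 3))
  ec <- env_correlations(df)
  expect_equal(ec$correlations$env, "e1")
  expect_equal(ec$skipped$env, "e2")
})

test_that("weighted mean correlation matches hand evaluation", {
  # constant r: weighted mean of a constant is the constant
  entries <- data.frame(env = c("a", "b", "c"), r = 0.4, n = c(5, 10, 50))
  entries$V <- (1 - entries$r^2) / (entries$n - 2)
  expect_equal(weighted_mean_correlation(entries), 0.4)

  # r = (0.5, 0.0), n = (10, 10): V = (0.09375, 0.125),
  # weights (10.667, 8) -> r_w = 0.2857
  entries <- data.frame(env = c("a", "b"), r = c(0.5, 0), n = c(10, 10))
  entries$V <- (1 - entries$r^2) / (entries$n - 2)
  expect_equal(weighted_mean_correlation(entries), 0.285714, tolerance = 1e-5)

  # single environment: r_w = r_1
  single <- entries[1, ]
  expect_equal(weighted_mean_correlation(single), 0.5)
  # r_w within [min r_j, max r_j]
  expect_true(weighted_mean_correlation(entries) >= 0 &&
                weighted_mean_correlation(entries) <= 0.5)
  expect_error(weighted_mean_correlation(entries[0, ]), "eligible")
})

test_that("variance percentages normalize across and within environments", {
  comp <- data.frame(term = c("E", "L", "G", "R"),
                     estimate = c(10, 10, 10, 10))
  across <- variance_percentages(comp, "across")
  expect_equal(across$pct, rep(25, 4))
  expect_equal(sum(across$pct), 100, tolerance = 1e-9)
  within <- variance_percentages(comp, "within")
  expect_false("E" %in% within$term)
  expect_equal(sum(within$pct), 100, tolerance = 1e-9)
  expect_error(variance_percentages(
    data.frame(term = "L", estimate = 0)), "zero")
  expect_error(variance_percentages(
    data.frame(term = "L", estimate = -1)), "nonnegative")
})

test_that("percentile grid classifies by empirical 20/50/80 cuts", {
  # perfect ranking: all mass on the diagonal blocks
  x <- as.numeric(1:100)
  g <- percentile_grid(x, x)
  expect_equal(unname(diag(g$proportions)), rep(1, 4))
  expect_equal(g$top20, 1)
  expect_equal(g$bottom20, 1)
  expect_equal(g$r_squared, 1)
  expect_equal(g$mse, 0)
  # columns are conditional distributions
  expect_equal(unname(colSums(g$proportions)), rep(1, 4))

  # reverse ranking: top-predicted mass lands in the bottom observed row
  g_rev <- percentile_grid(x, rev(x))
  expect_equal(g_rev$proportions["bottom20", "top20"], 1)
  expect_equal(g_rev$top20, 0)

  # 10-point example, success enumerated by hand: predicted top-2 are
  # positions 9,10 with observed (8, 9); observed top-2 are the values
  # (9, 10), so exactly one of two predicted-top genotypes is a true top
  obs <- c(1, 2, 3, 4, 5, 6, 7, 10, 8, 9)
  g10 <- percentile_grid(as.numeric(1:10), obs)
  expect_equal(g10$top20, 0.5)
  # and the pairwise-swap permutation keeps both top-2 inside the top bin
  obs2 <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  expect_equal(percentile_grid(as.numeric(1:10), obs2)$top20, 1)

  expect_error(percentile_grid(1:3, 1:3), "at least 5")
})

test_that("genotype_overall centers within environments then averages", {
  df <- data.frame(line = c("g1", "g2", "g3", "g1", "g2"),
                   env = c("e1", "e1", "e1", "e2", "e2"),
                   observed = c(10, 20, 30, 40, 50),
                   predicted = c(12, 18, 30, 42, 48))
  ov <- genotype_overall(df)
  # e1 means: obs 20, pred 20; e2 means: obs 45, pred 45
  expect_equal(ov$observed[ov$line == "g1"], mean(c(10 - 20, 40 - 45)))
  expect_equal(ov$predicted[ov$line == "g2"], mean(c(18 - 20, 48 - 45)))
  # line observed once: its overall value is its single centered value
  expect_equal(ov$observed[ov$line == "g3"], 10)

  # single environment: centered observed values sum to zero
  one <- df[df$env == "e1", ]
  expect_equal(sum(genotype_overall(one)$observed), 0)
})
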