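test_that("one-way ANOVA matches hand-computed sums of squares", {
  r <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  # SS_between = 13.5, SS_within = 4 -> F = 13.5, eta_p = 13.5/17.5
  expect_equal(r$statistic, 13.5)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 4)
  expect_equal(r$effect_size, 13.5 / 17.5)
  expect_equal(r$p, pf(13.5, 1, 4, lower.tail = FALSE))

  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)

  expect_error(anova_oneway(list(1:3)), class = "cb_argument_error")
  expect_error(anova_oneway(list(1:3, 5)), class = "cb_argument_error")
})

test_that("factorial ANOVA matches a hand-computed 2x2 decomposition", {
  # balanced 2x2 with 2 replicates per cell
  d <- data.frame(
    y = c(10, 12, 20, 22, 13, 15, 29, 31),
    A = rep(c("a1", "a2"), each = 4),
    B = rep(rep(c("b1", "b2"), each = 2), 2)
  )
  # hand decomposition: grand mean 19
  # A means 16, 22 -> SS_A = 4*(9+9) = 72
  # B means 12.5, 25.5 -> SS_B = 4*(6.5^2)*2 = 338
  # cell means 11,21,14,30; interaction deviations +/-1.5 -> SS_AB = 18
  # residual: each cell var 2 -> SS_err = 8, df_err = 4
  res <- anova_factorial(d, "y", c("A", "B"))
  expect_equal(res$A$statistic, (72 / 1) / (8 / 4))
  expect_equal(res$B$statistic, (338 / 1) / (8 / 4))
  expect_equal(res[["A x B"]]$statistic, (18 / 1) / (8 / 4))
  expect_equal(res$A$effect_size, 72 / 80)
  expect_equal(res$B$effect_size, 338 / 346)
  expect_equal(res[["A x B"]]$effect_size, 18 / 26)
  expect_equal(res$A$df2, 4)

  # swapping the factor order leaves every balanced-design F unchanged
  res2 <- anova_factorial(d, "y", c("B", "A"))
  expect_equal(res2$A$statistic, res$A$statistic)
  expect_equal(res2$B$statistic, res$B$statistic)
  expect_equal(res2[["B x A"]]$statistic, res[["A x B"]]$statistic)
})

test_that("additive cell means produce a null interaction", {
  # cell means exactly additive; replicates differ so the error SS is
  # positive and the interaction F is well defined (and zero)
  d <- expand.grid(A = c("a1", "a2", "a3"), B = c("b1", "b2"),
    rep = 1:2)
  d$y <- as.numeric(d$A) * 2 + as.numeric(d$B) * 5 +
    ifelse(d$rep == 1, -1, 1)
  res <- anova_factorial(d, "y", c("A", "B"))
  expect_equal(res[["A x B"]]$statistic, 0, tolerance = 1e-9)
  expect_equal(res[["A x B"]]$effect_size, 0, tolerance = 1e-9)

  d2 <- d[-1, ]
  d2$A <- as.character(d2$A)
  d2$B <- as.character(d2$B)
  d3 <- d2[!(d2$A == "a1" & d2$B == "b1"), ] # empty cell
  expect_error(anova_factorial(d3, "y", c("A", "B")),
    class = "cb_argument_error")
})

test_that("paired t follows the difference-based definition", {
  r <- paired_t(c(1, 2, 3), c(3, 2, 1)) # diffs -2, 0, 2
  expect_equal(r$statistic, 0)
  expect_equal(r$effect_size, 0)
  expect_equal(r$p, 1)

  same <- paired_t(c(4, 7, 1), c(4, 7, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)
  expect_equal(same$p, 1)

  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)),
    class = "cb_argument_error") # constant nonzero difference
  expect_error(paired_t(1:3, 1:2), class = "cb_argument_error")

  # hand check: diffs {1, 2, 3}, mean 2, sd 1 -> t = 2*sqrt(3), d = 2
  r2 <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r2$effect_size, 2)
  expect_equal(r2$df1, 2)
})

test_that("post hocs adjust pairwise p values per their definitions", {
  withr::with_seed(5, {
    g <- list(a = rnorm(8, 0), b = rnorm(8, 1), c = rnorm(8, 3))
  })
  bon <- posthoc(g, "bonferroni")
  expect_equal(bon$p_adj, pmin(1, bon$p_raw * 3))
  expect_true(all(bon$p_adj >= bon$p_raw))

  tk <- posthoc(g, "tukey_hsd")
  expect_true(all(tk$p_adj >= tk$p_raw - 1e-12))

  # brute-force studentised-range check on a small toy
  toy <- list(g1 = c(1, 2, 3, 4, 5), g2 = c(3, 4, 5, 6, 7),
    g3 = c(8, 9, 10, 11, 12))
  tk2 <- posthoc(toy, "tukey_hsd")
  mse <- mean(c(var(toy$g1), var(toy$g2), var(toy$g3)))
  qstat <- abs(mean(toy$g1) - mean(toy$g2)) / sqrt(mse / 5)
  p_expected <- ptukey(qstat, nmeans = 3, df = 12, lower.tail = FALSE)
  expect_equal(tk2$p_adj[tk2$comparison == "g1 - g2"], p_expected,
    tolerance = 1e-9)

  # identical groups: every adjusted p at 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_true(all(posthoc(same, "tukey_hsd")$p_adj > 1 - 1e-9))
  expect_true(all(posthoc(same, "bonferroni")$p_adj == 1))

  expect_error(posthoc(g, "holm"))
})

test_that("F, t, p and effect sizes are scale invariant", {
  withr::with_seed(17, {
    a <- rnorm(10, 5, 2)
    b <- rnorm(10, 6, 2)
    cc <- rnorm(10, 7, 2)
  })
  for (k in c(0.2, 10)) {
    r1 <- anova_oneway(list(a, b, cc))
    r2 <- anova_oneway(list(k * a, k * b, k * cc))
    expect_equal(r2$statistic, r1$statistic)
    expect_equal(r2$p, r1$p)
    expect_equal(r2$effect_size, r1$effect_size)
    t1 <- paired_t(a, b)
    t2 <- paired_t(k * a, k * b)
    expect_equal(t2$statistic, t1$statistic)
    expect_equal(t2$effect_size, t1$effect_size)
  }
})
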