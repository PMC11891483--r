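test_that("rank-sum test matches the brute-force U and orients its effect size", {
  rs <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$rank_biserial, -1)            # complete separation, x smaller
  expect_equal(ranksum_test(c(4, 5, 6), c(1, 2, 3))$rank_biserial, 1)
  set.seed(101)
  for (r in 1:5) {
    x <- sample(1:20, 4); y <- sample(1:20, 4)
    rs4 <- ranksum_test(x, y)
    expect_equal(rs4$statistic, brute_u(x, y))
    expect_equal(rs4$rank_biserial, 2 * brute_u(x, y) / 16 - 1)
  }
  expect_error(ranksum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum p-values are calibrated under a distributional null", {
  set.seed(102)
  ps <- replicate(300, ranksum_test(rnorm(25), rnorm(25))$p_value)
  rs <- replicate(300, ranksum_test(rnorm(25), rnorm(25))$rank_biserial)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("categorical test picks its method and computes Cramer's V", {
  perfect <- categorical_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(perfect$cramers_v, 1)
  indep <- categorical_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(indep$cramers_v, 0)
  expect_equal(indep$p_value, 1)
  # sparse 2x2 -> Fisher's exact
  sparse <- categorical_test(matrix(c(3, 1, 1, 4), 2))
  expect_equal(sparse$method, "fisher")
  expect_equal(sparse$p_value, fisher.test(matrix(c(3, 1, 1, 4), 2))$p.value)
  # 2x3 chi-squared against the hand-computed expected-count formula
  tab <- matrix(c(10, 20, 30, 25, 15, 20), 2, byrow = TRUE)
  ct <- categorical_test(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  expect_equal(ct$cramers_v, sqrt(chi2 / sum(tab)))
  expect_equal(ct$p_value, pchisq(chi2, 2, lower.tail = FALSE))
  expect_error(categorical_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
})

test_that("BH adjustment matches the step-up computation and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  perm <- sample(6)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("covariate-adjusted permutation test is calibrated and seeded", {
  set.seed(103)
  # null: outcome independent of group given covariates
  rej <- 0L
  for (r in 1:60) {
    cov <- rnorm(40)
    g <- rbinom(40, 1, 0.5)
    y <- 0.5 * cov + rnorm(40)
    p <- adjusted_perm_test(y, g, data.frame(cov = cov), n_perm = 99,
                            seed = 200 + r)$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 8)   # ~5% nominal, binomial slack at 60 replicates
  # strong effect -> p at the permutation floor
  g <- rep(0:1, each = 50)
  y <- 2 * g + rnorm(100)
  strong <- adjusted_perm_test(y, g, n_perm = 199, seed = 104)
  expect_equal(strong$p_value, 1 / 200)
  expect_identical(adjusted_perm_test(y, g, n_perm = 199, seed = 104)$p_value,
                   strong$p_value)
})

test_that("covariate-free permutation test agrees with exact label permutation", {
  set.seed(105)
  x <- rnorm(10)
  g <- rep(0:1, each = 5)
  p_perm <- adjusted_perm_test(x, g, n_perm = 1999, seed = 106)$p_value
  # exact permutation distribution of the two-sample t over all 252 splits
  combs <- combn(10, 5)
  t_obs <- abs(t.test(x[g == 1], x[g == 0], var.equal = TRUE)$statistic)
  t_all <- apply(combs, 2, function(idx)
    abs(t.test(x[idx], x[-idx], var.equal = TRUE)$statistic))
  p_exact <- mean(t_all >= t_obs - 1e-12)
  expect_equal(p_perm, p_exact, tolerance = 0.05)
})

test_that("interaction permutation test is symmetric and powered for crossover", {
  set.seed(107)
  n <- 160
  a <- rep(0:1, each = n / 2)
  b <- rep(0:1, n / 2)
  y_add <- 0.4 * a + 0.4 * b + rnorm(n)
  p_add <- interaction_behaviour_test(y_add, a, b, n_perm = 99, seed = 108)
  y_int <- 1.2 * a * b + rnorm(n)
  p_int <- interaction_behaviour_test(y_int, a, b, n_perm = 99, seed = 109)
  expect_lt(p_int$p_value, 0.05)
  # swapping factor roles leaves the interaction p unchanged
  p_swap <- interaction_behaviour_test(y_int, b, a, n_perm = 99, seed = 109)
  expect_equal(p_swap$p_value, p_int$p_value)
  expect_error(interaction_behaviour_test(y_add, rep(1, n), b), "two levels")
})

test_that("interaction test keeps its size on additive data and power on crossover", {
  set.seed(110)
  n <- 160
  a <- rep(0:1, each = n / 2)
  b <- rep(0:1, n / 2)
  null_hits <- 0L
  power_hits <- 0L
  for (r in 1:40) {
    y0 <- 0.5 * a + 0.5 * b + rnorm(n)
    if (interaction_behaviour_test(y0, a, b, n_perm = 59,
                                   seed = 300 + r)$p_value < 0.05)
      null_hits <- null_hits + 1L
    y1 <- 1.0 * a * b + rnorm(n)   # crossover-scale interaction at n = 160
    if (interaction_behaviour_test(y1, a, b, n_perm = 59,
                                   seed = 400 + r)$p_value < 0.05)
      power_hits <- power_hits + 1L
  }
  expect_lte(null_hits, 6)          # ~>=90% quiet under additivity
  expect_gte(power_hits / 40, 0.8)  # power > 0.8 at the planted effect
})

test_that("profile table mirrors the per-feature tests it wraps", {
  set.seed(111)
  x <- cbind(f1 = c(rnorm(30), rnorm(30, 1.5)), f2 = rnorm(60))
  g <- factor(rep(c("A", "B"), each = 30))
  tab <- behavioural_profile_table(x, g, n_perm = 99, seed = 112)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$p_value[1], ranksum_test(x[1:30, 1], x[31:60, 1])$p_value)
  expect_equal(tab$p_fdr, bh_fdr(tab$p_value))
  expect_lt(tab$rank_biserial[1], 0)   # first group smaller on f1
  expect_lt(tab$p_adjusted_fdr[1], 0.05)
  expect_gt(tab$p_value[2], 0.05)
})
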