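test_that("edgewise GLM matches per-edge lm and the two-sample t", {
  set.seed(81)
  n <- 20
  y <- matrix(rnorm(n * 45), n)          # 10-node stack, 45 edges
  g <- rep(0:1, each = n / 2)
  x <- cbind(1, g, rnorm(n))
  colnames(x) <- c("(Intercept)", "g", "cov")
  fit <- fit_edgewise_glm(y, x, "g")
  oracle <- apply(y, 2, function(col)
    summary(lm(col ~ g + x[, 3]))$coefficients["g", "t value"])
  expect_lt(max(abs(fit$t - oracle)), 1e-8)
  expect_equal(fit$df, n - 3)
  # no covariates -> classic pooled-variance two-sample t
  fit2 <- fit_edgewise_glm(y[, 1, drop = FALSE], cbind(1, g), 2)
  classic <- t.test(y[g == 1, 1], y[g == 0, 1], var.equal = TRUE)$statistic
  expect_equal(fit2$t, unname(classic), tolerance = 1e-10)
  # constant outcome -> degenerate edge flagged as t = 0
  y0 <- y; y0[, 3] <- 5
  expect_equal(fit_edgewise_glm(y0, x, "g")$t[3], 0)
  expect_error(fit_edgewise_glm(y, cbind(x, x[, 2]), 2), "rank")
})

test_that("supra-threshold retention follows the one-sided t quantile", {
  statmap <- list(t = c(2.4, 2.3, -2.4, 0), df = 100)
  expect_equal(qt(1 - 0.01, 100), 2.364, tolerance = 1e-3)
  expect_equal(suprathreshold_edges(statmap, 0.01, "positive"), 1L)
  expect_equal(suprathreshold_edges(statmap, 0.01, "negative"), 3L)
  # threshold -> 1 keeps everything
  expect_length(suprathreshold_edges(statmap, 0.9999, "positive"), 4)
  # all-negative t map under the positive tail -> empty
  expect_length(suprathreshold_edges(list(t = rep(-3, 5), df = 50), 0.05,
                                     "positive"), 0)
})

test_that("component extraction partitions edges like a union-find oracle", {
  ei <- edge_index(7)
  find_edge <- function(i, j) which(ei[, 1] == i & ei[, 2] == j)
  edges <- c(find_edge(1, 2), find_edge(2, 3), find_edge(5, 6))
  tv <- rep(0, nrow(ei)); tv[edges] <- c(2.5, 3.0, 1.5)
  comps <- extract_components(edges, ei, 7, tv)
  expect_length(comps, 2)
  expect_equal(vapply(comps, `[[`, numeric(1), "extent"), c(2, 1))
  expect_equal(comps[[1]]$strength, 5.5)
  expect_equal(comps[[1]]$nodes, 1:3)
  # nodal degrees as percentage of component edges, summing to 200
  expect_equal(sum(comps[[1]]$nodal_degree_percent), 200)
  expect_equal(unname(comps[[1]]$nodal_degree_percent["2"]), 100)
  # random graphs vs union-find oracle
  set.seed(82)
  ei30 <- edge_index(30)
  for (rep in 1:5) {
    sel <- sample(nrow(ei30), 40)
    tv30 <- runif(nrow(ei30), 1, 3)
    comps30 <- extract_components(sel, ei30, 30, tv30)
    uf <- union_find_components(ei30[sel, , drop = FALSE], 30)
    for (cmp in comps30) {
      expect_length(unique(uf[cmp$nodes]), 1)          # together in oracle
      others <- setdiff(unique(as.vector(ei30[sel, ])), cmp$nodes)
      expect_false(uf[cmp$nodes[1]] %in% uf[others])   # maximal
    }
    expect_equal(sum(vapply(comps30, `[[`, numeric(1), "extent")), 40)
  }
  expect_error(extract_components(6L, edge_index(4), 2, rep(1, 6)), "beyond")
})

test_that("permutation p-values respect the add-one convention and seed contract", {
  set.seed(83)
  md <- data.frame(group = factor(rep(c("A", "B"), each = 30)))
  spec <- planted_component_spec(n_nodes = 15, n_edges_planted = 12,
                                 delta = 0.8, edge_noise_sd = 0.2, seed = 84)
  stk <- gen_connectome_stack(md, spec)
  ei <- edge_index(15)
  y <- t(apply(stk$stack, 3, function(m) m[ei]))
  x <- build_design(md, ~ group)
  cfg <- nbs_config(p_threshold = 0.01, n_perm = 99, seed = 85)
  res <- permutation_fwer(y, x, "groupB", cfg, "positive", 15)
  expect_gt(length(res$components), 0)
  p <- vapply(res$components, `[[`, numeric(1), "p_fwer")
  expect_true(all(p >= 1 / 100 & p <= 1))
  expect_equal(min(p), 1 / 100)  # planted effect beats all 99 permutations
  # monotone: smaller strength cannot get smaller p within one run
  st <- vapply(res$components, `[[`, numeric(1), "strength")
  expect_true(all(diff(p[order(st)]) <= 0))
  res2 <- permutation_fwer(y, x, "groupB", cfg, "positive", 15)
  expect_identical(res2$null_max, res$null_max)
})

test_that("run_nbs recovers a planted component and splits tails exclusively", {
  set.seed(86)
  n <- 80
  md <- data.frame(group = factor(rep(c("VPT", "FT"), each = n / 2),
                                  levels = c("VPT", "FT")),
                   fd = rlnorm(n, log(0.13), 0.3),
                   age = rnorm(n, 30, 3))
  spec <- planted_component_spec(n_nodes = 25, n_edges_planted = 20,
                                 delta = 0.5, seed = 87)
  stk <- gen_connectome_stack(md, spec)
  cfg <- nbs_config(p_threshold = 0.01, n_perm = 99, seed = 88)
  rep_nbs <- run_nbs(stk$stack, md, ~ group + fd + age, config = cfg)
  pos <- rep_nbs$positive$components
  expect_gt(length(pos), 0)
  top <- pos[[1]]
  expect_lt(top$p_fwer, 0.05)
  rec <- length(intersect(top$edges$edge, stk$true_edge_idx)) /
    length(stk$true_edge_idx)
  expect_gt(rec, 0.7)
  # the two one-sided supra-threshold sets cannot share edges
  pos_edges <- unlist(lapply(rep_nbs$positive$components, function(c) c$edges$edge))
  neg_edges <- unlist(lapply(rep_nbs$negative$components, function(c) c$edges$edge))
  expect_length(intersect(pos_edges, neg_edges), 0)
})

test_that("interaction contrasts stay quiet on additive-only data", {
  set.seed(89)
  n <- 48
  md <- data.frame(g = factor(rep(c("A", "B"), each = n / 2)),
                   s = factor(rep(c("x", "y"), n / 2)))
  ei <- edge_index(10)
  hits <- 0L
  for (r in 1:20) {
    # additive effects only, no interaction
    y <- matrix(rnorm(n * nrow(ei)), n) +
      0.3 * (md$g == "B") + 0.2 * (md$s == "y")
    cfg <- nbs_config(p_threshold = 0.05, n_perm = 49, seed = 900 + r)
    res <- run_nbs(y, md, ~ g * s, config = cfg, contrast = "gB:sy")
    p_all <- c(vapply(res$positive$components, `[[`, numeric(1), "p_fwer"),
               vapply(res$negative$components, `[[`, numeric(1), "p_fwer"))
    if (length(p_all) && min(p_all) < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 4)  # ~90% quiet under the null
})
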