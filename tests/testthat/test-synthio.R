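test_that("cohort generator plants the requested feature structure", {
  # null case: no effects -> no mean differences at large n
  spec0 <- cohort_spec(n_subjects = 500, feature_effects = 0, seed = 21)
  coh0 <- gen_cohort(spec0)
  tvals <- apply(coh0$features, 2, function(f)
    t.test(f[coh0$subgroup == 1], f[coh0$subgroup == 2])$statistic)
  expect_lt(max(abs(tvals)), 4)
  expect_equal(ncol(coh0$features), 13)
  # planted case: large effects separate the subgroups
  spec3 <- cohort_spec(feature_effects = rep(c(3, 0), c(8, 5)), seed = 22)
  coh3 <- gen_cohort(spec3)
  diffs <- colMeans(coh3$features[coh3$subgroup == 2, ]) -
    colMeans(coh3$features[coh3$subgroup == 1, ])
  expect_true(all(diffs[1:8] > 2))
  expect_true(all(abs(diffs[9:13]) < 1))
  # metadata contract and determinism
  expect_named(coh3$metadata, c("subject_id", "group", "age", "sex", "ses", "fd"))
  expect_identical(gen_cohort(spec3), coh3)
  expect_error(cohort_spec(subgroup_fraction = 1.2), "subgroup_fraction")
  expect_error(cohort_spec(n_subjects = 0), "positive")
})

test_that("covariate model reproduces the group-confounded motion pattern", {
  coh <- gen_cohort(cohort_spec(n_subjects = 2000, seed = 23))
  md <- coh$metadata
  expect_gt(median(md$fd[md$group == "VPT"]), median(md$fd[md$group == "FT"]))
  expect_equal(median(md$fd[md$group == "VPT"]), 0.15, tolerance = 0.1)
  expect_gt(mean(md$sex[md$group == "VPT"] == "male"), 0.5)
  expect_equal(levels(md$ses), c("1", "2", "3"))
})

test_that("connectome stack plants a connected component with the stated effect", {
  md <- data.frame(group = factor(rep(c("A", "B"), each = 60)))
  spec <- planted_component_spec(n_nodes = 30, n_edges_planted = 25,
                                 delta = 0.4, seed = 31)
  res <- gen_connectome_stack(md, spec)
  expect_equal(dim(res$stack), c(30, 30, 120))
  s1 <- res$stack[, , 1]
  expect_equal(s1, t(s1))
  expect_equal(diag(s1), rep(0, 30))
  # planted edges connected (union-find oracle)
  comp <- union_find_components(res$true_edges, 30)
  touched <- unique(as.vector(res$true_edges))
  expect_equal(length(unique(comp[touched])), 1)
  # group mean difference ~ delta on planted edges, ~0 elsewhere
  ei <- edge_index(30)
  y <- t(apply(res$stack, 3, function(m) m[ei]))
  dmean <- colMeans(y[md$group == "B", ]) - colMeans(y[md$group == "A", ])
  expect_equal(mean(dmean[res$true_edge_idx]), 0.4, tolerance = 0.05)
  expect_equal(mean(dmean[-res$true_edge_idx]), 0, tolerance = 0.02)
  expect_error(planted_component_spec(n_nodes = 4, n_edges_planted = 7),
               "possible")
})

test_that("time-series generator yields block-structured band-limited signals", {
  part <- factor(rep(c("a", "b"), each = 6))
  ts <- gen_timeseries(3, 12, n_timepoints = 256, tr_seconds = 2,
                       partition = part, rho = 0.5, seed = 41)
  expect_length(ts, 3)
  expect_equal(dim(ts[[1]]), c(256, 12))
  r <- correlation_matrix(ts[[1]])
  same <- outer(part, part, "==") & upper.tri(r)
  diff <- !outer(part, part, "==") & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[diff]))
  # duplicated columns stay perfectly correlated through the pipeline
  dup <- cbind(ts[[1]], ts[[1]][, 1])
  expect_equal(correlation_matrix(dup)[1, 13], 1)
  expect_error(gen_timeseries(1, 4, n_timepoints = 4), "8")
})

test_that("partition generator covers all labels and honours forced sizes", {
  p8 <- gen_partition(8, 8, seed = 51)
  expect_equal(sort(as.character(p8)), sort(intrinsic_networks))
  p374 <- gen_partition(374, 8, n_subcortical = 16, seed = 52)
  expect_equal(sum(p374 == "subcortical"), 16)
  expect_true(all(table(p374) >= 1))
  expect_identical(gen_partition(50, 8, seed = 53), gen_partition(50, 8, seed = 53))
  expect_error(gen_partition(5, 8), "networks")
})
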