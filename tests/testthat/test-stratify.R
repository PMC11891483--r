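test_that("standardization centres and scales every feature", {
  expect_equal(as.vector(standardize(matrix(1:3))), c(-1, 0, 1))
  set.seed(61)
  x <- matrix(rnorm(156 * 13, mean = 5, sd = 3), 156)
  z <- standardize(x)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(apply(z, 2, sd), rep(1, 13), ignore_attr = TRUE)
  expect_equal(unname(standardize(z)), unname(z), tolerance = 1e-12) # idempotent
  colnames(x) <- paste0("f", 1:13)
  x[, 4] <- 7
  expect_error(standardize(x), "f4")
})

test_that("euclidean distances match a brute-force double loop", {
  expect_equal(euclidean_distance(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  set.seed(62)
  x <- matrix(rnorm(12 * 4), 12)
  d <- euclidean_distance(x)
  brute <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) brute[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  expect_equal(d, brute, ignore_attr = TRUE)
  expect_equal(diag(d), rep(0, 12), ignore_attr = TRUE)
})

test_that("affinity kernel matches its formula and behaves monotonically", {
  set.seed(63)
  x <- matrix(rnorm(5 * 2), 5)
  d <- euclidean_distance(x)
  w <- affinity_network(d, k = 2, alpha = 0.5)
  # brute-force recomputation of the locally scaled kernel
  mu <- sapply(1:5, function(i) mean(sort(d[i, -i])[1:2]))
  for (i in 1:5) for (j in 1:5) {
    eps <- (mu[i] + mu[j] + d[i, j]) / 3
    expected <- if (d[i, j] == 0) 1 else exp(-d[i, j]^2 / (2 * (0.5 * eps)^2))
    expect_equal(w[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(diag(unclass(w)), rep(1, 5), ignore_attr = TRUE)
  # monotone: for fixed scale, larger distance -> smaller weight
  expect_true(all(diff(exp(-(1:5)^2 / (2 * 0.7^2))) < 0))
  expect_error(affinity_network(d, k = 5, alpha = 0.5), "k")
})

test_that("spectral clustering recovers planted blob and block structure", {
  blobs <- make_blobs(20, rbind(c(0, 0), c(6, 6)), seed = 64)
  w <- affinity_network(euclidean_distance(standardize(blobs$x)), 10, 0.5)
  lab <- spectral_cluster(w, 2, seed = 7)
  expect_equal(adjusted_rand_index(blobs$labels, lab), 1)
  # exact block-diagonal similarity, 3 blocks
  wb <- matrix(0.001, 30, 30)
  for (b in 0:2) wb[b * 10 + 1:10, b * 10 + 1:10] <- 1
  lab3 <- spectral_cluster(wb, 3, seed = 8)
  expect_equal(adjusted_rand_index(rep(1:3, each = 10), lab3), 1)
  # determinism and subject-order equivariance
  expect_identical(spectral_cluster(w, 2, seed = 9), spectral_cluster(w, 2, seed = 9))
  perm <- sample(40)
  lab_p <- spectral_cluster(w[perm, perm], 2, seed = 9)
  expect_equal(adjusted_rand_index(lab_p, spectral_cluster(w, 2, seed = 9)[perm]), 1)
  expect_error(spectral_cluster(w, 1), "C")
})

test_that("bootstrap consensus yields bimodal co-clustering on separated blobs", {
  blobs <- make_blobs(18, rbind(c(0, 0), c(7, 7)), seed = 65)
  w <- affinity_network(euclidean_distance(standardize(blobs$x)), 8, 0.5)
  cons <- bootstrap_consensus(w, 2, n_bootstrap = 100, seed = 10)
  expect_equal(adjusted_rand_index(blobs$labels, cons$labels), 1)
  off <- cons$co_cluster[upper.tri(cons$co_cluster)]
  expect_true(all(off < 0.05 | off > 0.95))
  expect_equal(cons$co_cluster, t(cons$co_cluster))
  expect_true(all(cons$co_cluster >= 0 & cons$co_cluster <= 1))
  expect_true(all(diag(cons$co_cluster)[diag(cons$co_sampled) > 0] == 1))
})

test_that("degenerate single full-sample resample reproduces one spectral run", {
  blobs <- make_blobs(10, rbind(c(0, 0), c(5, 5)), seed = 66)
  w <- affinity_network(euclidean_distance(standardize(blobs$x)), 5, 0.5)
  cons <- bootstrap_consensus(w, 2, n_bootstrap = 1, inner_subsample = 0.999,
                              seed = 12)
  expect_true(all(cons$co_cluster %in% c(0, 1)))
  co <- outer(cons$labels, cons$labels, "==") * 1
  expect_equal(unname(cons$co_cluster), co, ignore_attr = TRUE)
})

test_that("silhouette matches closed forms and the brute-force formula", {
  d4 <- as.matrix(dist(c(0, 0, 10, 10)))
  expect_equal(silhouette_width(c(1, 1, 2, 2), d4), 1)
  dz <- matrix(0, 4, 4)
  expect_equal(silhouette_width(c(1, 1, 2, 2), dz), 0)
  set.seed(67)
  x <- matrix(rnorm(25 * 3), 25)
  d <- euclidean_distance(x)
  lab <- sample(1:3, 25, TRUE)
  expect_equal(silhouette_width(lab, d), brute_silhouette(lab, d))
  expect_lt(abs(silhouette_width(lab, d)), 0.2)  # structureless data
  # label-permutation invariance
  relab <- c(3, 1, 2)[lab]
  expect_equal(silhouette_width(relab, d), silhouette_width(lab, d))
  expect_error(silhouette_width(rep(1, 25), d), "2 clusters")
})

test_that("grid selection evaluates the full K-alpha grid and recovers truth", {
  blobs <- make_blobs(25, rbind(c(0, 0), c(6, 6)), seed = 68)
  cfg <- stratify_config(k_grid = c(5, 10), alpha_grid = c(0.4, 0.8),
                         n_bootstrap = 30, nstart = 3)
  sol <- select_best_grid(standardize(blobs$x), 2, cfg, seed = 13)
  expect_equal(nrow(sol$grid), 4)
  expect_equal(adjusted_rand_index(blobs$labels, sol$labels), 1)
  expect_true(sol$k %in% cfg$k_grid && sol$alpha %in% cfg$alpha_grid)
  expect_equal(sol$silhouette, max(sol$grid$silhouette))
  # default grids span 30 combinations
  dflt <- stratify_config()
  expect_equal(length(dflt$k_grid) * length(dflt$alpha_grid), 30)
})

test_that("subsampled consensus labels every subject and recovers planted subgroups", {
  spec <- cohort_spec(n_subjects = 60, feature_effects = rep(c(3, 0), c(8, 5)),
                      seed = 69)
  coh <- gen_cohort(spec)
  cfg <- stratify_config(k_grid = c(10, 20), alpha_grid = c(0.4, 0.7),
                         n_repeats = 20, n_bootstrap = 25, nstart = 3, seed = 70)
  res <- subsample_consensus(coh$features, 2, cfg)
  expect_length(res$solution$labels, 60)
  expect_gt(adjusted_rand_index(coh$subgroup, res$solution$labels), 0.9)
  expect_equal(nrow(res$solution$provenance), 20)
  expect_true(all(res$co_cluster >= 0 & res$co_cluster <= 1))
  # determinism under the master seed
  res2 <- subsample_consensus(coh$features, 2, cfg)
  expect_identical(res2$solution$labels, res$solution$labels)
})

test_that("cluster-number criteria find planted block counts", {
  wb <- matrix(0.001, 30, 30)
  for (b in 0:2) wb[b * 10 + 1:10, b * 10 + 1:10] <- 1
  est <- estimate_num_clusters(wb, 2:6)
  expect_equal(est$eigengap$best, 3)
  expect_equal(est$rotation_cost$best, 3)
  # two blobs -> 2 by both criteria; adding a third moves the estimate to 3
  b2 <- make_blobs(20, rbind(c(0, 0), c(8, 8)), sd = 0.3, seed = 71)
  w2 <- affinity_network(euclidean_distance(standardize(b2$x)), 10, 0.5)
  e2 <- estimate_num_clusters(w2, 2:5)
  expect_equal(e2$eigengap$best, 2)
  expect_equal(e2$rotation_cost$best, 2)
  b3 <- make_blobs(20, rbind(c(0, 0), c(8, 8), c(-8, 8)), sd = 0.3, seed = 72)
  w3 <- affinity_network(euclidean_distance(standardize(b3$x)), 10, 0.5)
  e3 <- estimate_num_clusters(w3, 2:5)
  expect_equal(e3$eigengap$best, 3)
  expect_equal(e3$rotation_cost$best, 3)
  expect_error(estimate_num_clusters(wb, 2:40), "candidates")
})

test_that("clustering recovery improves with planted effect size", {
  ari_at <- function(d_eff) {
    spec <- cohort_spec(n_subjects = 60,
                        feature_effects = rep(c(d_eff, 0), c(8, 5)), seed = 73)
    coh <- gen_cohort(spec)
    cfg <- stratify_config(k_grid = 10, alpha_grid = 0.5, n_repeats = 15,
                           n_bootstrap = 20, nstart = 3, seed = 74)
    res <- subsample_consensus(coh$features, 2, cfg)
    adjusted_rand_index(coh$subgroup, res$solution$labels)
  }
  aris <- c(ari_at(1), ari_at(2), ari_at(3))
  expect_true(all(diff(aris) >= 0))
  expect_gt(aris[3], 0.9)
})
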