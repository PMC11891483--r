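# Data-driven behavioural stratification: affinity-kernel similarity
# networks over a K x alpha grid, nested resampled spectral clustering,
# silhouette-based grid selection, outer 80%-subsample consensus, and
# eigengap / rotation-cost estimation of the number of clusters.

#' Configuration for the consensus-clustering pipeline
#'
#' Default grids follow the recommended hyper-parameter ranges of locally
#' scaled affinity kernels: neighbourhood sizes K in 10..30 and edge
#' weighting alpha in 0.3..0.8, giving 30 K-alpha combinations. Defaults for
#' the resampling depth are 1000 inner resamples and 1000 outer repeats at
#' an 80% subsample; analyses on small cohorts can reduce both (see the
#' methods vignette for the scaled-down settings used in the bundled
#' analyses).
#'
#' @param k_grid Neighbourhood sizes for the affinity kernel.
#' @param alpha_grid Edge-weighting values for the affinity kernel.
#' @param n_bootstrap Inner resamples per grid point.
#' @param n_repeats Outer subsample repeats.
#' @param subsample_fraction Fraction of subjects per outer repeat (0, 1).
#' @param candidate_c Cluster numbers worth evaluating.
#' @param inner_resample `"subsample"` (without replacement, default) or
#'   `"bootstrap"` (with replacement) for the inner resampling.
#' @param nstart k-means restarts inside each spectral run.
#' @param seed Master seed; spawns independent per-repeat streams.
#' @return A list of class `"stratify_config"`.
#' @export
stratify_config <- function(k_grid = c(10, 15, 20, 25, 30),
                            alpha_grid = c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
                            n_bootstrap = 1000,
                            n_repeats = 1000,
                            subsample_fraction = 0.8,
                            candidate_c = c(2, 3, 5),
                            inner_resample = c("subsample", "bootstrap"),
                            nstart = 5,
                            seed = NULL) {
  if (!length(k_grid) || !length(alpha_grid)) stop("grids must be non-empty")
  if (!(subsample_fraction > 0 && subsample_fraction < 1))
    stop("`subsample_fraction` must be in (0, 1)")
  if (n_bootstrap < 1 || n_repeats < 1) stop("resample counts must be >= 1")
  structure(list(k_grid = sort(k_grid), alpha_grid = sort(alpha_grid),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_repeats = as.integer(n_repeats),
                 subsample_fraction = subsample_fraction,
                 candidate_c = candidate_c,
                 inner_resample = match.arg(inner_resample),
                 nstart = as.integer(nstart), seed = seed),
            class = "stratify_config")
}

#' Standardize behavioural features
#'
#' Centres every feature to mean 0 and scales to sample standard deviation 1.
#'
#' @param features Numeric matrix or data frame, subjects x features, no
#'   missing values.
#' @return Standardized numeric matrix.
#' @export
standardize <- function(features) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("features must be numeric")
  if (anyNA(x)) stop("missing feature values are not supported; impute or drop first")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    stop("constant feature(s): ", paste(bad, collapse = ", "))
  }
  scale(x)[, , drop = FALSE]
}

#' Euclidean distance matrix between subjects
#'
#' @param features Numeric matrix, subjects x features (normally the output
#'   of [standardize()]).
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
euclidean_distance <- function(features) {
  as.matrix(dist(as.matrix(features), method = "euclidean"))
}

#' Locally scaled affinity (similarity) network
#'
#' Builds a subject similarity network from a distance matrix with a
#' locally scaled Gaussian kernel:
#' `W(i,j) = exp(-d(i,j)^2 / (2 * (alpha * eps(i,j))^2))` where
#' `eps(i,j) = (mean_i + mean_j + d(i,j)) / 3` and `mean_i` is the mean
#' distance from subject i to its K nearest neighbours (self excluded).
#' Larger K widens the local scale (denser networks); larger alpha retains
#' weaker edges.
#'
#' @param dist_mat Symmetric distance matrix.
#' @param k Neighbourhood size, `1 <= k < n`.
#' @param alpha Edge-weighting parameter (positive).
#' @return Symmetric similarity matrix with unit diagonal and attributes
#'   `k` and `alpha`.
#' @export
affinity_network <- function(dist_mat, k, alpha) {
  d <- as.matrix(dist_mat)
  n <- nrow(d)
  if (k < 1 || k >= n) stop("`k` must satisfy 1 <= k < n")
  if (alpha <= 0) stop("`alpha` must be positive")
  sorted <- apply(d, 1, sort)               # columns = rows of d, ascending
  mu <- colMeans(sorted[2:(k + 1), , drop = FALSE])
  eps <- (outer(mu, mu, "+") + d) / 3
  if (any(eps == 0 & d > 0)) stop("zero local scale with nonzero distance")
  sigma <- alpha * eps
  w <- ifelse(d == 0, 1, exp(-d^2 / (2 * sigma^2)))
  w <- (w + t(w)) / 2
  structure(w, k = k, alpha = alpha)
}

#' Spectral clustering of a similarity network
#'
#' Normalized spectral clustering: the C eigenvectors of the symmetric
#' normalized graph Laplacian with smallest eigenvalues are row-normalised
#' and partitioned by k-means (several restarts, best within-cluster sum of
#' squares kept). Deterministic for a fixed `seed`.
#'
#' @param w Similarity matrix (nonnegative, symmetric).
#' @param c_clusters Number of clusters, `2 <= C < n`.
#' @param seed Integer seed for the k-means restarts; if `NULL`, drawn from
#'   the R random stream.
#' @param nstart Number of k-means restarts.
#' @return Integer cluster labels in `1..C`, all clusters non-empty.
#' @export
spectral_cluster <- function(w, c_clusters, seed = NULL, nstart = 10) {
  w <- as.matrix(w)
  n <- nrow(w)
  if (c_clusters < 2 || c_clusters >= n) stop("`c_clusters` must satisfy 2 <= C < n")
  seed <- seed %||% spawn_seeds(NULL, 1)
  .spectral_cluster_cpp(w, as.integer(c_clusters), seed, as.integer(nstart))
}

#' Resampled consensus clustering of one similarity network
#'
#' Draws `n_bootstrap` resamples of the subjects, spectral-clusters the
#' corresponding subnetwork each time, and records for every subject pair
#' the proportion of resamples containing both in which they clustered
#' together. Final labels come from average-linkage hierarchical clustering
#' of `1 - co_cluster` cut at C.
#'
#' @param w Similarity matrix.
#' @param c_clusters Number of clusters.
#' @param n_bootstrap Number of inner resamples.
#' @param inner_subsample Fraction of subjects per resample.
#' @param seed Integer seed.
#' @param nstart k-means restarts per spectral run.
#' @param inner_resample `"subsample"` (without replacement) or `"bootstrap"`.
#' @return List with `co_cluster` (proportions; 0 where a pair was never
#'   co-sampled), `co_sampled` (joint inclusion counts) and `labels`.
#' @export
bootstrap_consensus <- function(w, c_clusters, n_bootstrap = 1000,
                                inner_subsample = 0.8, seed = NULL,
                                nstart = 5,
                                inner_resample = c("subsample", "bootstrap")) {
  w <- as.matrix(w)
  inner_resample <- match.arg(inner_resample)
  if (c_clusters < 2) stop("`c_clusters` must be >= 2")
  seed <- seed %||% spawn_seeds(NULL, 1)
  res <- .consensus_boot_cpp(w, as.integer(c_clusters), as.integer(n_bootstrap),
                             inner_subsample, seed, as.integer(nstart),
                             inner_resample == "bootstrap")
  both <- res$both
  never <- both == 0 & upper.tri(both)
  if (any(never))
    warning(sum(never), " subject pair(s) never co-sampled; consensus set to 0")
  co <- res$together / pmax(both, 1)        # 0 where never co-sampled
  labels <- consensus_labels(co, c_clusters)
  list(co_cluster = co, co_sampled = both, labels = labels)
}

# average-linkage hierarchical clustering of consensus dissimilarity
consensus_labels <- function(co_cluster, c_clusters, linkage = "average") {
  d <- 1 - co_cluster
  diag(d) <- 0
  unname(cutree(hclust(as.dist(d), method = linkage), k = c_clusters))
}

#' Mean silhouette width of a partition
#'
#' For subject i with within-cluster mean dissimilarity `a` and smallest
#' other-cluster mean dissimilarity `b`, `s(i) = (b - a) / max(a, b)`
#' (0 when `max(a, b) = 0`); members of singleton clusters score 0.
#'
#' @param labels Integer cluster labels.
#' @param dissimilarity Square dissimilarity matrix.
#' @return Mean of the per-subject silhouette widths, in \[-1, 1\].
#' @export
silhouette_width <- function(labels, dissimilarity) {
  d <- as.matrix(dissimilarity)
  n <- length(labels)
  if (nrow(d) != n) stop("labels and dissimilarity are misaligned")
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("silhouette needs at least 2 clusters")
  sizes <- table(factor(labels, levels = cl))
  # mean dissimilarity from every subject to every cluster
  sums <- sapply(cl, function(c) rowSums(d[, labels == c, drop = FALSE]))
  s <- numeric(n)
  for (idx in seq_len(n)) {
    c_own <- match(labels[idx], cl)
    n_own <- sizes[c_own]
    if (n_own == 1) { s[idx] <- 0; next }
    a <- sums[idx, c_own] / (n_own - 1)
    b <- min(sums[idx, -c_own] / sizes[-c_own])
    s[idx] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the best K-alpha grid point by silhouette
#'
#' Runs [bootstrap_consensus()] for every (K, alpha) combination in the
#' config grid and keeps the solution with the highest mean silhouette
#' width, computed on the consensus dissimilarity `1 - co_cluster`
#' (set `silhouette_basis = "euclidean"` to score on the input distances
#' instead). Ties break towards smaller K, then smaller alpha.
#'
#' @param features Standardized feature matrix (subjects x features).
#' @param c_clusters Number of clusters.
#' @param config A [stratify_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @param silhouette_basis `"consensus"` (default) or `"euclidean"`.
#' @return List with `labels`, `k`, `alpha`, `silhouette`, `co_cluster`,
#'   `c_clusters` and `grid` (silhouette per grid point).
#' @export
select_best_grid <- function(features, c_clusters, config = stratify_config(),
                             seed = NULL,
                             silhouette_basis = c("consensus", "euclidean")) {
  silhouette_basis <- match.arg(silhouette_basis)
  x <- as.matrix(features)
  dmat <- euclidean_distance(x)
  grid <- expand.grid(alpha = config$alpha_grid, k = config$k_grid)[, c("k", "alpha")]
  seeds <- spawn_seeds(seed %||% config$seed, nrow(grid))
  best <- NULL
  sil_all <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    w <- affinity_network(dmat, grid$k[g], grid$alpha[g])
    cons <- bootstrap_consensus(w, c_clusters, n_bootstrap = config$n_bootstrap,
                                seed = seeds[g], nstart = config$nstart,
                                inner_resample = config$inner_resample)
    diss <- if (silhouette_basis == "consensus") {
      d <- 1 - cons$co_cluster; diag(d) <- 0; d
    } else dmat
    sil <- silhouette_width(cons$labels, diss)
    sil_all[g] <- sil
    if (is.null(best) || sil > best$silhouette) {
      best <- list(labels = cons$labels, k = grid$k[g], alpha = grid$alpha[g],
                   silhouette = sil, co_cluster = cons$co_cluster,
                   c_clusters = c_clusters)
    }
  }
  best$grid <- cbind(grid, silhouette = sil_all)
  best
}

#' Subsampled consensus clustering of a behavioural cohort
#'
#' The full stratification pipeline: `n_repeats` times, a random
#' `subsample_fraction` of the cohort is drawn (without replacement) and
#' [select_best_grid()] is run on the subsample; the winning labels of every
#' repeat are accumulated into an outer consensus matrix (proportion of
#' joint inclusions in which two subjects co-clustered). Final labels come
#' from average-linkage hierarchical clustering of `1 - co_cluster` cut at
#' C, so every subject is labelled.
#'
#' @param features Feature matrix or data frame (subjects x features); it is
#'   standardized internally.
#' @param c_clusters Number of clusters.
#' @param config A [stratify_config()].
#' @return List with `co_cluster`, `co_sampled`, and `solution` (final
#'   `labels`, `c_clusters`, `mean_silhouette` on consensus dissimilarity,
#'   and `provenance`: chosen K, alpha and silhouette per repeat).
#' @export
subsample_consensus <- function(features, c_clusters, config = stratify_config()) {
  x <- standardize(features)
  n <- nrow(x)
  seeds <- spawn_seeds(config$seed, 2L * config$n_repeats)
  m <- round(config$subsample_fraction * n)
  together <- matrix(0, n, n)
  both <- matrix(0, n, n)
  prov <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    set.seed(seeds[r])
    idx <- sort(sample.int(n, m))
    sol <- select_best_grid(x[idx, , drop = FALSE], c_clusters, config,
                            seed = seeds[config$n_repeats + r])
    both[idx, idx] <- both[idx, idx] + 1
    same <- outer(sol$labels, sol$labels, "==")
    together[idx, idx] <- together[idx, idx] + same
    prov[[r]] <- data.frame(repeat_id = r, k = sol$k, alpha = sol$alpha,
                            silhouette = sol$silhouette)
  }
  if (any(diag(both) == 0))
    stop("subject(s) never sampled across repeats; increase `n_repeats`")
  co <- together / pmax(both, 1)
  labels <- consensus_labels(co, c_clusters)
  diss <- 1 - co
  diag(diss) <- 0
  list(co_cluster = co, co_sampled = both,
       solution = list(labels = labels, c_clusters = c_clusters,
                       mean_silhouette = silhouette_width(labels, diss),
                       provenance = do.call(rbind, prov)))
}

#' Estimate the number of clusters from a similarity network
#'
#' Two spectral criteria on the symmetric normalized graph Laplacian:
#' the eigengap (C maximizing the gap between the C-th and (C+1)-th
#' ascending eigenvalues) and a rotation-cost criterion (C minimizing the
#' residual of rotating the C-dimensional spectral embedding onto a
#' cluster-indicator matrix, scaled by the eigenvalue ratio). Both return
#' the best and second-best candidate.
#'
#' @param w Similarity matrix.
#' @param candidates Candidate cluster numbers, within `[2, n - 1]`.
#' @return List with components `eigengap` and `rotation_cost`, each a list
#'   of `best`, `second` and the per-candidate criterion values.
#' @export
estimate_num_clusters <- function(w, candidates = 2:10) {
  w <- as.matrix(w)
  n <- nrow(w)
  if (any(candidates < 2) || any(candidates > n - 1))
    stop("candidates must lie in [2, n - 1]")
  deg <- pmax(rowSums(w), .Machine$double.eps)
  dis <- 1 / sqrt(deg)
  lap <- diag(n) - w * outer(dis, dis)
  es <- eigen((lap + t(lap)) / 2, symmetric = TRUE)
  lambda <- rev(es$values)                       # ascending
  vecs <- es$vectors[, n:1, drop = FALSE]
  gaps <- lambda[candidates + 1] - lambda[candidates]
  cost <- vapply(candidates, function(c) {
    u <- vecs[, seq_len(c), drop = FALSE]
    rn <- sqrt(rowSums(u^2))
    u <- u / pmax(rn, .Machine$double.eps)
    ratio <- (1 - lambda[c + 1]) / (1 - lambda[c])
    # Laplacian eigenvalues can exceed 1; fall back to the raw residual
    # rather than let the scaling go non-positive
    if (!is.finite(ratio) || ratio <= 0) ratio <- 1
    rotation_residual(u) * ratio
  }, numeric(1))
  ord_g <- order(gaps, decreasing = TRUE)
  ord_c <- order(cost)
  list(eigengap = list(best = candidates[ord_g[1]], second = candidates[ord_g[2]],
                       values = setNames(gaps, candidates)),
       rotation_cost = list(best = candidates[ord_c[1]], second = candidates[ord_c[2]],
                            values = setNames(cost, candidates)))
}

# Alignment cost of the spectral embedding with a discrete cluster
# indicator (Yu & Shi discretisation): alternate between snapping the
# rotated embedding to one-hot rows and re-estimating the rotation by SVD;
# the residual 2*(n_rows - sum of singular values) is 0 when a perfect
# rotation onto indicators exists (ideal block structure).
rotation_residual <- function(u, max_iter = 30) {
  n <- nrow(u)
  c <- ncol(u)
  # deterministic farthest-point initial rotation
  r <- matrix(0, c, c)
  r[, 1] <- u[which.max(rowSums(u^2)), ]
  csum <- rep(0, n)
  for (k in seq_len(c - 1)) {
    csum <- csum + abs(u %*% r[, k, drop = FALSE])
    r[, k + 1] <- u[which.min(csum), ]
  }
  qrr <- qr(r)
  r <- qr.Q(qrr)
  last <- Inf
  for (it in seq_len(max_iter)) {
    y <- u %*% r
    disc <- matrix(0, n, c)
    disc[cbind(seq_len(n), max.col(y, ties.method = "first"))] <- 1
    sv <- svd(crossprod(disc, u))
    obj <- 2 * (n - sum(sv$d))
    r <- tcrossprod(sv$v, sv$u)
    if (abs(last - obj) < 1e-10) break
    last <- obj
  }
  max(obj, 0)
}
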