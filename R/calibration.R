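# Simulation experiments that validate the pipelines end-to-end on
# synthetic cohorts with known ground truth: NBS family-wise error
# calibration under the null, planted-component recovery, and planted
# subgroup recovery by the consensus-clustering pipeline.

#' Family-wise error calibration of NBS under the null
#'
#' Generates `n_datasets` connectome stacks with no group effect
#' (`delta = 0`), runs the one-sided NBS inference on each (group + head
#' motion design, Freedman-Lane permutations), and reports the proportion
#' of datasets in which any component reaches `p_fwer < alpha`. For a
#' calibrated procedure this false-positive rate matches `alpha` up to
#' binomial noise.
#'
#' @param n_datasets Number of null replicates.
#' @param n_subjects Subjects per replicate (split between two groups).
#' @param n_nodes Nodes per connectome.
#' @param n_perm Permutations per NBS run.
#' @param p_threshold Edge-level NBS threshold.
#' @param alpha Component-level significance level tested for calibration.
#' @param seed Master seed.
#' @return List with `fwer` (observed rate), `n_significant`, `n_datasets`,
#'   and the 95% binomial interval around `alpha` implied by `n_datasets`.
#' @export
nbs_null_calibration <- function(n_datasets = 200, n_subjects = 60,
                                 n_nodes = 30, n_perm = 200,
                                 p_threshold = 0.05, alpha = 0.05,
                                 seed = NULL) {
  seeds <- spawn_seeds(seed, 2L * n_datasets)
  hits <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    set.seed(seeds[d])
    md <- data.frame(group = factor(sample(rep(c("A", "B"),
                                               each = n_subjects / 2))),
                     fd = rlnorm(n_subjects, log(0.13), 0.3))
    spec <- planted_component_spec(n_nodes = n_nodes, n_edges_planted = 2,
                                   delta = 0, seed = seeds[d])
    stk <- gen_connectome_stack(md, spec)
    ei <- edge_index(n_nodes)
    y <- t(apply(stk$stack, 3, function(m) m[ei]))
    x <- build_design(md, ~ group + fd)
    cfg <- nbs_config(p_threshold = p_threshold, n_perm = n_perm,
                      seed = seeds[n_datasets + d])
    res <- permutation_fwer(y, x, 2L, cfg, "positive", n_nodes)
    p <- vapply(res$components, `[[`, numeric(1), "p_fwer")
    hits[d] <- length(p) > 0 && min(p) < alpha
  }
  half_width <- 1.96 * sqrt(alpha * (1 - alpha) / n_datasets)
  list(fwer = mean(hits), n_significant = sum(hits), n_datasets = n_datasets,
       ci = c(lower = alpha - half_width, upper = alpha + half_width))
}

#' Recovery of a planted connectome component by NBS
#'
#' Plants a connected component with a group effect of `delta` Fisher-z
#' units, runs the full NBS analysis, and measures which fraction of the
#' planted edges lands in the most significant recovered component.
#'
#' @param n_subjects Cohort size (balanced two groups).
#' @param n_nodes,n_edges_planted,delta,edge_noise_sd Planted-component
#'   parameters, see [planted_component_spec()].
#' @param p_threshold,n_perm NBS settings.
#' @param seed Master seed.
#' @return List with `recovery` (fraction of planted edges recovered),
#'   `p_fwer` of the top component, its `extent`, and a Dice coefficient
#'   between recovered and planted edge sets.
#' @export
nbs_recovery_experiment <- function(n_subjects = 160, n_nodes = 60,
                                    n_edges_planted = 80, delta = 0.3,
                                    edge_noise_sd = 0.3, p_threshold = 0.01,
                                    n_perm = 199, seed = NULL) {
  seeds <- spawn_seeds(seed, 3)
  set.seed(seeds[1])
  md <- data.frame(group = factor(rep(c("A", "B"), each = n_subjects / 2)),
                   fd = rlnorm(n_subjects, log(0.13), 0.3))
  spec <- planted_component_spec(n_nodes = n_nodes,
                                 n_edges_planted = n_edges_planted,
                                 delta = delta, edge_noise_sd = edge_noise_sd,
                                 seed = seeds[2])
  stk <- gen_connectome_stack(md, spec)
  cfg <- nbs_config(p_threshold = p_threshold, n_perm = n_perm,
                    seed = seeds[3])
  rep_nbs <- run_nbs(stk$stack, md, ~ group + fd, config = cfg)
  comps <- rep_nbs$positive$components
  if (length(comps) == 0)
    return(list(recovery = 0, p_fwer = NA_real_, extent = 0, dice = 0))
  top <- comps[[1]]
  shared <- length(intersect(top$edges$edge, stk$true_edge_idx))
  list(recovery = shared / length(stk$true_edge_idx),
       p_fwer = top$p_fwer,
       extent = top$extent,
       dice = dice(top$extent, length(stk$true_edge_idx), shared))
}

#' Recovery of planted behavioural subgroups by consensus clustering
#'
#' Generates a cohort with two planted subgroups separated by `d_effect`
#' standard deviations on `n_affected` of the features, runs the subsampled
#' consensus-clustering pipeline, and scores the final labels against the
#' planted truth with the adjusted Rand index.
#'
#' @param n_subjects Cohort size.
#' @param d_effect Standardized mean difference on the affected features.
#' @param n_affected Number of features carrying the effect (of 13).
#' @param c_clusters Number of clusters.
#' @param config A [stratify_config()]; its seed is overridden by `seed`.
#' @param seed Master seed.
#' @return List with `ari`, the final `labels`, the planted `truth` and the
#'   pipeline `solution`.
#' @export
clustering_recovery_experiment <- function(n_subjects = 156, d_effect = 3,
                                           n_affected = 8, c_clusters = 2,
                                           config = stratify_config(
                                             n_repeats = 50, n_bootstrap = 100),
                                           seed = NULL) {
  seeds <- spawn_seeds(seed, 2)
  spec <- cohort_spec(n_subjects = n_subjects,
                      feature_effects = rep(c(d_effect, 0),
                                            c(n_affected, 13 - n_affected)),
                      seed = seeds[1])
  coh <- gen_cohort(spec)
  config$seed <- seeds[2]
  res <- subsample_consensus(coh$features, c_clusters, config)
  list(ari = adjusted_rand_index(coh$subgroup, res$solution$labels),
       labels = res$solution$labels, truth = coh$subgroup,
       solution = res$solution)
}
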