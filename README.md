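# connstrat

Behavioural consensus clustering and Network Based Statistic inference for
functional connectomes.

Case-control neurodevelopmental cohorts (for example adults born very
preterm versus full-term controls) are behaviourally heterogeneous: the
clinically defined groups blur distinct outcome profiles that cut across
them. `connstrat` implements the two analytical arms such studies need,
plus the machinery to relate them:

1. **Data-driven stratification.** Participants are partitioned into
   behavioural subgroups — irrespective of clinical group — by subsampled
   consensus clustering: a locally scaled affinity kernel
   `W(i,j) = exp(-d(i,j)^2 / (2 (alpha * eps(i,j))^2))` over a K x alpha
   hyper-parameter grid (30 combinations by default), nested resampled
   spectral clustering per network, silhouette-based grid selection, and an
   outer 80%-subsample consensus whose matrix is cut by average-linkage
   hierarchical clustering. Eigengap and rotation-cost criteria on the
   graph Laplacian estimate the number of clusters C.
2. **Network Based Statistic (NBS).** Group differences in resting-state
   functional connectomes are tested at the level of connected edge
   components: an edgewise linear model (covariates: head motion, sex,
   age, socio-economic status) yields a t-statistic per connection;
   one-sided supra-threshold edges (edge-level p of 0.05/0.01/0.001) form
   connected components scored by strength `sum(t)` and extent; and a
   max-statistic permutation null (Freedman–Lane residual permutation by
   default) assigns each component a family-wise-error-corrected p-value
   `p_FWER = (1 + #{perm max >= strength}) / (1 + n_perm)`.

Around these sit the connectome builder (confound regression, 0.01–0.1 Hz
zero-phase band-pass, Pearson correlation, `r >= 0.2` threshold + Fisher
z), within/between summaries over the 7 + 1 intrinsic connectivity
networks, Sorensen–Dice and hypergeometric overlap statistics between NBS
components, rank-sum/Cramer's-V behavioural comparisons with BH-FDR and
covariate-adjusted permutation tests, and synthetic-cohort generators that
plant known subgroup and component structure so every stage is testable
end-to-end.

## Worked example

```r
library(connstrat)

# behavioural stratification on a planted cohort
coh <- gen_cohort(cohort_spec(n_subjects = 60,
                              feature_effects = rep(c(3, 0), c(8, 5)),
                              seed = 1))
cfg <- stratify_config(k_grid = c(10, 20), alpha_grid = c(0.4, 0.7),
                       n_repeats = 20, n_bootstrap = 25, seed = 2)
res <- subsample_consensus(coh$features, c_clusters = 2, config = cfg)
res$solution$mean_silhouette                        # 1
adjusted_rand_index(coh$subgroup, res$solution$labels)  # 1

# NBS on a planted connectome component
md  <- coh$metadata
stk <- gen_connectome_stack(md, planted_component_spec(
         n_nodes = 30, n_edges_planted = 40, delta = 0.5, seed = 3))
rep <- run_nbs(stk$stack, md, ~ group + fd + sex + age + ses,
               config = nbs_config(p_threshold = 0.01, n_perm = 499, seed = 4))
top <- rep$positive$components[[1]]
c(top$extent, length(top$nodes), top$strength, top$p_fwer)
# 42 edges over 27 nodes, strength 228.6, p-FWER = 0.002
length(intersect(top$edges$edge, stk$true_edge_idx))    # 40 of 40 planted
```

The cohort here plants two behavioural subgroups separated by d = 3 on 8
of 13 features: the consensus pipeline recovers them exactly (adjusted
Rand index 1, silhouette 1 on the consensus dissimilarity). The connectome
stack plants a connected 40-edge component whose edges are 0.5 Fisher-z
units stronger in the second group: the positive-tail NBS component
contains all 40 planted edges (plus two noise edges that crossed the
threshold) at the permutation floor-adjacent p of 0.002.

## The bundled analyses

`analysis/` holds the numbered drivers that exercise the whole workflow on
a simulated study (outputs under `results/`):

| script | what it does |
| --- | --- |
| `01_simulate_cohort.R` | cohort, features, partition, time series, planted component |
| `02_build_connectomes.R` | time series -> thresholded Fisher-z connectomes |
| `03_stratify_behaviour.R` | cluster-number estimation + subsampled consensus at C = 2 |
| `04_nbs_group_differences.R` | both one-sided NBS contrasts + 8-network summaries |
| `05_overlap_and_interaction.R` | Dice/hypergeometric overlap, interaction NBS |
| `06_behavioural_profiles.R` | rank-sum/FDR/adjusted-permutation profile tables |

Run them in order with `Rscript analysis/01_simulate_cohort.R` etc.; each
prints a short narrative of what it found and records the settings it
used.

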