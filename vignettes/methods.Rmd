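---
title: "Behavioural stratification and connectome inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural stratification and connectome inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`connstrat` implements two complementary analytical arms for case-control
neurodevelopmental cohorts, exercised end-to-end on synthetic data with known
ground truth:

1. **data-driven behavioural stratification** — partitioning participants
   into subgroups by subsampled consensus clustering over affinity-kernel
   similarity networks, irrespective of clinical group membership; and
2. **Network Based Statistic (NBS) inference** — testing which connected
   sets of functional-connectome edges differ between groups (clinical
   groups, data-driven subgroups, or their interaction), with family-wise
   error controlled by a max-statistic permutation null.

Post hoc machinery quantifies the overlap between the components the two
stratifications yield, and rank-based covariate-adjusted statistics compare
behavioural profiles across groups.

## Connectome construction

Regional time series (T time points x N regions; e.g. 256 volumes at
TR = 2 s over 374 regions) are processed in a fixed order:

1. **Confound regression.** Nuisance signals — conventionally the global
   signal plus six rigid-body motion parameters, k = 7 — are removed by
   ordinary least squares with an intercept; residuals are exactly
   orthogonal to every confound column.
2. **Band-pass.** A zero-phase (forward-backward) 2nd-order Butterworth
   filter retains 0.01–0.1 Hz. The filter family is a standard
   resting-state choice; forward-backward application avoids phase
   distortion. Measured on 256-point signals at TR = 2 s, a 0.05 Hz
   sinusoid retains more than 90% amplitude and a 0.24 Hz sinusoid is
   attenuated below 10%.
3. **Correlation.** Pearson correlation between all region pairs;
   zero-variance regions are an error naming the offending node.
4. **Threshold + Fisher z.** Correlations with `r >= 0.2` are retained and
   mapped by `atanh`; everything below the threshold — including all
   negative correlations — becomes 0. The comparison is an exact `>=`
   (ties at 0.2 retained). Negative correlations are zeroed rather than
   absolute-valued: the retention rule is defined on signed r. The result
   carries a `conn_matrix` class so re-applying the constructor is a
   no-op, making the operation idempotent.

Edges are ordered canonically: pairs `(i, j)` with `i < j`, lexicographic,
1-based; for N = 374 that is 69 751 possible connections. The
vectorize/devectorize pair is lossless for any symmetric zero-diagonal
matrix.

## Behavioural stratification

Input is a subjects x features table (13 behavioural measures in the
emulated design), standardized to mean 0 and sample SD 1. Missing values
are rejected at input rather than imputed.

**Similarity networks.** From the Euclidean distance matrix, a locally
scaled Gaussian kernel builds the affinity network

$$W_{ij} = \exp\!\left(-\frac{d_{ij}^2}{2\,(\alpha\,\varepsilon_{ij})^2}\right),
\qquad
\varepsilon_{ij} = \frac{\bar d_i + \bar d_j + d_{ij}}{3},$$

where $\bar d_i$ is the mean distance from subject *i* to its K nearest
neighbours. K controls the local scale (larger K, denser networks); alpha
weights how far weak edges survive. The kernel's density normalizing
constant is omitted — it cancels in normalized spectral clustering. The
default grid spans K in {10, 15, 20, 25, 30} and alpha in {0.3 ... 0.8},
30 combinations, the ranges conventional for this kernel family.

**Inner consensus.** For one similarity network and a candidate cluster
count C, subjects are resampled `n_bootstrap` times (80% without
replacement by default; with-replacement resampling is available via
`inner_resample = "bootstrap"`), each subnetwork is partitioned by
normalized spectral clustering (symmetric Laplacian embedding,
row-normalised eigenvectors, k-means with restarts), and the consensus
matrix records, for every pair, the fraction of co-inclusions in which the
pair co-clustered. Final labels cut an average-linkage dendrogram of
`1 - co_cluster` at C. Average linkage is the conventional default for
consensus matrices; the linkage is configurable.

**Grid selection.** Every (K, alpha) combination is scored by the mean
silhouette width of its consensus labels, computed on the consensus
dissimilarity `1 - co_cluster` — the quantity those labels actually
partition (`silhouette_basis = "euclidean"` scores on the input distances
instead). Ties break towards smaller K, then smaller alpha: deterministic
and biased towards sparser, simpler networks.

**Outer consensus.** To avoid overfitting the hyper-parameter choice, the
whole grid selection is repeated `n_repeats` times on random 80%
subsamples; the winning labels of each repeat feed a second, outer
consensus matrix, and the final solution cuts its average-linkage tree at
C. Every subject is labelled because each is sampled in many repeats (the
pipeline stops with an error if any subject was never sampled).

**Choosing C.** Two spectral criteria on the similarity network: the
*eigengap* (C maximizing $\lambda_{C+1} - \lambda_C$ of the ascending
symmetric-Laplacian spectrum) and a *rotation cost* (C minimizing the
residual of rotating the C-dimensional spectral embedding onto a discrete
cluster-indicator matrix — an alternating SVD discretisation — scaled by
$(1-\lambda_{C+1})/(1-\lambda_C)$; when that ratio is non-positive, which
can happen since Laplacian eigenvalues may exceed 1, the raw residual is
used). Both report best and runner-up. The published description of the
rotation-cost metric is behavioural rather than algebraic, so this
implementation is validated behaviourally: on block-diagonal and planted
blob similarity networks both criteria return the planted cluster count.
With locally scaled kernels the raw eigengap is only informative over a
modest candidate range (the upper spectrum of these sparse-ish graphs
produces large uninformative gaps), so candidate counts of 2–5 are the
sensible range at these cohort sizes.

**Determinism.** One master seed spawns independent sub-seeds for every
repeat, grid point and resample; fixed seed gives bit-identical output at
any level of the pipeline. The spectral/k-means inner loop runs in
compiled code with its own seeded generator, ~1 ms per resample, which is
what makes 50 repeats x 30 grid points x 100 resamples (~150 000 spectral
runs) practical on one CPU.

## Network Based Statistic

For a stack of connectomes (subjects x edges after vectorization) and a
design matrix (intercept, group indicator, and covariates: mean framewise
displacement in mm, sex, age in years, socio-economic status coded as one
ordinal column), the NBS pipeline is:

1. **Edgewise GLM.** The same linear model is fitted to every edge by
   least squares; the contrast coefficient's t-statistic (df = n − p) is
   the edge statistic. Edges with residual variance at floating-point
   noise level are flagged degenerate and set to t = 0.
2. **Supra-threshold edges.** One-sided retention at the t-quantile for
   the edge-level threshold (0.05, 0.01 or 0.001 conventionally); both
   one-sided contrasts are run, and their supra-threshold sets are
   mutually exclusive by construction.
3. **Components.** Maximal connected components of the supra-threshold
   graph, each summarised by *strength* (sum of edge t-values), *extent*
   (edge count) and per-node degree as a percentage of component edges.
4. **Permutation FWER.** The maximum component strength (extent available
   via `statistic = "extent"`) is recorded over `n_perm` permutations and
   each observed component gets
   $p_{FWER} = (1 + \#\{\max^{perm} \ge s\}) / (1 + n_{perm})$ —
   the add-one estimator, which cannot return 0.

**Permutation scheme.** Group labels are confounded with covariates in
this design (head motion differs between groups), so the default
permutes *reduced-model residuals* (Freedman–Lane): the outcome is
re-formed as reduced-model fit plus permuted reduced-model residuals, and
the full pipeline re-runs on every permutation. Naive label shuffling is
available via `perm_scheme = "labels"`. Calibration on 200 synthetic null
cohorts (60 subjects, 30 nodes, 200 permutations) keeps the family-wise
false-positive rate within the 95% binomial band around the nominal 0.05.

**Network summaries.** With a node-to-network partition (7 cortical
intrinsic connectivity networks plus a subcortical network), each
significant component is summarised by two symmetric 8 x 8 matrices: the
percentage of component edges joining each network pair (upper triangle
plus diagonal sums to 100) and the summed t-strength per pair (summing to
component strength). Between-network cells are undirected and counted
once.

## Post hoc overlap and interaction

Two NBS components are compared by the Sorensen–Dice coefficient
$2k/(|A|+|B|)$ on node sets and on edge sets, and the edge overlap is
tested against a hypergeometric null: the upper-tail probability of
drawing at least the observed number of shared edges when both edge sets
are placed independently among all possible connections. Interaction
contrasts (clinical group x data-driven subgroup) reuse the full NBS
machinery with the interaction column as the tested coefficient, and the
behavioural analogue tests the interaction coefficient of a two-factor
linear model under Freedman–Lane permutation.

## Behavioural group comparisons

Continuous measures: Wilcoxon rank-sum (normal approximation with tie
correction; continuity correction off by default, matching common
rank-sum defaults) with the rank-biserial correlation
$2U/(n_1 n_2) - 1$ as effect size, oriented so positive means the
first-listed group tends larger. Categorical measures: chi-squared
(without continuity correction), or Fisher's exact for 2 x 2 tables with
any expected cell below 5 (larger sparse tables keep chi-squared with a
warning); Cramer's V in either case. Multiplicity: Benjamini–Hochberg
step-up FDR. Covariate-adjusted sensitivity analyses use Freedman–Lane
permutation (5000 permutations by default) of the group coefficient's t.
The covariate-adjusted p-values are computed per feature first and then
FDR-corrected (adjust-then-FDR).

## Synthetic cohorts: what they emulate, and what not

The generator defaults are fixed to the emulated study conditions:

* cohort of **156 subjects** (85 labelled VPT, 71 FT), **13 features**,
  and a planted two-subgroup structure with 85 subjects in the second
  ("at-risk") subgroup;
* feature effects default to a standardized mean difference of **d = 1 on
  10 of 13 features** — reflecting that most, but not all, behavioural
  measures separate such subgroups — with unit-variance Gaussian noise
  per subgroup (rank-based downstream tests are distribution-robust, so
  Gaussianity is a convenience, not a commitment);
* covariates are drawn with the group confounds such cohorts show:
  log-normal framewise displacement with medians **0.15 mm (VPT) vs
  0.12 mm (FT)**, age medians near 31 vs 29 years, male fractions 0.60 vs
  0.46, and a 3-level ordinal socio-economic status with more lower-SES
  subjects among VPT;
* planted connectome components are grown by random expansion from
  randomly placed anchor hubs (guaranteeing topological connectedness and
  hub-anchored shape), defaulting to **80 edges over 60 nodes** with a
  group effect of **delta = 0.3** Fisher-z units against a between-subject
  edge SD of 0.3 — a modest, realistic effect.

The generators emulate the *final* analysis inputs (feature tables,
connectome stacks), not their derivation: no raw 4-D imaging, no
parcellation of volumes, no behavioural feature pre-selection, and no
perinatal injury grades. Planted effects are additive and Gaussian;
passing recovery tests therefore demonstrates that the pipelines detect
the structure they target under clean conditions, not that they are
robust to every artefact of real cohort data (site effects, missingness,
heavy-tailed measures, non-additive brain-behaviour coupling).

## Problem sizes and numerical choices

The bundled analyses and validation suites run at sizes chosen to make
the full stack reproducible in minutes on one CPU, as deliberate design
points of the synthetic study: consensus clustering at 50 outer repeats x
100 inner resamples (reduced from the 1000 x 1000 production defaults;
recovery of planted subgroups at d = 3 is unaffected, ARI > 0.9), NBS
calibration on 200 null cohorts of 60 subjects x 30 nodes with 200
permutations, and recovery on 160 subjects x 60 nodes with 199–1000
permutations. Other fixed choices: consensus proportions treat
never-co-sampled pairs as 0 (with a warning); cluster labels from
`cutree` keep hierarchical order; k-means inside spectral clustering uses
several restarts and refills empty clusters with the worst-fitting point;
silhouette of singleton clusters is 0; SES enters designs as one ordinal
numeric column; all permutation p-values use the add-one rule.

## Known limitations

* The affinity kernel and rotation-cost formulas follow the cited tools'
  documented behaviour, validated behaviourally, not bit-for-bit against
  any particular implementation.
* Freedman–Lane is approximate (residual exchangeability); its
  calibration is demonstrated by simulation, not proved for arbitrary
  covariate structure.
* The hypergeometric overlap null assumes independent uniform edge
  placement, ignoring graph topology (two components sharing hub nodes
  are more likely to share edges than the null admits).
* Consensus clustering at C fixed by spectral criteria does not quantify
  uncertainty in C itself; the best/second-best reporting is a heuristic
  guide, not an inference.
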