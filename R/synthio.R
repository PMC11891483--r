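# Synthetic cohorts, regional time series, connectome stacks and network
# partitions with known ground truth, so the stratification and NBS
# pipelines can be exercised and calibrated end-to-end without real data.

#' Specification of a synthetic behavioural cohort
#'
#' Defaults emulate a middle-adulthood case-control cohort of 156 adults
#' (85 very-preterm, 71 full-term) measured on 13 standardized behavioural
#' features, with two planted latent behavioural subgroups. Default
#' per-feature effects plant a standardized mean difference of 1 on 10 of
#' the 13 features (most, but not all, measures separating the subgroups);
#' covariates follow group-specific distributions: age (years) slightly
#' higher in the VPT group, more males among VPT, a 3-level ordinal
#' socio-economic status, and log-normal in-scanner head motion (mean
#' framewise displacement, mm) with medians 0.15 (VPT) vs 0.12 (FT).
#'
#' @param n_subjects Cohort size.
#' @param n_features Number of behavioural features, default 13.
#' @param subgroup_fraction Fraction of subjects in the planted second
#'   ("at-risk") subgroup, in (0, 1).
#' @param feature_effects Per-feature standardized mean difference between
#'   the planted subgroups (Cohen's d units); recycled to `n_features`.
#' @param group_fraction Fraction labelled VPT, in (0, 1).
#' @param covariate_model List of per-covariate parameters; see defaults.
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 156,
                        n_features = 13,
                        subgroup_fraction = 85 / 156,
                        feature_effects = rep(c(1, 0), c(10, 3)),
                        group_fraction = 85 / 156,
                        covariate_model = list(
                          age_mean = c(vpt = 31, ft = 29), age_sd = 3,
                          male_fraction = c(vpt = 0.60, ft = 0.46),
                          ses_probs = list(vpt = c(0.52, 0.34, 0.14),
                                           ft = c(0.45, 0.33, 0.22)),
                          fd_median = c(vpt = 0.15, ft = 0.12),
                          fd_sdlog = 0.35),
                        seed = NULL) {
  if (n_subjects < 2 || n_features < 1) stop("counts must be positive")
  if (!(subgroup_fraction > 0 && subgroup_fraction < 1))
    stop("`subgroup_fraction` must be in (0, 1)")
  if (!(group_fraction > 0 && group_fraction < 1))
    stop("`group_fraction` must be in (0, 1)")
  feature_effects <- rep_len(feature_effects, n_features)
  if (any(!is.finite(feature_effects))) stop("feature effects must be finite")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_features = as.integer(n_features),
                 subgroup_fraction = subgroup_fraction,
                 feature_effects = feature_effects,
                 group_fraction = group_fraction,
                 covariate_model = covariate_model, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic behavioural cohort
#'
#' Subjects are split into two latent subgroups; feature k is drawn as unit
#' Gaussian noise around a subgroup mean difference of `feature_effects[k]`
#' (subgroup 2 higher). Birth-status group, age, sex, socio-economic status
#' and head motion are drawn from the covariate model, independent of the
#' latent subgroup (the planted signal lives in the features only).
#'
#' @param spec A [cohort_spec()].
#' @return List with `metadata` (subject_id, group, age, sex, ses, fd),
#'   `features` (n x n_features matrix) and `subgroup` (true labels 1/2).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_subjects
  cm <- spec$covariate_model

  n_sub2 <- round(spec$subgroup_fraction * n)
  subgroup <- sample(rep(c(1L, 2L), c(n - n_sub2, n_sub2)))
  n_vpt <- round(spec$group_fraction * n)
  group <- factor(sample(rep(c("VPT", "FT"), c(n_vpt, n - n_vpt))),
                  levels = c("VPT", "FT"))
  is_vpt <- group == "VPT"

  age <- rnorm(n, ifelse(is_vpt, cm$age_mean["vpt"], cm$age_mean["ft"]), cm$age_sd)
  sex <- factor(ifelse(runif(n) < ifelse(is_vpt, cm$male_fraction["vpt"],
                                         cm$male_fraction["ft"]),
                       "male", "female"), levels = c("female", "male"))
  ses <- integer(n)
  ses[is_vpt] <- sample(1:3, sum(is_vpt), TRUE, prob = cm$ses_probs$vpt)
  ses[!is_vpt] <- sample(1:3, sum(!is_vpt), TRUE, prob = cm$ses_probs$ft)
  ses <- factor(ses, levels = 1:3, ordered = TRUE)
  fd <- rlnorm(n, log(ifelse(is_vpt, cm$fd_median["vpt"], cm$fd_median["ft"])),
               cm$fd_sdlog)

  shift <- outer(subgroup == 2L, spec$feature_effects)
  features <- matrix(rnorm(n * spec$n_features), n) + shift
  colnames(features) <- sprintf("feature_%02d", seq_len(spec$n_features))

  list(metadata = data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                             group = group, age = age, sex = sex,
                             ses = ses, fd = fd),
       features = features,
       subgroup = subgroup)
}

#' Specification of a planted connectome component
#'
#' @param n_nodes Number of nodes.
#' @param n_edges_planted Number of planted edges (at most `n (n - 1) / 2`).
#' @param anchor_nodes Number of hub seeds the component grows from.
#' @param delta Additive group effect on planted edges (Fisher-z units);
#'   the second group level gets `+delta`.
#' @param edge_noise_sd Between-subject standard deviation of an edge.
#' @param seed Integer seed.
#' @return A list of class `"planted_component_spec"`.
#' @export
planted_component_spec <- function(n_nodes = 60, n_edges_planted = 80,
                                   anchor_nodes = 3, delta = 0.3,
                                   edge_noise_sd = 0.3, seed = NULL) {
  if (n_nodes < 2 || n_edges_planted < 1) stop("counts must be positive")
  if (n_edges_planted > possible_edge_count(n_nodes))
    stop("more planted edges than possible edges")
  if (anchor_nodes < 1 || anchor_nodes > n_nodes)
    stop("`anchor_nodes` must be in [1, n_nodes]")
  structure(list(n_nodes = as.integer(n_nodes),
                 n_edges_planted = as.integer(n_edges_planted),
                 anchor_nodes = as.integer(anchor_nodes),
                 delta = delta, edge_noise_sd = edge_noise_sd, seed = seed),
            class = "planted_component_spec")
}

# Grow a connected edge set by random expansion from anchor hubs: anchors
# are chained first (connectivity), then edges preferentially touch an
# anchor, mimicking hub-anchored components.
grow_planted_component <- function(n_nodes, n_edges, anchors) {
  pick1 <- function(x) x[sample.int(length(x), 1L)]   # safe for length-1 x
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  anchor_ids <- sample.int(n_nodes, anchors)
  edges <- list()
  seen <- character()
  add_edge <- function(i, j) {
    k <- key(i, j)
    if (i == j || k %in% seen) return(FALSE)
    edges[[length(edges) + 1L]] <<- c(min(i, j), max(i, j))
    seen <<- c(seen, k)
    TRUE
  }
  members <- anchor_ids
  if (anchors > 1)
    for (a in seq_len(anchors - 1)) add_edge(anchor_ids[a], anchor_ids[a + 1])
  while (length(edges) < n_edges) {
    from <- if (runif(1) < 0.5 || length(members) == 0)
      pick1(anchor_ids) else pick1(members)
    grow_new <- runif(1) < 0.5 && length(members) < n_nodes
    to <- if (grow_new) pick1(setdiff(seq_len(n_nodes), members))
          else pick1(members)
    if (add_edge(from, to) && !(to %in% members)) members <- c(members, to)
  }
  do.call(rbind, edges)
}

#' Generate a stack of connectomes with a planted group effect
#'
#' Each subject gets a symmetric zero-diagonal matrix whose edges are
#' Gaussian around per-edge population means (drawn uniform on a plausible
#' thresholded Fisher-z range); subjects in the second group level receive
#' an extra `delta` on the planted edges, which form one connected
#' component grown from anchor hubs. All other edges are exchangeable
#' between groups.
#'
#' @param metadata Data frame with a `group` factor (two levels).
#' @param spec A [planted_component_spec()].
#' @return List with `stack` (n_nodes x n_nodes x n_subjects array),
#'   `true_edges` (matrix of planted node pairs i < j) and
#'   `true_edge_idx` (indices into [edge_index()] order).
#' @export
gen_connectome_stack <- function(metadata, spec = planted_component_spec()) {
  stopifnot(inherits(spec, "planted_component_spec"))
  if (!"group" %in% names(metadata)) stop("metadata must contain `group`")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_sub <- nrow(metadata)
  n_nodes <- spec$n_nodes
  group <- as.factor(metadata$group)
  effect <- as.numeric(group == levels(group)[2])

  planted <- grow_planted_component(n_nodes, spec$n_edges_planted, spec$anchor_nodes)
  ei <- edge_index(n_nodes)
  n_edges <- nrow(ei)
  edge_id <- function(i, j) (i - 1) * n_nodes - i * (i + 1) / 2 + j
  planted_idx <- sort(edge_id(planted[, 1], planted[, 2]))

  mu <- runif(n_edges, 0.25, 0.55)
  y <- matrix(rnorm(n_sub * n_edges, sd = spec$edge_noise_sd), n_sub, n_edges)
  y <- sweep(y, 2, mu, "+")
  y[, planted_idx] <- y[, planted_idx] + spec$delta * effect

  stack <- array(0, dim = c(n_nodes, n_nodes, n_sub))
  for (s in seq_len(n_sub)) stack[, , s] <- devectorize_edges(y[s, ], n_nodes, ei)
  list(stack = stack,
       true_edges = planted[order(planted[, 1], planted[, 2]), , drop = FALSE],
       true_edge_idx = planted_idx)
}

#' Generate band-limited regional time series with block covariance
#'
#' Every node's signal mixes a shared latent signal of its network with
#' node noise (`sqrt(rho)` / `sqrt(1 - rho)` weights), then the canonical
#' 0.01-0.1 Hz band-pass is applied, so within-network correlations exceed
#' between-network ones.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Number of nodes.
#' @param n_timepoints Time points per subject, default 256 (at least 8).
#' @param tr_seconds Sampling interval in seconds, default 2.
#' @param partition Network labels per node (defaults to one block).
#' @param rho Within-network shared-variance fraction, default 0.35.
#' @param seed Integer seed.
#' @return List of `n_subjects` matrices, each `n_timepoints` x `n_nodes`.
#' @export
gen_timeseries <- function(n_subjects, n_nodes, n_timepoints = 256,
                           tr_seconds = 2, partition = NULL, rho = 0.35,
                           seed = NULL) {
  if (n_timepoints < 8) stop("need at least 8 time points")
  if (tr_seconds <= 0) stop("`tr_seconds` must be positive")
  if (!is.null(seed)) set.seed(seed)
  part <- as.integer(as.factor(partition %||% rep(1, n_nodes)))
  if (length(part) != n_nodes) stop("partition length must equal n_nodes")
  lapply(seq_len(n_subjects), function(s) {
    latent <- matrix(rnorm(n_timepoints * max(part)), n_timepoints)
    noise <- matrix(rnorm(n_timepoints * n_nodes), n_timepoints)
    raw <- sqrt(rho) * latent[, part, drop = FALSE] + sqrt(1 - rho) * noise
    bandpass(raw, tr_seconds)
  })
}

#' Generate a node-to-network partition
#'
#' Assigns every node to one of `n_networks` intrinsic networks (the
#' canonical 7 cortical networks plus subcortical when `n_networks = 8`),
#' each network non-empty. `n_subcortical` forces the exact size of the
#' subcortical network (e.g. 16 of 374 regions).
#'
#' @param n_nodes Number of nodes (at least `n_networks`).
#' @param n_networks Number of networks, default 8.
#' @param n_subcortical Optional exact size of the subcortical network.
#' @param seed Integer seed.
#' @return Factor of length `n_nodes` with network labels as levels.
#' @export
gen_partition <- function(n_nodes, n_networks = 8, n_subcortical = NULL,
                          seed = NULL) {
  if (n_networks > n_nodes) stop("more networks than nodes")
  if (!is.null(seed)) set.seed(seed)
  labs <- if (n_networks == 8) intrinsic_networks
          else paste0("network_", seq_len(n_networks))
  if (!is.null(n_subcortical)) {
    if (n_networks != 8) stop("`n_subcortical` needs the canonical 8 networks")
    if (n_subcortical + (n_networks - 1) > n_nodes)
      stop("`n_subcortical` leaves too few nodes for the cortical networks")
    n_cort <- n_nodes - n_subcortical
    cort <- sample(c(labs[1:7], sample(labs[1:7], n_cort - 7, TRUE)))
    assignment <- sample(c(cort, rep(labs[8], n_subcortical)))
  } else {
    assignment <- sample(c(labs, sample(labs, n_nodes - n_networks, TRUE)))
  }
  factor(assignment, levels = labs)
}
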