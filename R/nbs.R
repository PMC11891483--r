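# Network Based Statistic: edgewise general linear models across a stack of
# connectivity matrices, supra-threshold component extraction, and
# max-statistic permutation control of the family-wise error rate.

#' NBS settings
#'
#' @param p_threshold Edge-level (one-sided) p-value threshold used to
#'   declare an edge supra-threshold; conventional choices are 0.05, 0.01
#'   and 0.001.
#' @param n_perm Number of permutations for the FWER null, default 1000.
#' @param statistic Component statistic the permutation null is built on:
#'   `"strength"` (sum of edge t-statistics, default) or `"extent"`
#'   (edge count).
#' @param perm_scheme `"freedman_lane"` (permute reduced-model residuals,
#'   default; the recommended scheme when nuisance covariates are
#'   confounded with the predictor of interest) or `"labels"` (naive
#'   shuffling of the predictor column).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `"nbs_config"`.
#' @export
nbs_config <- function(p_threshold = 0.01, n_perm = 1000,
                       statistic = c("strength", "extent"),
                       perm_scheme = c("freedman_lane", "labels"),
                       seed = NULL) {
  if (!(p_threshold > 0 && p_threshold < 1)) stop("`p_threshold` must be in (0, 1)")
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  structure(list(p_threshold = p_threshold, n_perm = as.integer(n_perm),
                 statistic = match.arg(statistic),
                 perm_scheme = match.arg(perm_scheme), seed = seed),
            class = "nbs_config")
}

#' Edgewise ordinary-least-squares t-statistics
#'
#' Fits the same linear model to every edge of a connectome stack and
#' returns the t-statistic of one coefficient. Edges with zero residual
#' variance (e.g. a constant outcome) get t = 0.
#'
#' @param y Numeric matrix, subjects x edges (edge-vectorized stack).
#' @param x Design matrix, subjects x predictors, full column rank.
#' @param contrast Column name or index of the tested coefficient.
#' @return List with `t` (per-edge t-statistics), `df` (residual degrees of
#'   freedom, `n - p`) and `beta` (per-edge estimates of the contrast
#'   coefficient).
#' @export
fit_edgewise_glm <- function(y, x, contrast) {
  y <- as.matrix(y)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (nrow(y) != n) stop("stack and design matrix are misaligned")
  if (n <= p) stop("need more subjects than predictors (n = ", n, ", p = ", p, ")")
  j <- if (is.character(contrast)) match(contrast, colnames(x)) else as.integer(contrast)
  if (is.na(j) || j < 1 || j > p) stop("contrast does not select a design column")
  xtx <- crossprod(x)
  r <- qr(x)$rank
  if (r < p) stop("design matrix is rank deficient")
  xtx_inv <- chol2inv(chol(xtx))
  beta <- xtx_inv %*% crossprod(x, y)
  res <- y - x %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  # degenerate edges: residual variance at floating-point-noise level
  scale2 <- colMeans(y^2)
  degen <- sigma2 <= pmax(scale2, 1) * 1e-12
  se <- sqrt(sigma2 * xtx_inv[j, j])
  t_stat <- ifelse(degen | se == 0, 0, beta[j, ] / se)
  list(t = unname(t_stat), df = n - p, beta = unname(beta[j, ]))
}

#' Supra-threshold edges for a one-sided test
#'
#' Keeps the edges whose t-statistic exceeds the one-sided critical value
#' `qt(1 - p_threshold, df)` in the tested direction.
#'
#' @param statmap Result of [fit_edgewise_glm()].
#' @param p_threshold Edge-level p-value threshold.
#' @param tail `"positive"` (t >= critical) or `"negative"` (-t >= critical).
#' @return Integer vector of edge indices (canonical edge order).
#' @export
suprathreshold_edges <- function(statmap, p_threshold, tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  crit <- qt(1 - p_threshold, statmap$df)
  t_dir <- if (tail == "positive") statmap$t else -statmap$t
  which(t_dir >= crit)
}

#' Connected components of a supra-threshold edge set
#'
#' Partitions the graph formed by the supra-threshold edges into maximal
#' connected components and summarises each: its edges, nodes, strength
#' (sum of the tested-direction t-statistics over its edges), extent (edge
#' count) and per-node degree as a percentage of the component's edges.
#' Isolated nodes are ignored.
#'
#' @param edges Integer vector of edge indices into `ei`.
#' @param ei Edge index matrix from [edge_index()].
#' @param n_nodes Number of nodes in the connectome.
#' @param t_values Per-edge statistics (tested direction) aligned with `ei`.
#' @return List of components, ordered by decreasing strength. Each has
#'   `edges` (data frame i, j, t), `nodes`, `strength`, `extent` and
#'   `nodal_degree_percent` (named by node; sums to 200).
#' @export
extract_components <- function(edges, ei, n_nodes, t_values) {
  if (length(edges) == 0) return(list())
  pairs <- ei[edges, , drop = FALSE]
  if (any(pairs > n_nodes)) stop("edge references node beyond n_nodes")
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  # drop isolated vertices (zero-edge singleton components)
  with_edges <- sort(unique(membership[pairs[, 1]]))
  out <- lapply(with_edges, function(k) {
    nodes <- which(membership == k)
    in_comp <- membership[pairs[, 1]] == k       # both endpoints share a component
    e_idx <- edges[in_comp]
    tv <- t_values[e_idx]
    deg <- table(factor(c(pairs[in_comp, 1], pairs[in_comp, 2]), levels = nodes))
    list(edges = data.frame(i = pairs[in_comp, 1], j = pairs[in_comp, 2],
                            edge = e_idx, t = tv),
         nodes = nodes,
         strength = sum(tv),
         extent = sum(in_comp),
         nodal_degree_percent = setNames(100 * as.numeric(deg) / sum(in_comp), nodes))
  })
  out[order(vapply(out, `[[`, numeric(1), "strength"), decreasing = TRUE)]
}

# maximum component statistic (strength or extent) of one t-map, one tail
max_component_stat <- function(t_stat, df, p_threshold, tail, ei, n_nodes,
                               statistic = "strength") {
  crit <- qt(1 - p_threshold, df)
  t_dir <- if (tail == "positive") t_stat else -t_stat
  keep <- which(t_dir >= crit)
  if (length(keep) == 0) return(0)
  comps <- extract_components(keep, ei, n_nodes, t_dir)
  max(vapply(comps, `[[`, numeric(1), statistic))
}

#' Permutation FWER for supra-threshold components
#'
#' Runs the full NBS inference for one contrast and one tail: the edgewise
#' GLM, supra-threshold component extraction, and a max-statistic
#' permutation null. Under the default Freedman-Lane scheme, the outcome is
#' re-formed as reduced-model fit plus permuted reduced-model residuals on
#' every permutation (the reduced model excludes the contrast column), the
#' full pipeline is re-run, and the maximum component statistic recorded.
#' Each observed component gets
#' `p_fwer = (1 + #\{perm max >= observed\}) / (1 + n_perm)`.
#'
#' @param y Subjects x edges outcome matrix.
#' @param x Full design matrix.
#' @param contrast Column name or index of the coefficient of interest.
#' @param config An [nbs_config()].
#' @param tail `"positive"` or `"negative"`.
#' @param n_nodes Number of nodes in the connectome.
#' @return List with `components` (each with `p_fwer` added), `statmap`,
#'   `null_max` (permutation distribution of the max component statistic)
#'   and the settings used.
#' @export
permutation_fwer <- function(y, x, contrast, config = nbs_config(),
                             tail = c("positive", "negative"), n_nodes) {
  tail <- match.arg(tail)
  y <- as.matrix(y)
  x <- as.matrix(x)
  ei <- edge_index(n_nodes)
  if (ncol(y) != nrow(ei)) stop("`y` has ", ncol(y), " edges but n_nodes implies ", nrow(ei))
  j <- if (is.character(contrast)) match(contrast, colnames(x)) else as.integer(contrast)
  if (is.na(j)) stop("contrast does not select a design column")

  obs <- fit_edgewise_glm(y, x, j)
  t_dir <- if (tail == "positive") obs$t else -obs$t
  keep <- suprathreshold_edges(obs, config$p_threshold, tail)
  comps <- extract_components(keep, ei, n_nodes, t_dir)

  seeds <- spawn_seeds(config$seed, config$n_perm)
  n <- nrow(y)
  if (config$perm_scheme == "freedman_lane") {
    z <- x[, -j, drop = FALSE]
    qz <- qr(z)
    fit_red <- qr.fitted(qz, y)
    res_red <- qr.resid(qz, y)
  }
  null_max <- vapply(seq_len(config$n_perm), function(b) {
    set.seed(seeds[b])
    perm <- sample.int(n)
    if (config$perm_scheme == "freedman_lane") {
      y_star <- fit_red + res_red[perm, , drop = FALSE]
      fit_b <- fit_edgewise_glm(y_star, x, j)
    } else {
      x_star <- x
      x_star[, j] <- x[perm, j]
      fit_b <- fit_edgewise_glm(y, x_star, j)
    }
    max_component_stat(fit_b$t, fit_b$df, config$p_threshold, tail, ei,
                       n_nodes, config$statistic)
  }, numeric(1))

  for (k in seq_along(comps)) {
    stat_k <- comps[[k]][[config$statistic]]
    comps[[k]]$p_fwer <- (1 + sum(null_max >= stat_k)) / (1 + config$n_perm)
  }
  list(components = comps, statmap = obs, null_max = null_max,
       tail = tail, contrast = colnames(x)[j] %||% j, config = config)
}

#' Build an NBS design matrix from subject metadata
#'
#' Expands a model formula over the metadata table into a full-rank design
#' matrix. Ordered factors (e.g. a 3-level socio-economic status) are coded
#' as a single ordinal numeric column; unordered binary factors become 0/1
#' indicators via `model.matrix`.
#'
#' @param metadata Data frame of subject covariates, rows aligned with the
#'   connectome stack.
#' @param formula Model formula over metadata columns, e.g.
#'   `~ group + fd + sex + age + ses`.
#' @return Design matrix with intercept.
#' @export
build_design <- function(metadata, formula) {
  md <- as.data.frame(metadata)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(md))
  if (length(missing_vars))
    stop("metadata is missing covariate(s): ", paste(missing_vars, collapse = ", "))
  for (v in vars) if (is.ordered(md[[v]])) md[[v]] <- as.numeric(md[[v]])
  x <- model.matrix(formula, md)
  if (nrow(x) != nrow(md)) stop("missing values in covariates")
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  x
}

#' Run the full NBS analysis on a connectome stack
#'
#' Vectorizes the stack, builds the design matrix, and runs permutation
#' FWER inference for both one-sided contrasts (group A < B and A > B) of
#' the coefficient of interest. When a node-to-network partition is
#' supplied, each significant component also gets within/between-network
#' percentage and strength summaries.
#'
#' @param stack Either a 3-D array (nodes x nodes x subjects) of symmetric
#'   connectivity matrices or a subjects x edges matrix.
#' @param metadata Data frame of covariates, one row per subject.
#' @param formula Model formula over metadata columns; the first
#'   non-intercept term is the default contrast.
#' @param config An [nbs_config()].
#' @param contrast Optional explicit contrast (design column name or index).
#' @param partition Optional node-to-network factor for [within_between_summary()].
#' @param alpha FWER significance level used to flag components, default 0.05.
#' @return List of class `"nbs_report"` with one result per tail, the design
#'   matrix, and settings.
#' @export
run_nbs <- function(stack, metadata, formula, config = nbs_config(),
                    contrast = NULL, partition = NULL, alpha = 0.05) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    n_nodes <- dim(stack)[1]
    ei <- edge_index(n_nodes)
    y <- t(apply(stack, 3, function(m) m[ei]))
  } else {
    y <- as.matrix(stack)
    n_nodes <- round((1 + sqrt(1 + 8 * ncol(y))) / 2)
    if (possible_edge_count(n_nodes) != ncol(y))
      stop("cannot infer n_nodes from ", ncol(y), " edges")
  }
  if (nrow(y) != nrow(metadata)) stop("stack and metadata are misaligned")
  x <- build_design(metadata, formula)
  j <- contrast %||% colnames(x)[2]
  seeds <- spawn_seeds(config$seed, 2)
  tails <- c("positive", "negative")
  results <- lapply(seq_along(tails), function(ti) {
    cfg <- config
    cfg$seed <- seeds[ti]
    res <- permutation_fwer(y, x, j, cfg, tails[ti], n_nodes)
    if (!is.null(partition)) {
      res$network_summary <- lapply(res$components, function(cmp) {
        if (cmp$p_fwer <= alpha)
          within_between_summary(cmp, partition)
        else NULL
      })
    }
    res
  })
  names(results) <- tails
  structure(list(positive = results$positive, negative = results$negative,
                 design = x, contrast = j, n_nodes = n_nodes, alpha = alpha),
            class = "nbs_report")
}
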