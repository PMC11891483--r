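# Group comparisons of behavioural and demographic variables: rank-sum
# tests with rank-biserial effect sizes, categorical tests with Cramer's V,
# Benjamini-Hochberg FDR, and covariate-adjusted permutation tests.

#' Wilcoxon rank-sum test with rank-biserial effect size
#'
#' Mann-Whitney U with normal approximation and tie correction (continuity
#' correction off by default, switchable). The rank-biserial correlation is
#' `2U / (n1 * n2) - 1`, oriented so positive values mean the first sample
#' tends larger.
#'
#' @param x,y Numeric samples (non-empty).
#' @param correct Apply the continuity correction to the normal
#'   approximation; default `FALSE`.
#' @return List with `statistic` (U for the first sample), `p_value`
#'   (two-sided) and `rank_biserial`.
#' @export
ranksum_test <- function(x, y, correct = FALSE) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  wt <- wilcox.test(x, y, exact = FALSE, correct = correct)
  u <- unname(wt$statistic)
  r_rb <- 2 * u / (length(x) * length(y)) - 1
  list(statistic = u, p_value = wt$p.value, rank_biserial = r_rb)
}

#' Association test for a contingency table with Cramer's V
#'
#' Fisher's exact test when the table is 2x2 with any expected cell below
#' 5, otherwise a chi-squared test (without continuity correction; larger
#' sparse tables fall back to chi-squared with a warning). Cramer's V is
#' `sqrt(chi2 / (n * (min(r, c) - 1)))` in either case.
#'
#' @param tab Nonnegative integer matrix, at least 2x2.
#' @return List with `method`, `p_value` and `cramers_v`.
#' @export
categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: all-zero row or column")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  v <- sqrt(unname(chi$statistic) / (n * (min(dim(tab)) - 1)))
  sparse <- any(expected < 5)
  if (sparse && all(dim(tab) == 2)) {
    list(method = "fisher", p_value = fisher.test(tab)$p.value, cramers_v = v)
  } else {
    if (sparse)
      warning("expected counts below 5 in a table larger than 2x2; chi-squared used")
    list(method = "chisq", p_value = chi$p.value, cramers_v = v)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1,
#' invariant to the input ordering.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

# Freedman-Lane permutation p-value for one coefficient of a linear model:
# fit the reduced model (without the tested column), permute its residuals,
# refit the full model, compare |t| (or one-sided t) with the observed.
fl_perm_p <- function(y, x, j, n_perm, seed, two_sided = TRUE) {
  qx_full <- qr(x)
  if (qx_full$rank < ncol(x)) stop("design matrix is rank deficient")
  t_of <- function(yy) {
    fit <- fit_edgewise_glm(matrix(yy, ncol = 1), x, j)
    fit$t
  }
  t_obs <- t_of(y)
  z <- x[, -j, drop = FALSE]
  qz <- qr(z)
  fit_red <- qr.fitted(qz, y)
  res_red <- qr.resid(qz, y)
  seeds <- spawn_seeds(seed, n_perm)
  n <- length(y)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    set.seed(seeds[b])
    y_star <- fit_red + res_red[sample.int(n)]
    t_b <- t_of(y_star)
    hit <- if (two_sided) abs(t_b) >= abs(t_obs) else t_b >= t_obs
    exceed <- exceed + hit
  }
  list(p = (1 + exceed) / (1 + n_perm), t = t_obs)
}

#' Covariate-adjusted permutation test of a group effect
#'
#' Tests whether `outcome` differs between groups after adjusting for
#' covariates, by Freedman-Lane permutation of the reduced-model residuals
#' (the reduced model holds the covariates only). The test statistic is the
#' group coefficient's t; p-values use the add-one rule.
#'
#' @param outcome Numeric outcome vector.
#' @param group Two-level factor or 0/1 vector.
#' @param covariates Optional data frame or matrix of covariates (ordered
#'   factors are coded ordinally).
#' @param n_perm Number of permutations, default 5000.
#' @param seed Integer seed.
#' @return List with `p_value` (two-sided), `t` and `n_perm`.
#' @export
adjusted_perm_test <- function(outcome, group, covariates = NULL,
                               n_perm = 5000, seed = NULL) {
  g <- if (is.factor(group)) as.numeric(group) - 1 else as.numeric(group)
  if (length(unique(g)) != 2) stop("`group` must have exactly two levels")
  md <- data.frame(.g = g)
  if (!is.null(covariates)) md <- cbind(md, as.data.frame(covariates))
  for (v in names(md)) if (is.ordered(md[[v]])) md[[v]] <- as.numeric(md[[v]])
  x <- model.matrix(~ ., md)
  keep <- stats::complete.cases(cbind(outcome, md))
  if (!all(keep)) stop("missing values in outcome or covariates")
  res <- fl_perm_p(outcome, x, j = 2L, n_perm = n_perm, seed = seed)
  list(p_value = res$p, t = res$t, n_perm = n_perm)
}

#' Permutation test of a two-way group interaction on an outcome
#'
#' Tests the `factor_a x factor_b` interaction coefficient in a linear
#' model with both main effects and optional covariates, by Freedman-Lane
#' permutation (the reduced model holds main effects and covariates). The
#' interaction t is tested in both tails.
#'
#' @param outcome Numeric outcome vector.
#' @param factor_a,factor_b Two binary factors.
#' @param covariates Optional covariates.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `p_value`, `t` and `n_perm`.
#' @export
interaction_behaviour_test <- function(outcome, factor_a, factor_b,
                                       covariates = NULL, n_perm = 5000,
                                       seed = NULL) {
  a <- if (is.factor(factor_a)) as.numeric(factor_a) - 1 else as.numeric(factor_a)
  b <- if (is.factor(factor_b)) as.numeric(factor_b) - 1 else as.numeric(factor_b)
  if (length(unique(a)) != 2 || length(unique(b)) != 2)
    stop("both factors must have exactly two levels")
  md <- data.frame(.a = a, .b = b)
  if (!is.null(covariates)) md <- cbind(md, as.data.frame(covariates))
  for (v in names(md)) if (is.ordered(md[[v]])) md[[v]] <- as.numeric(md[[v]])
  x <- model.matrix(~ . + .a:.b, md)
  j <- which(colnames(x) == ".a:.b")
  res <- fl_perm_p(outcome, x, j = j, n_perm = n_perm, seed = seed)
  list(p_value = res$p, t = res$t, n_perm = n_perm)
}

#' Table of behavioural group comparisons
#'
#' Convenience wrapper mirroring a standard cohort-comparison table: for
#' every feature, the per-group median (IQR), rank-sum p, BH-FDR p,
#' covariate-adjusted permutation p after BH-FDR, and the rank-biserial
#' effect size (positive = first group larger).
#'
#' @param features Numeric matrix or data frame, subjects x features.
#' @param group Two-level factor; the first level is the reference.
#' @param covariates Optional covariates for the adjusted permutation test.
#' @param n_perm Permutations for the adjusted test, default 5000.
#' @param seed Integer seed.
#' @return Data frame, one row per feature.
#' @export
behavioural_profile_table <- function(features, group, covariates = NULL,
                                      n_perm = 5000, seed = NULL) {
  x <- as.matrix(features)
  group <- as.factor(group)
  lv <- levels(group)
  if (length(lv) != 2) stop("`group` must have exactly two levels")
  seeds <- spawn_seeds(seed, ncol(x))
  rows <- lapply(seq_len(ncol(x)), function(k) {
    v <- x[, k]
    rs <- ranksum_test(v[group == lv[1]], v[group == lv[2]])
    adj <- adjusted_perm_test(v, group, covariates, n_perm = n_perm,
                              seed = seeds[k])
    data.frame(feature = colnames(x)[k] %||% paste0("feature_", k),
               median_1 = median(v[group == lv[1]]),
               iqr_1 = stats::IQR(v[group == lv[1]]),
               median_2 = median(v[group == lv[2]]),
               iqr_2 = stats::IQR(v[group == lv[2]]),
               p_value = rs$p_value,
               p_adjusted = adj$p_value,
               rank_biserial = rs$rank_biserial)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_value)
  out$p_adjusted_fdr <- bh_fdr(out$p_adjusted)
  out[, c("feature", "median_1", "iqr_1", "median_2", "iqr_2",
          "p_value", "p_fdr", "p_adjusted_fdr", "rank_biserial")]
}
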