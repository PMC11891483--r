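# Within/between intrinsic-network summaries of an NBS component.

#' Canonical intrinsic connectivity network labels
#'
#' Seven cortical resting-state networks plus a subcortical network.
#' @export
intrinsic_networks <- c("visual", "somatomotor", "dorsal_attention",
                        "ventral_attention", "limbic", "frontoparietal",
                        "default_mode", "subcortical")

#' Within- and between-network summary of a component
#'
#' Tallies a component's edges over the (unordered) pairs of intrinsic
#' networks its endpoints belong to. Returns two symmetric matrices on the
#' partition's label set: percentage of component edges per network pair
#' (the upper triangle including the diagonal sums to 100) and the sum of
#' edge t-statistics per pair (summing to the component strength). The
#' diagonal holds within-network edges; between-network cells are
#' undirected and counted once in totals.
#'
#' @param component One component from [extract_components()].
#' @param partition Factor (or vector) of network labels, one per node; its
#'   levels fix the output row/column order.
#' @return List with `percent` and `strength` matrices plus `n_edges`.
#' @export
within_between_summary <- function(component, partition) {
  labs <- if (is.factor(partition)) levels(partition) else sort(unique(partition))
  part <- as.character(partition)
  ed <- component$edges
  if (anyNA(part[c(ed$i, ed$j)]))
    stop("partition does not label every component node")
  k <- length(labs)
  pct <- matrix(0, k, k, dimnames = list(labs, labs))
  stren <- pct
  a <- match(part[ed$i], labs)
  b <- match(part[ed$j], labs)
  if (anyNA(a) || anyNA(b)) stop("component node with unknown network label")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  for (e in seq_along(lo)) {
    pct[lo[e], hi[e]] <- pct[lo[e], hi[e]] + 1
    stren[lo[e], hi[e]] <- stren[lo[e], hi[e]] + ed$t[e]
  }
  n_edges <- nrow(ed)
  pct <- pct / n_edges * 100
  # mirror for symmetric presentation; totals count each pair once
  pct[lower.tri(pct)] <- t(pct)[lower.tri(pct)]
  stren[lower.tri(stren)] <- t(stren)[lower.tri(stren)]
  list(percent = pct, strength = stren, n_edges = n_edges)
}
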