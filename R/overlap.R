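# Overlap statistics between two NBS components: Sorensen-Dice
# coefficients on node/edge sets and a hypergeometric edge-overlap test.

#' Sorensen-Dice coefficient from set sizes
#'
#' `2k / (|A| + |B|)` for two sets of sizes `|A|`, `|B|` sharing `k`
#' elements; 0 by convention when both sets are empty.
#'
#' @param size_a,size_b Set sizes (nonnegative).
#' @param overlap Number of shared elements, at most `min(size_a, size_b)`.
#' @return Coefficient in \[0, 1\].
#' @examples
#' dice(360, 337, 325) # 0.93
#' @export
dice <- function(size_a, size_b, overlap) {
  if (size_a < 0 || size_b < 0 || overlap < 0) stop("sizes must be nonnegative")
  if (overlap > min(size_a, size_b)) stop("overlap exceeds a set size")
  if (size_a + size_b == 0) return(0)
  2 * overlap / (size_a + size_b)
}

#' Sorensen-Dice coefficient of two explicit sets
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return Coefficient in \[0, 1\].
#' @export
dice_sets <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  dice(length(a), length(b), length(intersect(a, b)))
}

#' Hypergeometric upper-tail test of edge overlap
#'
#' Probability of observing at least `n_overlap` shared edges between two
#' edge sets of sizes `n_edges_a` and `n_edges_b` drawn from `n_possible`
#' possible edges, under the hypergeometric null of random, independent
#' placement. Symmetric in the two sets.
#'
#' @param n_possible Number of possible edges in the graph.
#' @param n_edges_a,n_edges_b Sizes of the two edge sets.
#' @param n_overlap Observed shared edges.
#' @return Upper-tail p-value `P(X >= n_overlap)`.
#' @export
edge_overlap_test <- function(n_possible, n_edges_a, n_edges_b, n_overlap) {
  if (n_edges_a > n_possible || n_edges_b > n_possible)
    stop("edge set larger than the number of possible edges")
  if (n_overlap > min(n_edges_a, n_edges_b))
    stop("overlap exceeds an edge-set size")
  if (n_overlap < max(0, n_edges_a + n_edges_b - n_possible))
    stop("overlap smaller than the forced minimum")
  phyper(n_overlap - 1, n_edges_b, n_possible - n_edges_b, n_edges_a,
         lower.tail = FALSE)
}

#' Node and edge overlap between two NBS components
#'
#' @param comp_a,comp_b Components from [extract_components()].
#' @param n_possible Number of possible edges (for the hypergeometric test).
#' @return List with node Dice, edge Dice, overlap counts, and the
#'   hypergeometric upper-tail p of the edge overlap.
#' @export
component_overlap <- function(comp_a, comp_b, n_possible) {
  ea <- comp_a$edges$edge
  eb <- comp_b$edges$edge
  k_edges <- length(intersect(ea, eb))
  list(node_dice = dice_sets(comp_a$nodes, comp_b$nodes),
       edge_dice = dice(length(ea), length(eb), k_edges),
       n_shared_nodes = length(intersect(comp_a$nodes, comp_b$nodes)),
       n_shared_edges = k_edges,
       edge_overlap_p = edge_overlap_test(n_possible, length(ea), length(eb),
                                          k_edges))
}
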