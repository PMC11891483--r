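#' Number of possible edges in an undirected graph
#'
#' For `n` nodes there are `n * (n - 1) / 2` distinct undirected node pairs,
#' i.e. possible connections in a connectome with no self-loops.
#'
#' @param n_nodes Number of nodes (at least 2).
#' @return Integer count of node pairs.
#' @examples
#' possible_edge_count(374) # 69751
#' @export
possible_edge_count <- function(n_nodes) {
  if (length(n_nodes) != 1L || !is.finite(n_nodes) || n_nodes < 2)
    stop("`n_nodes` must be a single number >= 2")
  n_nodes <- as.numeric(n_nodes)
  n_nodes * (n_nodes - 1) / 2
}

#' Edge index for the strict upper triangle
#'
#' Fixes the canonical ordering of edges used everywhere in the package:
#' node pairs `(i, j)` with `i < j`, in lexicographic order (all pairs with
#' `i = 1` first, then `i = 2`, ...). Node ids are 1-based.
#'
#' @param n_nodes Number of nodes.
#' @return A two-column integer matrix with columns `i` and `j`, one row per
#'   edge, `n_nodes * (n_nodes - 1) / 2` rows in total.
#' @export
edge_index <- function(n_nodes) {
  if (n_nodes < 2) stop("`n_nodes` must be >= 2")
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L, from = 2:n_nodes)
  cbind(i = i, j = j)
}

#' Vectorize a symmetric matrix along the canonical edge order
#'
#' @param mat Symmetric matrix with zero diagonal.
#' @param ei Optional precomputed [edge_index()] for `nrow(mat)`.
#' @return Numeric vector of upper-triangle entries in edge-index order.
#' @seealso [devectorize_edges()] for the inverse.
#' @export
vectorize_edges <- function(mat, ei = NULL) {
  if (is.null(ei)) ei <- edge_index(nrow(mat))
  mat[ei]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' @param x Numeric vector in canonical edge order.
#' @param n_nodes Number of nodes.
#' @param ei Optional precomputed [edge_index()].
#' @return `n_nodes` x `n_nodes` symmetric matrix with zero diagonal.
#' @export
devectorize_edges <- function(x, n_nodes, ei = NULL) {
  if (is.null(ei)) ei <- edge_index(n_nodes)
  if (length(x) != nrow(ei)) stop("edge vector length does not match n_nodes")
  m <- matrix(0, n_nodes, n_nodes)
  m[ei] <- x
  m[ei[, c(2, 1)]] <- x
  m
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions (up to label names), 0 is chance level.
#'
#' @param a,b Label vectors of equal length.
#' @return Adjusted Rand index in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}

# derive a stream of sub-seeds (< 2^31) from one master seed
spawn_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
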