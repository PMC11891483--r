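# Independent oracles and tiny fixture builders used across the suite.

# two (or more) Gaussian blobs with known labels
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(c)
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[c, ], n_per, ncol(centers), byrow = TRUE)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# union-find connected components over an edge list (oracle for igraph path)
union_find_components <- function(pairs, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

# per-point silhouette by explicit loops
brute_silhouette <- function(labels, d) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(c)
      mean(d[i, labels == c]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# hypergeometric upper tail by direct binomial-coefficient arithmetic
enum_hypergeom_upper <- function(n_possible, n_a, n_b, k) {
  i <- k:min(n_a, n_b)
  sum(choose(n_b, i) * choose(n_possible - n_b, n_a - i)) / choose(n_possible, n_a)
}

# Mann-Whitney U by exhaustive pairwise comparison
brute_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
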