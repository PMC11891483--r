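// Spectral clustering kernel and inner bootstrap-consensus loop.
// Kept in C++ because the consensus pipeline evaluates the kernel ~1e5
// times per run; everything is deterministic given the integer seed
// (own mt19937-based sampling, no R RNG involvement).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

static inline uword draw_below(std::mt19937_64 &rng, uword n) {
  // unbiased bounded draw via rejection
  uint64_t limit = UINT64_MAX - (UINT64_MAX % n);
  uint64_t x;
  do { x = rng(); } while (x >= limit);
  return (uword)(x % n);
}

// Fisher-Yates partial shuffle: first k entries of a random permutation of 0..n-1
static uvec sample_without_replacement(std::mt19937_64 &rng, uword n, uword k) {
  uvec idx = regspace<uvec>(0, n - 1);
  for (uword i = 0; i < k; i++) {
    uword j = i + draw_below(rng, n - i);
    std::swap(idx[i], idx[j]);
  }
  return idx.head(k);
}

// Lloyd k-means with `nstart` random initialisations; returns labels 0..C-1.
// Empty clusters are refilled with the point farthest from its centroid.
static uvec kmeans_lloyd(const mat &X, uword C, std::mt19937_64 &rng,
                         int nstart, int max_iter = 100) {
  uword n = X.n_rows;
  uvec best_lab(n, fill::zeros);
  double best_wcss = datum::inf;
  for (int s = 0; s < nstart; s++) {
    uvec init = sample_without_replacement(rng, n, C);
    mat cent = X.rows(init);
    uvec lab(n, fill::zeros);
    for (int it = 0; it < max_iter; it++) {
      bool changed = false;
      // assign
      for (uword i = 0; i < n; i++) {
        double dmin = datum::inf; uword amin = 0;
        for (uword c = 0; c < C; c++) {
          double d = accu(square(X.row(i) - cent.row(c)));
          if (d < dmin) { dmin = d; amin = c; }
        }
        if (lab[i] != amin) { lab[i] = amin; changed = true; }
      }
      // refill empty clusters with the worst-fitting point
      for (uword c = 0; c < C; c++) {
        if (!any(lab == c)) {
          double dmax = -1; uword imax = 0;
          for (uword i = 0; i < n; i++) {
            double d = accu(square(X.row(i) - cent.row(lab[i])));
            if (d > dmax) { dmax = d; imax = i; }
          }
          lab[imax] = c; changed = true;
        }
      }
      // update
      for (uword c = 0; c < C; c++) {
        uvec members = find(lab == c);
        cent.row(c) = mean(X.rows(members), 0);
      }
      if (!changed) break;
    }
    double wcss = 0;
    for (uword i = 0; i < n; i++)
      wcss += accu(square(X.row(i) - cent.row(lab[i])));
    if (wcss < best_wcss) { best_wcss = wcss; best_lab = lab; }
  }
  return best_lab;
}

// Normalized spectral clustering (symmetric Laplacian embedding,
// row-normalised eigenvectors, k-means); labels 0..C-1.
static uvec spectral_core(const mat &W, uword C, std::mt19937_64 &rng, int nstart) {
  uword n = W.n_rows;
  vec deg = sum(W, 1);
  deg.replace(0.0, datum::eps);
  vec dis = 1.0 / sqrt(deg);
  mat L = -(W.each_col() % dis);
  L.each_row() %= dis.t();
  L.diag() += 1.0;            // L_sym = I - D^-1/2 W D^-1/2
  L = symmatu(L);
  vec ev; mat V;
  eig_sym(ev, V, L, "dc");    // ascending eigenvalues
  mat U = V.cols(0, C - 1);
  vec rn = sqrt(sum(square(U), 1));
  rn.replace(0.0, 1.0);
  U.each_col() /= rn;
  return kmeans_lloyd(U, C, rng, nstart);
}

// [[Rcpp::export(name = ".spectral_cluster_cpp")]]
Rcpp::IntegerVector spectral_cluster_cpp(const arma::mat &W, int C,
                                         double seed, int nstart) {
  std::mt19937_64 rng((uint64_t)seed);
  uvec lab = spectral_core(W, (uword)C, rng, nstart);
  Rcpp::IntegerVector out(lab.n_elem);
  for (uword i = 0; i < lab.n_elem; i++) out[i] = (int)lab[i] + 1;
  return out;
}

// Inner resampling consensus: n_boot subsamples (without replacement, or
// bootstrap with replacement) of the similarity network, spectral
// clustering of each subnetwork, accumulation of co-clustering and
// co-inclusion counts.
// [[Rcpp::export(name = ".consensus_boot_cpp")]]
Rcpp::List consensus_boot_cpp(const arma::mat &W, int C, int n_boot,
                              double frac, double seed, int nstart,
                              bool replace) {
  uword n = W.n_rows;
  uword m = (uword)std::round(frac * n);
  if (m < (uword)C) Rcpp::stop("subsample smaller than number of clusters");
  std::mt19937_64 rng((uint64_t)seed);
  mat together(n, n, fill::zeros);
  mat both(n, n, fill::zeros);
  for (int b = 0; b < n_boot; b++) {
    uvec idx;
    if (replace) {
      idx.set_size(m);
      for (uword i = 0; i < m; i++) idx[i] = draw_below(rng, n);
      idx = unique(idx);          // distinct items of the bootstrap draw
      if (idx.n_elem < (uword)C) { b--; continue; }
    } else {
      idx = sort(sample_without_replacement(rng, n, m));
    }
    mat Ws = W.submat(idx, idx);
    uvec lab = spectral_core(Ws, (uword)C, rng, nstart);
    for (uword a = 0; a < idx.n_elem; a++) {
      for (uword bb = a; bb < idx.n_elem; bb++) {
        uword ia = idx[a], ib = idx[bb];
        both(ia, ib) += 1.0;
        if (lab[a] == lab[bb]) together(ia, ib) += 1.0;
      }
    }
  }
  together = symmatu(together);
  both = symmatu(both);
  return Rcpp::List::create(Rcpp::Named("together") = together,
                            Rcpp::Named("both") = both);
}
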