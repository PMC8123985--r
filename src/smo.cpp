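// RBF-SVM support: SMO dual solver (maximal-violating-pair working set,
// LIBSVM-style), one-vs-one multiclass voting, and batched cross-validation
// / jackknife drivers that reuse squared-distance matrices across the
// (C, gamma) grid.  Deterministic: no randomness below this line.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Solve: min 0.5 a'Qa - e'a, 0 <= a <= C, y'a = 0, with Q_ij = y_i y_j K_ij.
// On exit alpha and b satisfy the KKT conditions to tolerance eps.
static int smo_solve(const mat& K, const vec& y, double C, double eps,
                     int max_iter, vec& alpha, double& b) {
  const int n = y.n_elem;
  alpha.zeros(n);
  vec G(n, fill::value(-1.0));  // gradient: Q a - e
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double gmax = -datum::inf, gmin = datum::inf;
    for (int t = 0; t < n; ++t) {
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      const double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    const double quad = std::max(K(i, i) + K(j, j) - 2.0 * K(i, j), 1e-12);
    double delta = (gmax - gmin) / quad;
    // box constraints along direction d_i = y_i, d_j = -y_j
    delta = std::min(delta, y[i] > 0 ? C - alpha[i] : alpha[i]);
    delta = std::min(delta, y[j] > 0 ? alpha[j] : C - alpha[j]);
    alpha[i] += y[i] * delta;
    alpha[j] -= y[j] * delta;
    for (int t = 0; t < n; ++t) {
      G[t] += delta * y[t] * (K(t, i) - K(t, j));
    }
  }
  // intercept from free support vectors, else midpoint of the violating gap
  double sum = 0.0; int nfree = 0;
  double gmax = -datum::inf, gmin = datum::inf;
  for (int t = 0; t < n; ++t) {
    const double v = -y[t] * G[t];
    const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    const bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (up) gmax = std::max(gmax, v);
    if (lo) gmin = std::min(gmin, v);
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { sum += v; ++nfree; }
  }
  b = nfree > 0 ? sum / nfree : (gmax + gmin) / 2.0;
  return iter;
}

// [[Rcpp::export]]
Rcpp::List smo_fit_cpp(const arma::mat& K, const arma::vec& y, double C,
                       double eps = 1e-3, int max_iter = 100000) {
  vec alpha; double b;
  int it = smo_solve(K, y, C, eps, max_iter, alpha, b);
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("iterations") = it);
}

// One-vs-one: train a binary SVM per class pair on Ktr (train x train
// kernel, labels 1..ncl) and vote on Kte (test x train kernel).
// Ties go to the smallest class index; a decision value of exactly 0
// votes for the smaller class of the pair.
static ivec ovo_vote(const mat& Ktr, const ivec& ytr, const mat& Kte,
                     int ncl, double C, double eps, int max_iter) {
  const int nte = Kte.n_rows;
  imat votes(nte, ncl, fill::zeros);
  for (int p = 1; p <= ncl; ++p) {
    uvec ip = find(ytr == p);
    if (ip.n_elem == 0) continue;
    for (int q = p + 1; q <= ncl; ++q) {
      uvec iq = find(ytr == q);
      if (iq.n_elem == 0) continue;
      uvec idx = join_cols(ip, iq);
      vec yb(idx.n_elem);
      yb.head(ip.n_elem).fill(1.0);
      yb.tail(iq.n_elem).fill(-1.0);
      mat Ksub = Ktr(idx, idx);
      vec alpha; double b;
      smo_solve(Ksub, yb, C, eps, max_iter, alpha, b);
      vec f = Kte.cols(idx) * (alpha % yb) + b;
      for (int t = 0; t < nte; ++t) {
        if (f[t] > 0) votes(t, p - 1) += 1; else votes(t, q - 1) += 1;
      }
    }
  }
  ivec pred(nte);
  for (int t = 0; t < nte; ++t) {
    pred[t] = (int)votes.row(t).index_max() + 1;  // first max: smallest class
  }
  return pred;
}

// [[Rcpp::export]]
arma::ivec ovo_predict_cpp(const arma::mat& Ktr, const arma::ivec& ytr,
                           const arma::mat& Kte, int ncl, double C,
                           double eps = 1e-3, int max_iter = 100000) {
  return ovo_vote(Ktr, ytr, Kte, ncl, C, eps, max_iter);
}

// Per-feature scale (train-sample sd, ddof 1) with constant columns -> 1.
static rowvec train_scale(const mat& X, const uvec& tr) {
  rowvec s = stddev(X.rows(tr), 0, 0);
  s.elem(find(s < 1e-12)).ones();
  return s;
}

// Squared Euclidean distances between all rows of A.
static mat sqdist(const mat& A) {
  vec q = sum(square(A), 1);
  mat D = repmat(q, 1, A.n_rows) + repmat(q.t(), A.n_rows, 1) - 2.0 * A * A.t();
  D.elem(find(D < 0)).zeros();
  return D;
}

// Pooled CV accuracy (correct counts) for every (C, gamma) pair.
// fold: 1..nfold per sample.  Standardization statistics are refit on each
// fold's training samples; centering cancels in kernel distances, so only
// the per-feature scale matters.
// [[Rcpp::export]]
arma::mat cv_grid_cpp(const arma::mat& X, const arma::ivec& y,
                      const arma::ivec& fold, const arma::vec& C_grid,
                      const arma::vec& gamma_grid, bool standardize = true,
                      double eps = 1e-3, int max_iter = 100000) {
  const int ncl = y.max();
  const int nfold = fold.max();
  mat correct(C_grid.n_elem, gamma_grid.n_elem, fill::zeros);
  for (int f = 1; f <= nfold; ++f) {
    uvec te = find(fold == f);
    uvec tr = find(fold != f);
    mat A = X;
    if (standardize) A.each_row() /= train_scale(X, tr);
    mat D = sqdist(A);
    ivec ytr = y(tr), yte = y(te);
    for (uword g = 0; g < gamma_grid.n_elem; ++g) {
      mat K = exp(-gamma_grid[g] * D);
      mat Ktr = K(tr, tr), Kte = K(te, tr);
      for (uword c = 0; c < C_grid.n_elem; ++c) {
        ivec pred = ovo_vote(Ktr, ytr, Kte, ncl, C_grid[c], eps, max_iter);
        correct(c, g) += accu(pred == yte);
      }
    }
  }
  return correct / (double)X.n_rows;
}

// Leave-one-out predictions of the one-vs-one RBF-SVM.
// [[Rcpp::export]]
arma::ivec jackknife_cpp(const arma::mat& X, const arma::ivec& y, double C,
                         double gamma, bool standardize = true,
                         double eps = 1e-3, int max_iter = 100000) {
  const int n = X.n_rows;
  const int ncl = y.max();
  ivec pred(n);
  uvec all = regspace<uvec>(0, n - 1);
  for (int i = 0; i < n; ++i) {
    uvec tr = find(all != (uword)i);
    mat A = X;
    if (standardize) A.each_row() /= train_scale(X, tr);
    mat D = sqdist(A);
    mat K = exp(-gamma * D);
    uvec te(1); te[0] = i;
    ivec p = ovo_vote(K(tr, tr), y(tr), K(te, tr), ncl, C, eps, max_iter);
    pred[i] = p[0];
  }
  return pred;
}
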