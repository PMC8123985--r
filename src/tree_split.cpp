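// Hot loop of the decision-tree grower: exhaustive information-gain search
// over (feature, midpoint-threshold) pairs.  Tie rules match the R caller:
// within a feature the first maximum wins (smallest threshold); across
// features, iterated in name order, a later feature must beat the
// incumbent by more than 1e-12 (lower feature name wins ties).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double entropy_counts(const double* c, int nclass, double tot) {
  double h = 0.0;
  for (int k = 0; k < nclass; ++k) {
    if (c[k] > 0) {
      const double p = c[k] / tot;
      h -= p * std::log2(p);
    }
  }
  return h;
}

// [[Rcpp::export]]
Rcpp::List best_split_cpp(const arma::mat& X, const arma::ivec& yi, int nclass,
                          const arma::uvec& feat_order) {
  const int n = yi.n_elem;
  std::vector<double> parent(nclass, 0.0);
  for (int i = 0; i < n; ++i) parent[yi[i] - 1] += 1.0;
  const double h_parent = entropy_counts(parent.data(), nclass, n);

  double best_ig = -1.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<double> lc(nclass), rc(nclass);
  for (uword fo = 0; fo < feat_order.n_elem; ++fo) {
    const int j = feat_order[fo] - 1;  // 1-based from R
    const vec x = X.col(j);
    const uvec o = stable_sort_index(x);
    std::fill(lc.begin(), lc.end(), 0.0);
    double local_best = -1.0, local_thr = 0.0;
    for (int r = 0; r < n - 1; ++r) {
      lc[yi[o[r]] - 1] += 1.0;
      if (x[o[r]] < x[o[r + 1]]) {
        const double nl = r + 1, nr = n - nl;
        for (int k = 0; k < nclass; ++k) rc[k] = parent[k] - lc[k];
        const double ig = h_parent -
          (nl * entropy_counts(lc.data(), nclass, nl) +
           nr * entropy_counts(rc.data(), nclass, nr)) / n;
        if (ig > local_best) {
          local_best = ig;
          local_thr = (x[o[r]] + x[o[r + 1]]) / 2.0;
        }
      }
    }
    if (local_best > 1e-12 && (best_f < 0 || local_best > best_ig + 1e-12)) {
      best_ig = local_best;
      best_f = j + 1;
      best_thr = local_thr;
    }
  }
  if (best_f < 0) return Rcpp::List::create(Rcpp::Named("fidx") = -1);
  return Rcpp::List::create(Rcpp::Named("fidx") = best_f,
                            Rcpp::Named("threshold") = best_thr,
                            Rcpp::Named("info_gain") = best_ig);
}
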