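#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// One Gauss-Seidel block-coordinate-descent sweep over features.
//
// Phi : n x p matrix of current transformed (standardized) values.
// W   : p x p projector U U' onto the current top-q eigenspace of K.
// D   : n x p integer matrix of 0-based category labels.
// m   : per-feature category counts.
//
// For each feature j (in index order, using the latest values of all
// other features) the update sets phi_j(c) to the mean of
// g_j(i) = sum_{j' != j} W(j,j') phi_{j'}(D[i,j']) over samples i with
// D[i,j] = c, then re-standardizes to weighted mean 0 / variance 1
// (divisor n).  A zero-variance ("degenerate") update keeps the
// previous transform so the objective cannot decrease.
// [[Rcpp::export]]
Rcpp::List bcd_sweep(arma::mat Phi, const arma::mat& W,
                     const arma::imat& D, const arma::ivec& m) {
  const arma::uword n = Phi.n_rows, p = Phi.n_cols;
  int degenerate = 0;
  for (arma::uword j = 0; j < p; ++j) {
    arma::vec g = Phi * W.col(j) - W(j, j) * Phi.col(j);
    const int mj = m(j);
    arma::vec s(mj, arma::fill::zeros), cnt(mj, arma::fill::zeros);
    for (arma::uword i = 0; i < n; ++i) {
      const int c = D(i, j);
      s(c) += g(i);
      cnt(c) += 1.0;
    }
    arma::vec phi(mj, arma::fill::zeros);
    for (int c = 0; c < mj; ++c)
      if (cnt(c) > 0) phi(c) = s(c) / cnt(c);
    const double mu = arma::dot(cnt, phi) / static_cast<double>(n);
    double v = 0.0;
    for (int c = 0; c < mj; ++c)
      v += cnt(c) * (phi(c) - mu) * (phi(c) - mu);
    v /= static_cast<double>(n);
    if (v < 1e-12) {  // constant update: retain previous transform
      ++degenerate;
      continue;
    }
    const double sd = std::sqrt(v);
    for (arma::uword i = 0; i < n; ++i)
      Phi(i, j) = (phi(D(i, j)) - mu) / sd;
  }
  return Rcpp::List::create(Rcpp::Named("Phi") = Phi,
                            Rcpp::Named("degenerate") = degenerate);
}

// Exact 1-D optimal partition (Fisher/Jenks dynamic programming).
//
// vals : sorted distinct values; wts : their multiplicities.
// Returns the 0-based class index of each distinct value for the
// partition into k contiguous classes minimizing the total weighted
// within-class sum of squares.  Contiguity in sorted order is optimal
// for 1-D k-means, and contiguity makes class labels automatically
// ordered by class mean.
// [[Rcpp::export]]
arma::ivec jenks_dp(const arma::vec& vals, const arma::vec& wts, const int k) {
  const int d = vals.n_elem;
  // prefix sums for O(1) weighted SS of a value range [i, j]
  arma::vec cw(d + 1, arma::fill::zeros), cs(d + 1, arma::fill::zeros),
      cq(d + 1, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    cw(i + 1) = cw(i) + wts(i);
    cs(i + 1) = cs(i) + wts(i) * vals(i);
    cq(i + 1) = cq(i) + wts(i) * vals(i) * vals(i);
  }
  auto ss = [&](int i, int j) {  // within-class SS of values i..j inclusive
    const double w = cw(j + 1) - cw(i);
    const double s = cs(j + 1) - cs(i);
    const double q = cq(j + 1) - cq(i);
    return q - s * s / w;
  };
  const double inf = std::numeric_limits<double>::infinity();
  arma::mat dp(k, d);
  arma::imat back(k, d);
  for (int j = 0; j < d; ++j) {
    dp(0, j) = ss(0, j);
    back(0, j) = 0;
  }
  for (int c = 1; c < k; ++c) {
    for (int j = 0; j < d; ++j) {
      if (j < c) {  // not enough values for c+1 nonempty classes
        dp(c, j) = inf;
        back(c, j) = -1;
        continue;
      }
      double best = inf;
      int arg = -1;
      for (int i = c; i <= j; ++i) {  // class c covers values i..j
        const double cand = dp(c - 1, i - 1) + ss(i, j);
        if (cand < best) {
          best = cand;
          arg = i;
        }
      }
      dp(c, j) = best;
      back(c, j) = arg;
    }
  }
  arma::ivec lab(d);
  int j = d - 1;
  for (int c = k - 1; c >= 0; --c) {
    const int i = back(c, j);
    for (int t = i; t <= j; ++t) lab(t) = c;
    j = i - 1;
  }
  return lab;
}
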