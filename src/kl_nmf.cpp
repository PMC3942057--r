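#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Generalized Kullback-Leibler divergence D(V || WH).
// Zero cells of V contribute WH only; WH is assumed floored away from 0.
static double gkl(const mat& V, const mat& WH) {
  double d = 0.0;
  const double* v = V.memptr();
  const double* w = WH.memptr();
  const uword n = V.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (v[i] > 0.0)
      d += v[i] * std::log(v[i] / w[i]) - v[i] + w[i];
    else
      d += w[i];
  }
  return d;
}

static inline void floor_eps(mat& X, double eps) {
  X.for_each([eps](double& x) { if (x < eps) x = eps; });
}

// Multiplicative-update NMF under generalized KL divergence (Lee-Seung /
// Brunet lineage). W and H are the caller-supplied initializations; the
// update is fully deterministic given them. Convergence is declared when
// the relative change of the objective between successive checkpoints
// (every `check_every` iterations) drops below `tol`. When `update_w` is
// false only H is updated (exposure refit against a fixed signature set).
//
// Returns W, H, the final divergence, the iteration count and the
// objective trace at checkpoints (for monotonicity assertions).
// [[Rcpp::export(name = ".kl_nmf_run")]]
Rcpp::List kl_nmf_run(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, int check_every,
                      bool update_w) {
  const double eps = 1e-12;
  floor_eps(W, eps);
  floor_eps(H, eps);

  mat WH = W * H;
  floor_eps(WH, eps);
  double prev = gkl(V, WH);
  std::vector<double> trace;
  trace.push_back(prev);

  int it = 0;
  double div = prev;
  for (it = 1; it <= max_iter; ++it) {
    // H <- H * (W' (V/WH)) / (W' 1)
    mat R = V / WH;
    colvec wsum = sum(W, 0).t() + eps;
    H %= (W.t() * R);
    H.each_col() /= wsum;
    WH = W * H;
    floor_eps(WH, eps);

    if (update_w) {
      // W <- W * ((V/WH) H') / (1 H')
      R = V / WH;
      rowvec hsum = sum(H, 1).t() + eps;
      W %= (R * H.t());
      W.each_row() /= hsum;
      WH = W * H;
      floor_eps(WH, eps);
    }

    if (it % check_every == 0 || it == max_iter) {
      div = gkl(V, WH);
      trace.push_back(div);
      double denom = std::max(1e-10, std::abs(prev));
      if (std::abs(prev - div) / denom < tol) break;
      prev = div;
    }
  }
  if (it > max_iter) it = max_iter;
  div = gkl(V, WH);

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("divergence") = div,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("trace") = trace);
}

// [[Rcpp::export(name = ".gkl_divergence")]]
double gkl_divergence(const arma::mat& V, const arma::mat& W,
                      const arma::mat& H) {
  mat WH = W * H;
  floor_eps(WH, 1e-12);
  return gkl(V, WH);
}
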