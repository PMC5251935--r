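// Multiplicative KL-divergence NMF updates (Brunet/Lee-Seung form).
// The update algebra is mirrored by the R reference functions
// nmf_update_h()/nmf_update_w(); tests assert the two paths agree.
//
// The kernels are fused over columns of A so that W and the k x 1 work
// vectors stay cache-resident: at the ranks used here (k <= 6) the naive
// BLAS route (explicit W*H) is memory-bound and several times slower.
//
// Two stopping rules are supported:
//  - KL rule: relative change in KL divergence over `check_every`
//    iterations below `tol` (used when converged W/H matter, e.g. for
//    D-score loadings);
//  - connectivity rule (`stable_iters` > 0): the argmax-of-H sample
//    assignment unchanged for `stable_iters` consecutive iterations
//    (the classical consensus-clustering criterion; only assignments are
//    consumed there).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// one full update round (H then W), fixed rank K for unrolling
template <int K>
static void update_round(const mat& A, mat& W, mat& H, double eps) {
  const uword n = A.n_rows, m = A.n_cols;
  double h[K], num[K], wc[K];

  // column sums of W (denominator of the H rule), floored at eps
  for (int a = 0; a < K; ++a) {
    double s = 0.0;
    const double* wcol = W.colptr(a);
    for (uword i = 0; i < n; ++i) s += wcol[i];
    wc[a] = s < eps ? eps : s;
  }

  // H_au <- H_au * [sum_i W_ia A_iu / (WH)_iu] / sum_k W_ka
  for (uword u = 0; u < m; ++u) {
    for (int a = 0; a < K; ++a) { h[a] = H.at(a, u); num[a] = 0.0; }
    const double* acol = A.colptr(u);
    for (uword i = 0; i < n; ++i) {
      double wh = 0.0;
      for (int a = 0; a < K; ++a) wh += W.at(i, a) * h[a];
      double r = acol[i] / (wh < eps ? eps : wh);
      for (int a = 0; a < K; ++a) num[a] += W.at(i, a) * r;
    }
    for (int a = 0; a < K; ++a) H.at(a, u) = h[a] * num[a] / wc[a];
  }

  // W_ia <- W_ia * [sum_u H_au A_iu / (WH)_iu] / sum_v H_av  (new H)
  mat numW(n, K, fill::zeros);
  double hr[K];
  for (int a = 0; a < K; ++a) hr[a] = 0.0;
  for (uword u = 0; u < m; ++u) {
    for (int a = 0; a < K; ++a) { h[a] = H.at(a, u); hr[a] += h[a]; }
    const double* acol = A.colptr(u);
    for (uword i = 0; i < n; ++i) {
      double wh = 0.0;
      for (int a = 0; a < K; ++a) wh += W.at(i, a) * h[a];
      double r = acol[i] / (wh < eps ? eps : wh);
      for (int a = 0; a < K; ++a) numW.at(i, a) += h[a] * r;
    }
  }
  for (int a = 0; a < K; ++a) {
    double d = hr[a] < eps ? eps : hr[a];
    double* wcol = W.colptr(a);
    const double* ncol = numW.colptr(a);
    for (uword i = 0; i < n; ++i) wcol[i] *= ncol[i] / d;
  }
}

// generic-rank fallback via BLAS
static void update_round_generic(const mat& A, mat& W, mat& H, double eps) {
  mat WH = clamp(W * H, eps, datum::inf);
  H %= (W.t() * (A / WH));
  vec wc = clamp(sum(W, 0).t(), eps, datum::inf);
  H.each_col() /= wc;
  WH = clamp(W * H, eps, datum::inf);
  W %= ((A / WH) * H.t());
  rowvec hr = clamp(sum(H, 1).t(), eps, datum::inf);
  W.each_row() /= hr;
}

static void do_round(const mat& A, mat& W, mat& H, double eps) {
  switch (W.n_cols) {
    case 1: update_round<1>(A, W, H, eps); break;
    case 2: update_round<2>(A, W, H, eps); break;
    case 3: update_round<3>(A, W, H, eps); break;
    case 4: update_round<4>(A, W, H, eps); break;
    case 5: update_round<5>(A, W, H, eps); break;
    case 6: update_round<6>(A, W, H, eps); break;
    default: update_round_generic(A, W, H, eps); break;
  }
}

static double kl_div(const mat& A, const mat& W, const mat& H, double eps,
                     double sum_A, double sum_AlogA) {
  const uword n = A.n_rows, m = A.n_cols, k = W.n_cols;
  double cross = 0.0, sum_WH = 0.0;
  std::vector<double> h(k);
  for (uword u = 0; u < m; ++u) {
    for (uword a = 0; a < k; ++a) h[a] = H.at(a, u);
    const double* acol = A.colptr(u);
    for (uword i = 0; i < n; ++i) {
      double wh = 0.0;
      for (uword a = 0; a < k; ++a) wh += W.at(i, a) * h[a];
      sum_WH += wh;
      if (acol[i] > 0.0) {
        cross += acol[i] * std::log(wh < eps ? eps : wh);
      }
    }
  }
  return sum_AlogA - cross - sum_A + sum_WH;
}

// [[Rcpp::export]]
Rcpp::List cpp_nmf_kl(const arma::mat& A, arma::mat W, arma::mat H,
                      int max_iter, double tol, int check_every, double eps,
                      int stable_iters) {
  uvec nz = find(A > 0);
  const double sum_A = accu(A.elem(nz));
  const double sum_AlogA = accu(A.elem(nz) % log(A.elem(nz)));

  std::vector<double> trace;
  double kl_prev = kl_div(A, W, H, eps, sum_A, sum_AlogA);
  trace.push_back(kl_prev);

  uvec labels_prev = index_max(H, 0).t();
  int stable = 0;
  bool converged = false;
  std::string reason = "max_iter";
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    do_round(A, W, H, eps);

    if (iter % check_every == 0 || iter == max_iter) {
      if (stable_iters > 0) {
        uvec labels = index_max(H, 0).t();
        if (labels.n_elem == labels_prev.n_elem && all(labels == labels_prev)) {
          stable += check_every;
        } else {
          stable = 0;
          labels_prev = labels;
        }
      }
      double kl = kl_div(A, W, H, eps, sum_A, sum_AlogA);
      trace.push_back(kl);
      double denom = std::max(kl_prev, eps);
      bool kl_stop = std::fabs(kl_prev - kl) / denom < tol;
      kl_prev = kl;
      if (kl_stop) {
        converged = true;
        reason = "kl";
        break;
      }
      if (stable_iters > 0 && stable >= stable_iters) {
        converged = true;
        reason = "connectivity";
        break;
      }
    }
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("reason") = reason,
    Rcpp::Named("final_kl") = kl_prev);
}
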