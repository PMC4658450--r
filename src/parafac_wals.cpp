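// Weighted nonnegative HALS core for the trilinear PARAFAC fit.
// The residual is taken over observed cells only (0/1 weights); each mode is
// updated one component column at a time, with the residual matrix
// maintained incrementally. The column subproblem is separable per entry:
// SSE(b_i) = const - 2 num_i b_i + d_i b_i^2, with d_i the observed design
// energy of the entry and num_i the residual projection.
//
// Two update rules share this machinery:
//  * plain ridge (monotone = false): b_i = max(0, num_i / (d_i + lam_r)),
//    the exact minimizer of the ridge-damped criterion. The ridge (a small
//    fraction of the component's maximum design energy) keeps structurally
//    unidentifiable cells — observed only where the component carries no
//    signal — from soaking up noise. Used for exploratory/initialization
//    passes.
//  * projected ridge (monotone = true): the ridge candidate is clamped to
//    the interval around the unpenalized minimizer where the observed SSE
//    does not increase, so every update is non-increasing in SSE by
//    construction while retaining the damping wherever it is free.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void update_mode(mat& M, const mat& X, const mat& O, const mat& Z,
                        double ridge_rel, bool monotone, mat& R) {
  const uword k = M.n_cols;
  mat D = O * square(Z);              // m x k observed design energy
  R = O % (X - M * Z.t());
  for (uword r = 0; r < k; ++r) {
    vec d = D.col(r);
    double dmax = d.max();
    if (dmax <= 0) { M.col(r).zeros(); continue; }
    double lam = ridge_rel * dmax;
    vec num = R * Z.col(r) + M.col(r) % d;
    vec mnew(M.n_rows);
    for (uword i = 0; i < M.n_rows; ++i) {
      double x = M(i, r);
      if (d(i) <= dmax * 1e-15) { mnew(i) = 0.0; continue; }
      double yr = num(i) / (d(i) + lam);
      if (yr < 0) yr = 0;
      if (monotone) {
        double ylr = num(i) / d(i);
        double lo = x + std::min(0.0, 2.0 * (ylr - x));
        double hi = x + std::max(0.0, 2.0 * (ylr - x));
        yr = std::max(lo, std::min(yr, hi));
      }
      mnew(i) = yr;
    }
    vec delta = mnew - M.col(r);
    R -= (delta * Z.col(r).t()) % O;
    M.col(r) = mnew;
  }
}

static mat khatri_rao(const mat& C, const mat& B) {
  // row index i + B.n_rows * j  ->  B.row(i) % C.row(j)
  mat Z(B.n_rows * C.n_rows, B.n_cols);
  for (uword j = 0; j < C.n_rows; ++j) {
    Z.rows(j * B.n_rows, (j + 1) * B.n_rows - 1) =
      B.each_row() % C.row(j);
  }
  return Z;
}

static double sse_of(const mat& XA, const mat& OA,
                     const mat& A, const mat& B, const mat& C) {
  return accu(square(OA % (XA - A * khatri_rao(C, B).t())));
}

// [[Rcpp::export(name = ".parafac_wals_cpp")]]
Rcpp::List parafac_wals_cpp(const arma::mat& XA, const arma::mat& OA,
                            const arma::mat& XB, const arma::mat& OB,
                            const arma::mat& XC, const arma::mat& OC,
                            arma::mat A, arma::mat B, arma::mat C,
                            double tol, int max_iter,
                            double ridge_rel, bool monotone) {
  const uword k = A.n_cols;
  std::vector<double> sse_history;
  double sse_prev = datum::inf;
  bool converged = false;
  int iter = 0;
  mat R;
  // line-search extrapolation state (accepted only when SSE decreases, so
  // the trajectory stays non-increasing)
  mat Ap, Bp, Cp;
  double accel_w = 1.5;
  while (iter < max_iter) {
    ++iter;
    mat A0 = A, B0 = B, C0 = C;
    update_mode(A, XA, OA, khatri_rao(C, B), ridge_rel, monotone, R);
    update_mode(B, XB, OB, khatri_rao(C, A), ridge_rel, monotone, R);
    update_mode(C, XC, OC, khatri_rao(B, A), ridge_rel, monotone, R);
    double sse = accu(square(R));  // R holds the final observed residual
    if (iter >= 5) {
      mat Ac = clamp(A + accel_w * (A - A0), 0.0, datum::inf);
      mat Bc = clamp(B + accel_w * (B - B0), 0.0, datum::inf);
      mat Cc = clamp(C + accel_w * (C - C0), 0.0, datum::inf);
      double sse_c = sse_of(XA, OA, Ac, Bc, Cc);
      if (sse_c < sse) {
        A = std::move(Ac); B = std::move(Bc); C = std::move(Cc);
        sse = sse_c;
        accel_w = std::min(accel_w * 1.15, 4.0);
      } else {
        accel_w = std::max(accel_w * 0.7, 1.0);
      }
    }
    // unit-maximum spectral loadings; scale absorbed into scores
    for (uword r = 0; r < k; ++r) {
      double mb = B.col(r).max(), mc = C.col(r).max();
      if (mb > 0) B.col(r) /= mb;
      if (mc > 0) C.col(r) /= mc;
      A.col(r) *= mb * mc;
    }
    sse_history.push_back(sse);
    if (std::isfinite(sse_prev) &&
        std::fabs(sse_prev - sse) <= tol * std::max(sse_prev, 1e-300)) {
      converged = true;
      break;
    }
    sse_prev = sse;
  }
  return Rcpp::List::create(
    Rcpp::Named("A") = A, Rcpp::Named("B") = B, Rcpp::Named("C") = C,
    Rcpp::Named("sse_history") = sse_history,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged);
}
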