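// Weighted linear least-squares DTI/DKI fitting and scalar-map extraction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Two-pass WLLS on log-signals. S: n_vol x n_vox, A: n_vol x p design.
// Pass 1 is a single unweighted solve shared across voxels; pass 2 weights
// each row by the squared predicted signal from pass 1. Signals are floored
// at floor_frac * (mean b0) before the log; voxels with any non-positive or
// non-finite raw signal are flagged (but still fitted on floored data).
// [[Rcpp::export(name = ".wlls_fit_cpp")]]
Rcpp::List wlls_fit_cpp(const arma::mat& S,
                        const arma::mat& A,
                        const arma::uvec& mask,
                        const arma::uvec& b0idx,  // 1-based indices of b=0 rows
                        double floor_frac,
                        bool weighted) {
  const int nvol = S.n_rows, p = A.n_cols;
  const uword nvox = S.n_cols;
  mat B(p, nvox, fill::value(datum::nan));
  uvec fit_ok(nvox, fill::zeros);

  // pass 1: common pseudo-inverse
  mat AtA = A.t() * A;
  mat AtAinv;
  if (!inv_sympd(AtAinv, symmatu(AtA)))
    Rcpp::stop("design matrix is rank deficient");
  mat P1 = AtAinv * A.t();  // p x n_vol

  vec logS(nvol), w(nvol);
  mat Aw(nvol, p);
  vec bw(nvol), beta(p), pred(nvol);
  for (uword vx = 0; vx < nvox; ++vx) {
    if (!mask(vx)) continue;
    const double* s = S.colptr(vx);
    double b0 = 0;
    for (uword i = 0; i < b0idx.n_elem; ++i) b0 += s[b0idx(i) - 1];
    b0 /= std::max((uword)1, b0idx.n_elem);
    if (!std::isfinite(b0) || b0 <= 0) b0 = 1.0;
    const double floorv = floor_frac * b0;
    bool clean = true;
    for (int v = 0; v < nvol; ++v) {
      double x = s[v];
      if (!std::isfinite(x) || x <= 0) clean = false;
      if (!std::isfinite(x) || x < floorv) x = floorv;
      logS(v) = std::log(x);
    }
    beta = P1 * logS;
    if (!weighted) {
      B.col(vx) = beta;
      fit_ok(vx) = clean && beta.is_finite() ? 1 : 0;
      continue;
    }
    pred = A * beta;
    // weights = squared predicted signals (scale-normalized); the weighted
    // rows are solved by QR for numerical stability
    double pmax = pred.max();
    for (int v = 0; v < nvol; ++v) w(v) = std::exp(pred(v) - pmax);
    for (int v = 0; v < nvol; ++v) {
      Aw.row(v) = w(v) * A.row(v);
      bw(v) = w(v) * logS(v);
    }
    vec beta2;
    if (solve(beta2, Aw, bw, solve_opts::no_approx)) {
      B.col(vx) = beta2;
      fit_ok(vx) = clean && beta2.is_finite() ? 1 : 0;
    } else {
      B.col(vx) = beta;  // keep the LLS solution, flag the voxel
      fit_ok(vx) = 0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("coef") = B, Rcpp::Named("fit_ok") = fit_ok);
}

namespace {

// kurtosis-tensor monomial evaluation: coefficient order is lexicographic
// (xxxx, xxxy, xxxz, xxyy, xxyz, xxzz, xyyy, xyyz, xyzz, xzzz,
//  yyyy, yyyz, yyzz, yzzz, zzzz) with symmetric-tensor multiplicities.
const int KT_MULT[15] = {1, 4, 4, 6, 12, 6, 4, 12, 12, 4, 1, 4, 6, 4, 1};
const int KT_PX[15] = {4, 3, 3, 2, 2, 2, 1, 1, 1, 1, 0, 0, 0, 0, 0};
const int KT_PY[15] = {0, 1, 0, 2, 1, 0, 3, 2, 1, 0, 4, 3, 2, 1, 0};
const int KT_PZ[15] = {0, 0, 1, 0, 1, 2, 0, 1, 2, 3, 0, 1, 2, 3, 4};

inline double powi(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

inline double kt_form(const double* kt, double nx, double ny, double nz) {
  double s = 0;
  for (int c = 0; c < 15; ++c)
    s += KT_MULT[c] * kt[c] * powi(nx, KT_PX[c]) * powi(ny, KT_PY[c]) * powi(nz, KT_PZ[c]);
  return s;
}

inline double dt_form(const double* dt, double nx, double ny, double nz) {
  // dt order: xx, xy, xz, yy, yz, zz
  return dt[0] * nx * nx + dt[3] * ny * ny + dt[5] * nz * nz +
         2.0 * (dt[1] * nx * ny + dt[2] * nx * nz + dt[4] * ny * nz);
}

}  // namespace

// Scalar maps from fitted coefficients. B is 22 x n_vox in the layout
// (lnS0, dt[6], kt[15]) with kt = MD^2 * W so K(n) = kt(n)/D(n)^2.
// dirs: 3 x ndir unit directions with quadrature weights wts (sum 1) for MK;
// n_rk: number of equally spaced in-plane directions for RK.
// [[Rcpp::export(name = ".scalar_maps_cpp")]]
Rcpp::List scalar_maps_cpp(const arma::mat& B,
                           const arma::uvec& mask,
                           const arma::mat& dirs,
                           const arma::vec& wts,
                           int n_rk) {
  const uword nvox = B.n_cols;
  const int ndir = dirs.n_cols;
  vec MD(nvox, fill::value(datum::nan)), AD(MD), RD(MD), FA(MD), MK(MD), AK(MD), RK(MD);
  uvec valid(nvox, fill::zeros);

  mat33 D;
  vec3 ev;
  mat33 V;
  for (uword vx = 0; vx < nvox; ++vx) {
    if (!mask(vx)) continue;
    const double* b = B.colptr(vx);
    const double* dt = b + 1;
    const double* kt = b + 7;
    bool fin = true;
    for (int i = 0; i < 22; ++i)
      if (!std::isfinite(b[i])) fin = false;
    if (!fin) continue;
    D(0, 0) = dt[0]; D(0, 1) = dt[1]; D(0, 2) = dt[2];
    D(1, 0) = dt[1]; D(1, 1) = dt[3]; D(1, 2) = dt[4];
    D(2, 0) = dt[2]; D(2, 1) = dt[4]; D(2, 2) = dt[5];
    if (!eig_sym(ev, V, D)) continue;  // ascending eigenvalues
    const double l1 = ev(2), l2 = ev(1), l3 = ev(0);
    const double md = (l1 + l2 + l3) / 3.0;
    MD(vx) = md;
    AD(vx) = l1;
    RD(vx) = 0.5 * (l2 + l3);
    const double num = (l1 - l2) * (l1 - l2) + (l1 - l3) * (l1 - l3) + (l2 - l3) * (l2 - l3);
    const double den = l1 * l1 + l2 * l2 + l3 * l3;
    FA(vx) = den > 0 ? std::sqrt(0.5 * num / den) : datum::nan;

    const vec3 e1 = V.col(2), e2 = V.col(1), e3 = V.col(0);
    // axial kurtosis: analytic along the principal eigenvector
    AK(vx) = (l1 != 0) ? kt_form(kt, e1(0), e1(1), e1(2)) / (l1 * l1) : datum::nan;
    // radial kurtosis: average over the e2/e3 plane
    double rk = 0;
    bool bad = false;
    for (int a = 0; a < n_rk; ++a) {
      const double ph = 2.0 * datum::pi * a / n_rk;
      const vec3 n = std::cos(ph) * e2 + std::sin(ph) * e3;
      const double dn = dt_form(dt, n(0), n(1), n(2));
      if (std::abs(dn) < 1e-12) { bad = true; break; }
      rk += kt_form(kt, n(0), n(1), n(2)) / (dn * dn);
    }
    RK(vx) = bad ? datum::nan : rk / n_rk;
    // mean kurtosis: weighted average over the global direction set
    double mk = 0;
    bad = false;
    for (int a = 0; a < ndir; ++a) {
      const double nx = dirs(0, a), ny = dirs(1, a), nz = dirs(2, a);
      const double dn = dt_form(dt, nx, ny, nz);
      if (std::abs(dn) < 1e-12) { bad = true; break; }
      mk += wts(a) * kt_form(kt, nx, ny, nz) / (dn * dn);
    }
    MK(vx) = bad ? datum::nan : mk;
    valid(vx) = 1;
  }
  return Rcpp::List::create(
      Rcpp::Named("MD") = MD, Rcpp::Named("AD") = AD, Rcpp::Named("RD") = RD,
      Rcpp::Named("FA") = FA, Rcpp::Named("MK") = MK, Rcpp::Named("AK") = AK,
      Rcpp::Named("RK") = RK, Rcpp::Named("valid") = valid);
}
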