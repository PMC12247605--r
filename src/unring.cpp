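// Subvoxel-shift Gibbs unringing (total-variation search over shifted
// resamplings) with the complementary spectral weighting filters that route
// each axis pass onto ringing oriented along that axis.
//
// The ringing geometry is set by the anatomy, which is shared by every
// diffusion-weighted volume, so the optimal shift field is estimated once
// per slice from total-variation measures summed over volumes and the same
// shifts are applied to all volumes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Unring a bundle of aligned lines (n samples x nvol volumes) along their
// length. nsh subvoxel shifts are tested on either side of zero (2*nsh+1
// total, covering [-1/2, 1/2] voxel); for each sample the shift minimizing
// the smaller of the left/right total variation over the [k1, k2] neighbor
// band (summed over volumes, excluding the pair touching the center sample)
// is kept, and each volume's shifted line is linearly interpolated back to
// the integer grid. Periodic boundaries.
mat unring_line_bundle(const mat& X, int nsh, int k1, int k2) {
  const int n = X.n_rows, nvol = X.n_cols;
  const int nshift = 2 * nsh + 1;
  cx_mat C = fft(cx_mat(X, mat(n, nvol, fill::zeros)));

  vec kk(n);
  for (int k = 0; k < n; ++k) kk(k) = (k <= n / 2) ? k : k - n;

  std::vector<mat> shifted(nshift);
  for (int j = 0; j < nshift; ++j) {
    const double s = (double)(j - nsh) / (2.0 * nsh);
    cx_vec ph(n);
    for (int k = 0; k < n; ++k) {
      if (n % 2 == 0 && k == n / 2) {
        ph(k) = cx_double(std::cos(datum::pi * s), 0.0);  // keep output real
      } else {
        const double a = 2.0 * datum::pi * kk(k) * s / n;
        ph(k) = cx_double(std::cos(a), std::sin(a));
      }
    }
    shifted[j] = real(ifft(cx_mat(C.each_col() % ph)));
  }

  // visit shifts by increasing magnitude so the zero shift wins ties
  std::vector<int> order(nshift);
  std::iota(order.begin(), order.end(), 0);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    const int da = std::abs(a - nsh), db = std::abs(b - nsh);
    if (da != db) return da < db;
    return a > b;
  });

  mat out(n, nvol);
  for (int t = 0; t < n; ++t) {
    double best = datum::inf;
    int bestj = nsh;
    for (int jj = 0; jj < nshift; ++jj) {
      const int j = order[jj];
      const mat& S = shifted[j];
      double tvl = 0, tvr = 0;
      for (int d = k1; d <= k2; ++d) {
        const int a = ((t - d) % n + n) % n, b = ((t - d - 1) % n + n) % n;
        const int e = ((t + d) % n + n) % n, f = ((t + d + 1) % n + n) % n;
        for (int v = 0; v < nvol; ++v) {
          tvl += std::abs(S(a, v) - S(b, v));
          tvr += std::abs(S(e, v) - S(f, v));
        }
      }
      const double m = std::min(tvl, tvr);
      if (m < best) {
        best = m;
        bestj = j;
      }
    }
    const double s = (double)(bestj - nsh) / (2.0 * nsh);
    const mat& S = shifted[bestj];
    if (s > 0) {
      const int tm = ((t - 1) % n + n) % n;
      for (int v = 0; v < nvol; ++v)
        out(t, v) = s * S(tm, v) + (1.0 - s) * S(t, v);
    } else if (s < 0) {
      const int tp = (t + 1) % n;
      for (int v = 0; v < nvol; ++v)
        out(t, v) = (-s) * S(tp, v) + (1.0 + s) * S(t, v);
    } else {
      for (int v = 0; v < nvol; ++v) out(t, v) = S(t, v);
    }
  }
  return out;
}

// complementary filter pair; G -> 1 near the row-frequency Nyquist
void filter_split(const mat& img, mat& part_row, mat& part_col) {
  const int n = img.n_rows, m = img.n_cols;
  cx_mat F = fft2(cx_mat(img, mat(n, m, fill::zeros)));
  mat G(n, m);
  for (int j = 0; j < m; ++j) {
    const double kj = 2.0 * datum::pi * ((j <= m / 2) ? j : j - m) / m;
    const double cj = 1.0 + std::cos(kj);
    for (int i = 0; i < n; ++i) {
      const double ki = 2.0 * datum::pi * ((i <= n / 2) ? i : i - n) / n;
      const double ci = 1.0 + std::cos(ki);
      const double den = ci + cj;
      G(i, j) = den > 1e-14 ? cj / den : 0.5;
    }
  }
  part_row = real(ifft2(F % cx_mat(G, mat(n, m, fill::zeros))));
  part_col = img - part_row;
}

}  // namespace

// Exposed single-bundle form (each column one volume of the same line).
// [[Rcpp::export(name = ".unring_cols_cpp")]]
arma::mat unring_cols_cpp(const arma::mat& X, int nsh, int k1, int k2) {
  return unring_line_bundle(X, nsh, k1, k2);
}

// Slice-wise unringing of a 4D stack packed as (nx, ny, nz*nvol) with the
// slice index fastest: slab s = z + nz*v. For every spatial slice z the
// shift field is shared across the nvol volumes. restrict: 0 = unring both
// in-plane axes, 1 = rows only, 2 = columns only.
// [[Rcpp::export(name = ".unring_stack_cpp")]]
arma::cube unring_stack_cpp(const arma::cube& A, int nz, int nvol, int nsh,
                            int k1, int k2, int restrict_axis) {
  const int nx = A.n_rows, ny = A.n_cols;
  cube out(nx, ny, A.n_slices);
  std::vector<mat> pr(nvol), pc(nvol);
  for (int z = 0; z < nz; ++z) {
    Rcpp::checkUserInterrupt();
    for (int v = 0; v < nvol; ++v)
      filter_split(A.slice(z + nz * v), pr[v], pc[v]);

    // rows pass: lines run along rows; bundle row-lines across volumes
    if (restrict_axis == 0 || restrict_axis == 1) {
      mat B(nx, nvol);
      for (int c = 0; c < ny; ++c) {
        for (int v = 0; v < nvol; ++v) B.col(v) = pr[v].col(c);
        mat U = unring_line_bundle(B, nsh, k1, k2);
        for (int v = 0; v < nvol; ++v) out.slice(z + nz * v).col(c) = U.col(v);
      }
    } else {
      for (int v = 0; v < nvol; ++v) out.slice(z + nz * v) = pr[v];
    }
    // columns pass
    if (restrict_axis == 0 || restrict_axis == 2) {
      mat B(ny, nvol);
      for (int r = 0; r < nx; ++r) {
        for (int v = 0; v < nvol; ++v) B.col(v) = pc[v].row(r).t();
        mat U = unring_line_bundle(B, nsh, k1, k2);
        for (int v = 0; v < nvol; ++v)
          out.slice(z + nz * v).row(r) += U.col(v).t();
      }
    } else {
      for (int v = 0; v < nvol; ++v) out.slice(z + nz * v) += pc[v];
    }
  }
  return out;
}
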