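// Marchenko-Pastur PCA denoising cores.
//
// Data layout: signals are passed as an n_vol x n_vox matrix (one column per
// voxel, volumes contiguous) so the bilateral intensity score streams
// column-wise. Patch spectra are computed through the smaller Gram matrix of
// the Casorati block, never an explicit SVD of the full block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct MPResult {
  double sigma2;  // noise variance estimate
  int P;          // retained signal components
};

// eigs: eigenvalues of Gram/M in DESCENDING order (length R = min(M, N)).
// M = rows (patch voxels), N = cols (volumes) of the Casorati block; when
// M < N the roles are swapped by the caller so that always M >= N here in
// the aspect-ratio sense of the criterion.
MPResult mp_criterion(const vec& eigs, int M, double reltol = 1e-12) {
  const int R = eigs.n_elem;
  // suffix means of trailing eigenvalues
  vec csum = cumsum(reverse(eigs));  // csum[i] = sum of smallest i+1
  MPResult res;
  res.sigma2 = eigs(R - 1);
  res.P = R - 1;
  const double tol = eigs(0) * reltol;  // numerically zero spectrum tail
  for (int p = 0; p < R; ++p) {
    const int ntail = R - p;
    const double s2 = csum(ntail - 1) / ntail;
    const double edge = s2 * std::pow(1.0 + std::sqrt((double)ntail / M), 2.0);
    if (eigs(p) <= edge || s2 <= tol) {
      res.sigma2 = s2 <= tol ? 0.0 : s2;
      res.P = p;
      break;
    }
  }
  if (res.sigma2 < 0) res.sigma2 = 0;
  return res;
}

// Optimal Frobenius-loss gain for one normalized singular value y = s/(sigma
// sqrt(M)) at aspect beta = N/M: shrunk singular value is sigma*sqrt(M)*
// sqrt((y^2-beta-1)^2 - 4 beta)/y beyond the bulk edge 1+sqrt(beta), 0 inside.
// Returned as a multiplicative gain on the original singular value.
double shrink_gain(double y, double beta) {
  const double edge = 1.0 + std::sqrt(beta);
  if (y <= edge) return 0.0;
  const double t = y * y - beta - 1.0;
  const double num = t * t - 4.0 * beta;
  if (num <= 0) return 0.0;
  return std::sqrt(num) / (y * y);
}

}  // namespace

// Denoise one Casorati matrix (patch voxels x volumes). Returns both the
// hard-truncated and the shrinkage reconstruction plus sigma and P.
// [[Rcpp::export(name = ".mp_denoise_matrix_cpp")]]
Rcpp::List mp_denoise_matrix_cpp(const arma::mat& X) {
  const int M = X.n_rows, N = X.n_cols;
  if (!X.is_finite()) Rcpp::stop("Casorati matrix contains non-finite values");
  if (std::min(M, N) < 2) Rcpp::stop("Casorati matrix needs both dimensions >= 2");

  const bool wide = (M < N);  // fewer voxels than volumes: use the M x M Gram
  mat G = wide ? mat(X * X.t()) : mat(X.t() * X);
  vec eval;
  mat evec;
  eig_sym(eval, evec, G, "dc");
  eval = reverse(eval) / (wide ? (double)N : (double)M);
  eval.transform([](double v) { return v < 0 ? 0.0 : v; });
  evec = fliplr(evec);

  const int Mb = wide ? N : M;  // long dimension (rows of the tall block)
  const int Nb = wide ? M : N;
  MPResult mp = mp_criterion(eval, Mb);
  const double sigma = std::sqrt(mp.sigma2);
  const double beta = (double)Nb / Mb;

  const int R = eval.n_elem;
  vec gain_tr(R, fill::zeros), gain_sh(R, fill::zeros);
  for (int i = 0; i < R; ++i) {
    if (i < mp.P) gain_tr(i) = 1.0;
    if (sigma <= 0) {
      gain_sh(i) = 1.0;  // noiseless: nothing to shrink
    } else {
      gain_sh(i) = shrink_gain(std::sqrt(eval(i)) / sigma, beta);
    }
  }

  mat Xtr, Xsh;
  if (wide) {
    // evec are eigenvectors of X X' (M x M); X_hat = U g U' X
    mat P1 = evec.each_row() % gain_tr.t();
    mat P2 = evec.each_row() % gain_sh.t();
    mat UtX = evec.t() * X;
    Xtr = P1 * UtX;
    Xsh = P2 * UtX;
  } else {
    // evec are eigenvectors of X'X (N x N); X_hat = X V g V'
    mat XV = X * evec;
    Xtr = (XV.each_row() % gain_tr.t()) * evec.t();
    Xsh = (XV.each_row() % gain_sh.t()) * evec.t();
  }
  return Rcpp::List::create(Rcpp::Named("truncated") = Xtr,
                            Rcpp::Named("shrunk") = Xsh,
                            Rcpp::Named("sigma") = sigma,
                            Rcpp::Named("npars") = mp.P);
}

// Bilateral adaptive-patch selection around one center voxel: candidates are
// in-mask voxels within the search box; the score is the equally weighted sum
// of the max-normalized spatial distance and max-normalized mean absolute
// intensity difference over volumes; ties break on linear voxel index.
// Exposed for direct testing; denoise_volume_cpp repeats the same logic
// inline.
// [[Rcpp::export(name = ".select_adaptive_patch_cpp")]]
arma::uvec select_adaptive_patch_cpp(const arma::mat& S,
                                     const arma::ivec& dims,
                                     const arma::uvec& mask,
                                     const arma::ivec& center,
                                     int patch_size,
                                     int half_window) {
  const int nx = dims(0), ny = dims(1), nz = dims(2);
  const int cx = center(0), cy = center(1), cz = center(2);
  const uword cidx = (uword)(cx + nx * (cy + (long long)ny * cz));
  if (!mask(cidx)) Rcpp::stop("center voxel lies outside the mask");
  const int nvol = S.n_rows;

  std::vector<uword> cand;
  std::vector<double> dist, idiff;
  cand.reserve((2 * half_window + 1) * (2 * half_window + 1) * (2 * half_window + 1));
  const double* sc = S.colptr(cidx);
  for (int z = std::max(0, cz - half_window); z <= std::min(nz - 1, cz + half_window); ++z)
    for (int y = std::max(0, cy - half_window); y <= std::min(ny - 1, cy + half_window); ++y)
      for (int x = std::max(0, cx - half_window); x <= std::min(nx - 1, cx + half_window); ++x) {
        const uword idx = (uword)(x + nx * (y + (long long)ny * z));
        if (!mask(idx)) continue;
        const double* sv = S.colptr(idx);
        double ad = 0;
        for (int v = 0; v < nvol; ++v) ad += std::abs(sv[v] - sc[v]);
        cand.push_back(idx);
        dist.push_back(std::sqrt((double)((x - cx) * (x - cx) + (y - cy) * (y - cy) +
                                          (z - cz) * (z - cz))));
        idiff.push_back(ad / nvol);
      }

  const size_t nc = cand.size();
  double dmax = *std::max_element(dist.begin(), dist.end());
  double imax = *std::max_element(idiff.begin(), idiff.end());
  if (dmax <= 0) dmax = 1.0;
  if (imax <= 0) imax = 1.0;
  std::vector<size_t> ord(nc);
  std::iota(ord.begin(), ord.end(), (size_t)0);
  std::vector<double> score(nc);
  for (size_t i = 0; i < nc; ++i) score[i] = dist[i] / dmax + idiff[i] / imax;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (score[a] != score[b]) return score[a] < score[b];
    return cand[a] < cand[b];
  });

  const size_t take = std::min((size_t)patch_size, nc);
  uvec out(take);
  // center first (its score is minimal on the distance term but possibly tied)
  out(0) = cidx;
  size_t k = 1;
  for (size_t i = 0; i < nc && k < take; ++i) {
    if (cand[ord[i]] == cidx) continue;
    out(k++) = cand[ord[i]];
  }
  return out + 1;  // 1-based for R
}

// Full-volume denoiser. mode 0 = local box patch, 1 = adaptive bilateral.
// Returns truncated and shrunk center-voxel reconstructions for every
// in-mask voxel so both variants come from one spectral decomposition.
// The per-patch spectral work runs in single precision (the estimates are
// statistical; float keeps the patchwise eigendecompositions within the
// runtime of a desk machine); a noise-free patch short-circuits to the
// exact identity.
// [[Rcpp::export(name = ".denoise_volume_cpp")]]
Rcpp::List denoise_volume_cpp(const arma::mat& S,
                              const arma::ivec& dims,
                              const arma::uvec& mask,
                              int mode,
                              int patch_size,
                              int half_window,
                              int local_half) {
  const int nx = dims(0), ny = dims(1), nz = dims(2);
  const uword nvox = S.n_cols;
  const int nvol = S.n_rows;
  const fmat Sf = conv_to<fmat>::from(S);
  mat out_tr(S), out_sh(S);
  vec sigma_map(nvox, fill::zeros);
  ivec np_map(nvox, fill::zeros);

  std::vector<uword> cand;
  std::vector<float> dist, idiff, score;
  std::vector<size_t> ord;

  for (int cz = 0; cz < nz; ++cz) {
    Rcpp::checkUserInterrupt();
    for (int cy = 0; cy < ny; ++cy) {
      for (int cx = 0; cx < nx; ++cx) {
        const uword cidx = (uword)(cx + nx * (cy + (long long)ny * cz));
        if (!mask(cidx)) continue;
        const int hw = (mode == 1) ? half_window : local_half;
        cand.clear();
        dist.clear();
        idiff.clear();
        const float* sc = Sf.colptr(cidx);
        for (int z = std::max(0, cz - hw); z <= std::min(nz - 1, cz + hw); ++z)
          for (int y = std::max(0, cy - hw); y <= std::min(ny - 1, cy + hw); ++y)
            for (int x = std::max(0, cx - hw); x <= std::min(nx - 1, cx + hw); ++x) {
              const uword idx = (uword)(x + nx * (y + (long long)ny * z));
              if (!mask(idx)) continue;
              cand.push_back(idx);
              if (mode == 1) {
                const float* sv = Sf.colptr(idx);
                float ad = 0;
                for (int v = 0; v < nvol; ++v) ad += std::abs(sv[v] - sc[v]);
                dist.push_back(std::sqrt((float)((x - cx) * (x - cx) +
                                                 (y - cy) * (y - cy) +
                                                 (z - cz) * (z - cz))));
                idiff.push_back(ad / nvol);
              }
            }
        size_t nc = cand.size();
        size_t take = nc;
        if (mode == 1) {
          float dmax = *std::max_element(dist.begin(), dist.end());
          float imax = *std::max_element(idiff.begin(), idiff.end());
          if (dmax <= 0) dmax = 1.0f;
          if (imax <= 0) imax = 1.0f;
          score.assign(nc, 0.0f);
          for (size_t i = 0; i < nc; ++i) score[i] = dist[i] / dmax + idiff[i] / imax;
          ord.resize(nc);
          std::iota(ord.begin(), ord.end(), (size_t)0);
          take = std::min((size_t)patch_size, nc);
          std::partial_sort(ord.begin(), ord.begin() + take, ord.end(),
                            [&](size_t a, size_t b) {
                              if (score[a] != score[b]) return score[a] < score[b];
                              return cand[a] < cand[b];
                            });
        } else {
          ord.resize(nc);
          std::iota(ord.begin(), ord.end(), (size_t)0);
        }
        if (take < 2) continue;  // too few voxels: leave center untouched

        // Casorati block, columns gathered contiguously: X2 is volumes x
        // patch voxels, i.e. the transpose of the M x N Casorati matrix
        uvec idxv(take);
        uword ccol = 0;
        for (size_t i = 0; i < take; ++i) {
          uword idx = (mode == 1) ? cand[ord[i]] : cand[i];
          if (idx == cidx) ccol = i;
          idxv(i) = idx;
        }
        fmat X2 = Sf.cols(idxv);  // nvol x take
        // center on the patch-mean signal: the dominant common mode carries
        // no patch-level information and would otherwise set the floating
        // point noise floor of the spectrum
        fvec mu = mean(X2, 1);
        X2.each_col() -= mu;
        const int M = take, N = nvol;
        const bool wide = (M < N);  // fewer patch voxels than volumes
        fmat G = wide ? fmat(X2.t() * X2) : fmat(X2 * X2.t());
        fvec evalf;
        fmat evec;
        if (!eig_sym(evalf, evec, G, "dc")) continue;
        vec eval = conv_to<vec>::from(reverse(evalf)) / (double)std::max(M, N);
        eval.transform([](double v) { return v < 0 ? 0.0 : v; });
        evec = fliplr(evec);
        const int Mb = std::max(M, N), Nb = std::min(M, N);
        MPResult mp = mp_criterion(eval, Mb, 1e-5);
        const double sig = std::sqrt(mp.sigma2);
        np_map(cidx) = mp.P;
        sigma_map(cidx) = sig;
        if (sig <= 0) continue;  // noise-free patch: keep the input exactly
        // reconstructions below act on the centered signals; the patch mean
        // is restored at the end

        const double beta = (double)Nb / Mb;
        const int R = eval.n_elem;
        fvec gain_tr(R, fill::zeros), gain_sh(R, fill::zeros);
        for (int i = 0; i < R; ++i) {
          if (i < mp.P) gain_tr(i) = 1.0f;
          gain_sh(i) = (float)shrink_gain(std::sqrt(eval(i)) / sig, beta);
        }

        fvec xtr, xsh;
        if (wide) {
          // evec: eigenvectors of X X' (M x M); center row of U g U' X
          fvec uc = evec.row(ccol).t();
          xtr = X2 * fvec(evec * (gain_tr % uc));
          xsh = X2 * fvec(evec * (gain_sh % uc));
        } else {
          // evec: eigenvectors of X'X (N x N); x_hat_c = V g V' x_c
          fvec t = evec.t() * X2.col(ccol);
          xtr = evec * (gain_tr % t);
          xsh = evec * (gain_sh % t);
        }
        out_tr.col(cidx) = conv_to<vec>::from(fvec(xtr + mu));
        out_sh.col(cidx) = conv_to<vec>::from(fvec(xsh + mu));
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("truncated") = out_tr,
                            Rcpp::Named("shrunk") = out_sh,
                            Rcpp::Named("sigma") = sigma_map,
                            Rcpp::Named("npars") = np_map);
}
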