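#' @title DTI/DKI design matrix
#'
#' @description Builds the log-linear design matrix for the diffusion
#' kurtosis signal model
#' `ln S = ln S0 - b D(n) + (b^2/6) V(n)` with b internally in ms/um^2 so
#' diffusivities emerge in um^2/ms. The 6 diffusion-tensor columns are
#' `-b * (nx^2, 2 nx ny, 2 nx nz, ny^2, 2 ny nz, nz^2)` (coefficient order
#' xx, xy, xz, yy, yz, zz) and the 15 kurtosis columns carry
#' `(b^2/6)` times the symmetric-tensor monomials with their multiplicities,
#' in lexicographic order (xxxx, xxxy, ..., zzzz). The fitted kurtosis
#' coefficients are therefore `MD^2 * W_ijkl`, so the apparent kurtosis
#' along `n` is `V(n)/D(n)^2` with no further scaling.
#'
#' @param grad a [gradient_table] with b-values in s/mm^2.
#' @param model "dki" (22 columns) or "dti" (7 columns).
#' @return Matrix with one row per volume.
#' @export
build_design_matrix <- function(grad, model = c("dki", "dti")) {
  model <- match.arg(model)
  b <- grad$bvals / 1000  # ms/um^2
  n <- grad$bvecs
  nvol <- length(b)
  shells_dw <- unique(grad$shell_index[b > 0])
  if (model == "dki") {
    if (nvol < 22L)
      stop("a full DKI fit needs at least 22 volumes", call. = FALSE)
    if (length(shells_dw) < 2L)
      stop("a DKI fit needs at least two nonzero shells", call. = FALSE)
  } else if (nvol < 7L) {
    stop("a DTI fit needs at least 7 volumes", call. = FALSE)
  }
  D <- cbind(n[, 1]^2, 2 * n[, 1] * n[, 2], 2 * n[, 1] * n[, 3],
             n[, 2]^2, 2 * n[, 2] * n[, 3], n[, 3]^2)
  A <- cbind(1, -b * D)
  if (model == "dki") {
    K <- kt_monomials(n)
    A <- cbind(A, (b^2 / 6) * K)
  }
  A
}

# 15 kurtosis monomials with symmetric-tensor multiplicities, lexicographic
# component order (xxxx, xxxy, xxxz, xxyy, xxyz, xxzz, xyyy, xyyz, xyzz,
# xzzz, yyyy, yyyz, yyzz, yzzz, zzzz)
kt_powers <- cbind(
  px = c(4, 3, 3, 2, 2, 2, 1, 1, 1, 1, 0, 0, 0, 0, 0),
  py = c(0, 1, 0, 2, 1, 0, 3, 2, 1, 0, 4, 3, 2, 1, 0),
  pz = c(0, 0, 1, 0, 1, 2, 0, 1, 2, 3, 0, 1, 2, 3, 4))
kt_mult <- c(1, 4, 4, 6, 12, 6, 4, 12, 12, 4, 1, 4, 6, 4, 1)

kt_monomials <- function(n) {
  out <- matrix(0, nrow(n), 15L)
  for (c in seq_len(15L))
    out[, c] <- kt_mult[c] * n[, 1]^kt_powers[c, 1] * n[, 2]^kt_powers[c, 2] *
      n[, 3]^kt_powers[c, 3]
  out
}

# quadratic/quartic forms for a single tensor pair (used by the phantom
# generators); dirs is n x 3
dt_form_dirs <- function(dt, dirs) {
  dirs[, 1]^2 * dt[1] + dirs[, 2]^2 * dt[4] + dirs[, 3]^2 * dt[6] +
    2 * (dirs[, 1] * dirs[, 2] * dt[2] + dirs[, 1] * dirs[, 3] * dt[3] +
           dirs[, 2] * dirs[, 3] * dt[5])
}

kt_form_dirs <- function(kt, dirs) {
  drop(kt_monomials(dirs) %*% kt)
}

#' Weighted linear least-squares DTI/DKI fit
#'
#' Two-pass fit on log-signals: an unweighted solve initializes predicted
#' signals, then each row is re-weighted by its squared predicted signal.
#' Signals are floored at `1e-8` times the voxel's mean b = 0 signal before
#' the log; voxels with non-positive or non-finite raw signal are flagged in
#' `fit_ok` (not dropped). No positivity constraints and no outlier
#' rejection are applied during fitting.
#'
#' @param vol a [dwi_volume].
#' @param mask optional 3D logical mask (defaults to the volume's mask).
#' @param model "dki" or "dti".
#' @param method "wlls" (two-pass, default) or "lls" (single unweighted
#'   pass, mainly for comparison).
#' @return An object of class `tensor_fit`: `coef` (n_coef x n_vox matrix:
#'   lnS0, 6 dt, 15 kt), `fit_ok`, `dims`, `mask`, `model`, `voxel_size`.
#' @export
wlls_fit <- function(vol, mask = NULL, model = c("dki", "dti"),
                     method = c("wlls", "lls")) {
  stopifnot(inherits(vol, "dwi_volume"))
  model <- match.arg(model)
  method <- match.arg(method)
  A <- build_design_matrix(vol$grad, model)
  d <- dim(vol$data)
  if (is.null(mask)) mask <- vol_mask(vol)
  S <- flat_signal(vol)
  b0idx <- which(vol$grad$bvals == 0)
  if (!length(b0idx)) b0idx <- which.min(vol$grad$bvals)
  res <- .wlls_fit_cpp(S, A, as.logical(mask), as.integer(b0idx), 1e-8,
                       method == "wlls")
  structure(list(coef = res$coef, fit_ok = array(res$fit_ok == 1, d[1:3]),
                 dims = d[1:3], mask = array(as.logical(mask), d[1:3]),
                 model = model, voxel_size = vol$voxel_size),
            class = "tensor_fit")
}

# 512-point spherical product quadrature for MK: 16-node Gauss-Legendre in
# cos(theta) x 32 uniform azimuths. Exponentially convergent for the smooth
# directional-kurtosis integrand; rotation-equivariant to ~1e-8 for
# physiological tensors, far inside the documented 1e-3 MK tolerance.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

mk_direction_set <- function(n_theta = 16L, n_phi = 32L) {
  q <- gauss_legendre(n_theta)
  ct <- q$nodes
  st <- sqrt(pmax(1 - ct^2, 0))
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  dirs <- matrix(0, 3, n_theta * n_phi)
  wts <- numeric(n_theta * n_phi)
  k <- 1L
  for (i in seq_len(n_theta)) {
    for (j in seq_len(n_phi)) {
      dirs[, k] <- c(st[i] * cos(phi[j]), st[i] * sin(phi[j]), ct[i])
      wts[k] <- q$weights[i] / 2 / n_phi
      k <- k + 1L
    }
  }
  list(dirs = dirs, wts = wts)
}

#' Scalar maps from a tensor fit
#'
#' Eigen-decomposes the diffusion tensor per voxel (eigenvalues descending)
#' and derives MD (mean eigenvalue), AD (largest), RD (mean of the two
#' smallest), FA (standard closed form), AK (apparent kurtosis along the
#' principal axis, analytic), RK (apparent kurtosis averaged over 64 equally
#' spaced directions in the radial plane) and MK (weighted average over a
#' 512-point spherical product quadrature). Voxels with non-finite
#' coefficients are emitted as `NaN` and flagged invalid.
#'
#' @param fit a [wlls_fit()] result with `model = "dki"`.
#' @return An object of class `scalar_maps`: 3D arrays `MD`, `AD`, `RD`
#'   (um^2/ms), `FA`, `MK`, `AK`, `RK` (dimensionless) and logical `valid`.
#' @export
scalar_maps <- function(fit) {
  stopifnot(inherits(fit, "tensor_fit"))
  if (fit$model != "dki")
    stop("scalar_maps needs a DKI fit (kurtosis coefficients)", call. = FALSE)
  q <- mk_direction_set()
  res <- .scalar_maps_cpp(fit$coef, as.logical(fit$mask), q$dirs, q$wts, 64L)
  out <- lapply(res[c("MD", "AD", "RD", "FA", "MK", "AK", "RK")],
                function(v) array(v, fit$dims))
  out$valid <- array(res$valid == 1, fit$dims)
  class(out) <- "scalar_maps"
  out
}

scalar_names <- c("MD", "AD", "RD", "FA", "MK", "AK", "RK")

#' Physical-bounds outlier specification
#'
#' Diffusivities must be positive, FA must lie strictly in (0, 1), and
#' kurtosis must exceed -2. No upper diffusivity bound is applied.
#'
#' @param d_lo,fa_lo,fa_hi,k_lo the bounds.
#' @return An object of class `outlier_spec`.
#' @export
outlier_spec <- function(d_lo = 0, fa_lo = 0, fa_hi = 1, k_lo = -2) {
  structure(list(d_lo = d_lo, fa_lo = fa_lo, fa_hi = fa_hi, k_lo = k_lo),
            class = "outlier_spec")
}

# logical violation map for one named scalar
outlier_flags <- function(values, name, spec = outlier_spec()) {
  v <- switch(name,
              MD = , AD = , RD = !(values > spec$d_lo),
              FA = !(values > spec$fa_lo & values < spec$fa_hi),
              MK = , AK = , RK = !(values > spec$k_lo),
              stop("unknown scalar ", name))
  v | !is.finite(values)
}

#' Percent physically implausible voxels per scalar map
#'
#' For each of the seven maps, `100 * outliers in ROI / voxels in ROI`, plus
#' the average across maps. Non-finite voxels count as outliers.
#'
#' @param maps a [scalar_maps()] result.
#' @param roi 3D logical region of interest (non-empty).
#' @param spec an [outlier_spec()].
#' @return List with `per_map` (named percentages) and `average`.
#' @export
outlier_stats <- function(maps, roi, spec = outlier_spec()) {
  roi <- as.logical(roi)
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  n <- sum(roi)
  per <- vapply(scalar_names, function(nm)
    100 * sum(outlier_flags(maps[[nm]][roi], nm, spec)) / n, numeric(1))
  list(per_map = per, average = mean(per))
}
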