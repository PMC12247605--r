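#' Patch specification for MPPCA denoising
#'
#' Local mode assembles a fixed box around each voxel (default 5x5x5);
#' adaptive mode pools a bilateral selection of the `patch_size` most similar
#' voxels (small spatial distance, small mean absolute intensity difference
#' over all volumes) inside a search window.
#'
#' @param mode "adaptive" or "local".
#' @param patch_size voxel count per patch in adaptive mode (default 100).
#'   At least 2; at least half the number of volumes is recommended.
#' @param search_window half-width in voxels of the adaptive candidate box
#'   (default 7).
#' @param local_half half-width of the local box (default 2, i.e. 5x5x5).
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(mode = c("adaptive", "local"), patch_size = 100,
                       search_window = 7, local_half = 2) {
  mode <- match.arg(mode)
  if (patch_size < 2) stop("patch_size must be at least 2", call. = FALSE)
  structure(list(mode = mode, patch_size = as.integer(patch_size),
                 search_window = as.integer(search_window),
                 local_half = as.integer(local_half)),
            class = "patch_spec")
}

#' Bilateral adaptive patch selection
#'
#' Ranks all in-mask voxels inside the search window by the equally weighted
#' sum of max-normalized spatial distance to the center and max-normalized
#' mean absolute signal difference over volumes; ties break on linear voxel
#' index. The center voxel is always first.
#'
#' @param vol a [dwi_volume] (its mask is used if present) or 4D array.
#' @param center length-3 integer voxel index (1-based).
#' @param spec a [patch_spec] in adaptive mode.
#' @return Integer matrix (`patch_size` x 3) of 1-based voxel indices.
#' @export
select_adaptive_patch <- function(vol, center, spec = patch_spec()) {
  if (inherits(vol, "dwi_volume")) {
    S <- flat_signal(vol)
    dims <- dim(vol$data)[1:3]
    mask <- vol_mask(vol)
  } else {
    d <- dim(vol)
    S <- t(matrix(vol, prod(d[1:3]), d[4L]))
    dims <- d[1:3]
    mask <- array(TRUE, dims)
  }
  idx <- .select_adaptive_patch_cpp(S, as.integer(dims), as.logical(mask),
                                    as.integer(center) - 1L,
                                    spec$patch_size, spec$search_window)
  arrayInd(as.integer(idx), dims)
}

#' Denoise a single Casorati matrix by the Marchenko-Pastur criterion
#'
#' Estimates the noise level and number of signal components from the
#' eigenvalue spectrum: the smallest leading count P is chosen such that the
#' trailing eigenvalues of the patch covariance are consistent with a
#' Marchenko-Pastur bulk (their mean gives the noise variance, and the next
#' eigenvalue lies below the corresponding bulk edge). With `shrink = FALSE`
#' components beyond P are discarded; with `shrink = TRUE` every singular
#' value is passed through the optimal Frobenius-loss shrinker at the
#' matrix's aspect ratio.
#'
#' @param X Casorati matrix, patch voxels x volumes (both dimensions >= 2).
#' @param shrink logical; use singular-value shrinkage instead of hard
#'   truncation.
#' @return List with `X_hat` (denoised matrix), `sigma` (noise standard
#'   deviation) and `npars` (retained components P).
#' @export
mp_denoise_matrix <- function(X, shrink = FALSE) {
  res <- .mp_denoise_matrix_cpp(as.matrix(X))
  list(X_hat = if (shrink) res$shrunk else res$truncated,
       sigma = res$sigma, npars = res$npars)
}

#' MPPCA denoising of a 4D diffusion volume
#'
#' Every in-mask voxel is denoised from the Casorati matrix of its patch;
#' the value written back at a voxel comes from the patch centered on it.
#' Alongside the denoised series, per-voxel noise level and retained
#' component maps are returned.
#'
#' @param vol a [dwi_volume].
#' @param spec a [patch_spec].
#' @param shrink logical; singular-value shrinkage instead of hard truncation.
#' @return An object of class `denoise_result`: list with `denoised`
#'   ([dwi_volume]), `sigma_map` (3D array) and `ncomponents_map` (3D
#'   integer array).
#' @export
denoise_volume <- function(vol, spec = patch_spec(), shrink = FALSE) {
  res <- denoise_volume_dual(vol, spec)
  out <- if (shrink) res$shrunk else res$truncated
  structure(list(denoised = out, sigma_map = res$sigma_map,
                 ncomponents_map = res$ncomponents_map),
            class = "denoise_result")
}

# One spectral pass, both reconstructions: the hard-truncated and the
# shrinkage estimate share the patch selection and eigendecomposition.
denoise_volume_dual <- function(vol, spec = patch_spec()) {
  stopifnot(inherits(vol, "dwi_volume"))
  d <- dim(vol$data)
  if (d[4L] < 8L)
    warning("fewer than 8 volumes: Marchenko-Pastur noise estimate is unreliable")
  mask <- vol_mask(vol)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  S <- flat_signal(vol)
  res <- .denoise_volume_cpp(S, as.integer(d[1:3]), as.logical(mask),
                             if (spec$mode == "adaptive") 1L else 0L,
                             spec$patch_size, spec$search_window,
                             spec$local_half)
  rewrap <- function(m) {
    v <- vol
    v$data <- array(t(m), dim = d)
    v$data[v$data < 0] <- 0  # reconstructions can slightly undershoot zero
    v
  }
  list(truncated = rewrap(res$truncated), shrunk = rewrap(res$shrunk),
       sigma_map = array(res$sigma, dim = d[1:3]),
       ncomponents_map = array(as.integer(res$npars), dim = d[1:3]))
}

#' Method-of-moments Rician bias correction
#'
#' Corrected magnitude is `sqrt(max(M^2 - sigma^2, 0))` per voxel and volume,
#' using the denoiser's noise map. Exact for the second moment up to the
#' Rician noise floor; leaves the signal unchanged where `sigma = 0`.
#'
#' @param denoised 4D array or [dwi_volume] of magnitudes.
#' @param sigma_map 3D array of noise standard deviations (>= 0).
#' @return Same type as `denoised`.
#' @export
rician_bias_correct <- function(denoised, sigma_map) {
  if (any(sigma_map < 0)) stop("sigma_map must be non-negative", call. = FALSE)
  is_vol <- inherits(denoised, "dwi_volume")
  arr <- if (is_vol) denoised$data else denoised
  d <- dim(arr)
  if (!all(dim(sigma_map) == d[1:3]))
    stop("sigma_map does not match the image grid", call. = FALSE)
  out <- sqrt(pmax(arr^2 - c(sigma_map)^2, 0))
  dim(out) <- d
  if (is_vol) {
    denoised$data <- out
    denoised
  } else out
}
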