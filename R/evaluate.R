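#' Signed voxelwise percentage error
#'
#' `100 * (estimate - truth) / truth`; voxels with zero truth are flagged
#' `NA` (invalid).
#'
#' @param estimate,truth 3D maps of matching shape.
#' @return 3D map in percent.
#' @export
percent_error_map <- function(estimate, truth) {
  if (!all(dim(estimate) == dim(truth)))
    stop("estimate and truth shapes differ", call. = FALSE)
  out <- 100 * (estimate - truth) / truth
  out[truth == 0] <- NA_real_
  out
}

#' Voxelwise median over noise realizations
#'
#' The median (not the mean) is used across realizations so single-outlier
#' voxels at low SNR do not dominate the aggregated map. `NA` voxels are
#' excluded voxelwise.
#'
#' @param maps non-empty list of 3D maps with identical shapes.
#' @return 3D map.
#' @export
median_over_realizations <- function(maps) {
  if (!length(maps)) stop("no maps supplied", call. = FALSE)
  d <- dim(maps[[1]])
  m <- vapply(maps, function(x) {
    if (!all(dim(x) == d)) stop("map shapes differ", call. = FALSE)
    as.numeric(x)
  }, numeric(prod(d)))
  array(row_medians(m), dim = d)
}

# rowwise median of a matrix, NA-excluding
row_medians <- function(m) {
  if (is.null(dim(m))) return(median(m, na.rm = TRUE))
  apply(m, 1L, median, na.rm = TRUE)
}

# --- separable Gaussian smoothing -------------------------------------------

gauss_kernel_matrix <- function(n, sigma_vox, truncate_sd = 4) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(truncate_sd * sigma_vox))
  off <- -r:r
  k <- exp(-off^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (d in seq_along(off)) {
    j <- seq_len(n) + off[d]
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + k[d]
  }
  K
}

# separable convolution of a 3D array (zero boundary)
conv3_sep <- function(arr, sigma_vox, truncate_sd = 4) {
  d <- dim(arr)
  for (ax in 1:3) {
    K <- gauss_kernel_matrix(d[ax], sigma_vox[ax], truncate_sd)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), d[ax])
    arr <- aperm(array(K %*% m, d[perm]), order(perm))
  }
  arr
}

#' CSF-excluded Gaussian smoothing
#'
#' Per-volume 3D Gaussian smoothing with FWHM equal to `fwhm_factor` times
#' the voxel size along each axis, as normalized masked convolution: CSF
#' voxels neither contribute weight nor receive smoothed values (they pass
#' through unchanged), and the renormalization prevents weight leakage at
#' CSF and image borders.
#'
#' @param vol a [dwi_volume] or 4D array.
#' @param fwhm_factor FWHM as a multiple of the voxel size (default 1.2).
#' @param csf_mask optional 3D logical mask of voxels to exclude.
#' @return Same type as `vol`.
#' @export
gaussian_smooth_csf_excluded <- function(vol, fwhm_factor = 1.2,
                                         csf_mask = NULL) {
  if (fwhm_factor <= 0) stop("fwhm_factor must be positive", call. = FALSE)
  is_vol <- inherits(vol, "dwi_volume")
  arr <- if (is_vol) vol$data else vol
  d <- dim(arr)
  sigma <- rep(fwhm_factor / (2 * sqrt(2 * log(2))), 3)  # voxel units
  w <- if (is.null(csf_mask)) array(1, d[1:3]) else array(as.numeric(!csf_mask), d[1:3])
  ws <- conv3_sep(w, sigma)
  out <- arr
  keep <- w > 0 & ws > 1e-12
  for (vv in seq_len(d[4])) {
    sl <- arr[, , , vv, drop = FALSE]
    dim(sl) <- d[1:3]
    num <- conv3_sep(sl * w, sigma)
    sm <- sl
    sm[keep] <- num[keep] / ws[keep]
    out[, , , vv] <- sm
  }
  if (is_vol) {
    vol$data <- out
    vol
  } else out
}

#' Quadratic fit of a parameter against age
#'
#' Ordinary least-squares fit of `y = a x^2 + b x + c` with adjusted R^2,
#' the overall-model F-test p-value versus intercept-only, a Bonferroni
#' correction (x 28: 7 parameters x 4 ROIs, capped at 1), and the vertex
#' classification: concave/convex with the inflection age when the vertex
#' lies inside the fitted age range, otherwise monotone increasing or
#' decreasing.
#'
#' @param ages ages in years (>= 4 points, not all equal).
#' @param values parameter medians, same length.
#' @param age_range range used for the vertex classification (default 25-75).
#' @param n_comparisons Bonferroni multiplier (default 28).
#' @return An object of class `quadratic_fit` with `coefficients` (a, b, c),
#'   `adjusted_r2`, `p_value`, `bonferroni_p`, `concavity`, `inflection_age`.
#' @export
quadratic_age_fit <- function(ages, values, age_range = c(25, 75),
                              n_comparisons = 28) {
  if (length(ages) < 4L) stop("need at least 4 points", call. = FALSE)
  if (length(unique(ages)) < 3L)
    stop("degenerate design: ages do not span a quadratic", call. = FALSE)
  fit <- lm(values ~ ages + I(ages^2))
  cf <- coef(fit)
  a <- unname(cf[3]); b <- unname(cf[2]); cc <- unname(cf[1])
  sm <- suppressWarnings(summary(fit))  # exact fits are handled below
  adj <- sm$adj.r.squared
  if (!is.null(sm$fstatistic) && is.finite(sm$fstatistic[1])) {
    p <- unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                   lower.tail = FALSE))
  } else {
    # zero residual variance: the model is exact
    p <- 0
    adj <- 1
  }
  vertex <- if (a != 0) -b / (2 * a) else Inf
  inside <- is.finite(vertex) && vertex >= age_range[1] && vertex <= age_range[2]
  if (inside) {
    concavity <- if (a < 0) "concave" else "convex"
    inflection <- vertex
  } else {
    mid <- mean(age_range)
    concavity <- if (2 * a * mid + b >= 0) "monotone-increasing" else "monotone-decreasing"
    inflection <- NA_real_
  }
  structure(list(coefficients = c(a = a, b = b, c = cc),
                 adjusted_r2 = adj, p_value = p,
                 bonferroni_p = min(1, p * n_comparisons),
                 concavity = concavity, inflection_age = inflection),
            class = "quadratic_fit")
}

# ground-truth scalar maps straight from the voxelwise truth coefficients
# (per-region assignments when the phantom carries no voxelwise texture)
truth_scalar_maps <- function(phantom) {
  lab <- phantom$region_labels
  d <- dim(lab)
  if (!is.null(phantom$coef_true)) {
    B <- phantom$coef_true
  } else {
    B <- matrix(NA_real_, 22L, prod(d))
    for (r in seq_along(phantom$region_params)) {
      sel <- which(lab == r)
      if (length(sel)) B[, sel] <- region_coef(phantom$region_params[[r]])
    }
  }
  fit <- structure(list(coef = B, fit_ok = lab > 0L, dims = d,
                        mask = lab > 0L, model = "dki",
                        voxel_size = phantom$truth$voxel_size),
                   class = "tensor_fit")
  scalar_maps(fit)
}

# fit + scalar maps in one call
fit_scalars <- function(vol, mask) scalar_maps(wlls_fit(vol, mask = mask))

denoise_condition_names <- c("none", "smooth", "dv1", "dv2", "dv2_noshrink",
                             "dv2_norician")

#' Denoising benchmark on the multi-shell noise phantom
#'
#' For each SNR and preprocessing condition, adds Rician noise to the
#' phantom (fixed per-realization seeds), applies the condition, fits DKI by
#' WLLS, and aggregates: the WM-ROI median of the voxelwise
#' median-over-realizations percentage-error map per scalar, and the
#' percent physically implausible voxels in WM (per map and averaged across
#' the seven maps, averaged over realizations). Conditions: `none` (no
#' correction), `smooth` (CSF-excluded Gaussian smoothing), `dv1` (local
#' patch MPPCA + Rician correction), `dv2` (adaptive patch + shrinkage +
#' Rician), `dv2_noshrink` (adaptive, hard truncation + Rician),
#' `dv2_norician` (adaptive + shrinkage only). The three adaptive variants
#' share one spectral decomposition per realization.
#'
#' @param phantom a [make_multishell_phantom()] result.
#' @param snrs SNR levels (default the full grid 10-60).
#' @param conditions subset of the condition names above.
#' @param nreps noise realizations per SNR.
#' @param seed base seed; realization seeds derive deterministically.
#' @param spec adaptive [patch_spec()] for the dv2 conditions.
#' @param fwhm_factor smoothing kernel FWHM in voxel units.
#' @param verbose print progress.
#' @return `data.frame` with columns condition, snr, scalar, roi,
#'   median_pct_error, outlier_pct; the scalar `"average"` row carries the
#'   across-maps average outlier percentage.
#' @export
run_denoise_benchmark <- function(phantom = make_multishell_phantom(),
                                  snrs = c(10, 15, 20, 25, 30, 60),
                                  conditions = denoise_condition_names,
                                  nreps = 50, seed = 1,
                                  spec = patch_spec(),
                                  fwhm_factor = 1.2, verbose = FALSE) {
  bad <- setdiff(conditions, denoise_condition_names)
  if (length(bad)) stop("unknown condition: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  mask <- vol_mask(phantom$truth)
  inm <- which(mask)
  wm_in <- phantom$wm_mask[mask]
  tm <- truth_scalar_maps(phantom)
  truth_in <- vapply(scalar_names, function(nm) tm[[nm]][inm], numeric(length(inm)))
  need_adapt <- any(c("dv2", "dv2_noshrink", "dv2_norician") %in% conditions)

  rows <- list()
  for (si in seq_along(snrs)) {
    snr <- snrs[si]
    sigma <- phantom_sigma(phantom, snr)
    vals <- lapply(conditions, function(cn)
      array(NA_real_, c(length(inm), 7L, nreps)))
    names(vals) <- conditions
    out_avg <- matrix(NA_real_, nreps, length(conditions),
                      dimnames = list(NULL, conditions))
    out_map <- array(NA_real_, c(nreps, 7L, length(conditions)),
                     dimnames = list(NULL, scalar_names, conditions))
    for (rep in seq_len(nreps)) {
      rseed <- (seed + 7919L * (si - 1L) + rep) %% 2147483647L
      noisy <- add_rician_noise(phantom, noise_model(snr, sigma, rseed))
      dual <- if (need_adapt) denoise_volume_dual(noisy, spec) else NULL
      for (cn in conditions) {
        sm <- switch(cn,
          none = fit_scalars(noisy, mask),
          smooth = fit_scalars(gaussian_smooth_csf_excluded(
            noisy, fwhm_factor, phantom$csf_mask), mask),
          dv1 = {
            dn <- denoise_volume(noisy, patch_spec("local"), shrink = FALSE)
            fit_scalars(rician_bias_correct(dn$denoised, dn$sigma_map), mask)
          },
          dv2 = fit_scalars(rician_bias_correct(dual$shrunk, dual$sigma_map), mask),
          dv2_noshrink = fit_scalars(rician_bias_correct(dual$truncated,
                                                         dual$sigma_map), mask),
          dv2_norician = fit_scalars(dual$shrunk, mask))
        for (p in seq_len(7L)) vals[[cn]][, p, rep] <- sm[[scalar_names[p]]][inm]
        os <- outlier_stats(sm, phantom$wm_mask)
        out_avg[rep, cn] <- os$average
        out_map[rep, , cn] <- os$per_map
      }
      if (verbose)
        message(sprintf("snr %g rep %d/%d done", snr, rep, nreps))
    }
    for (cn in conditions) {
      for (p in seq_len(7L)) {
        med <- row_medians(vals[[cn]][, p, , drop = TRUE])
        err <- 100 * (med - truth_in[, p]) / truth_in[, p]
        err[truth_in[, p] == 0] <- NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cn, snr = snr, scalar = scalar_names[p], roi = "WM",
          median_pct_error = median(err[wm_in], na.rm = TRUE),
          outlier_pct = mean(out_map[, p, cn]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cn, snr = snr, scalar = "average", roi = "WM",
        median_pct_error = NA_real_, outlier_pct = mean(out_avg[, cn]))
    }
  }
  do.call(rbind, rows)
}

#' Gibbs-removal benchmark on the Shepp-Logan diffusion phantom
#'
#' Fits DKI on the ringing-corrupted phantom with no correction, with
#' subvoxel-shift (SuShi) correction, and with the partial-Fourier (RPG)
#' correction, and reports the mean absolute percentage error against the
#' clean truth per ringing ROI and scalar. Deterministic (no noise is
#' added).
#'
#' @param resolution in-plane grid size.
#' @param protocol a [gradient_table].
#' @param pf_fraction partial-Fourier fraction of the simulated acquisition.
#' @param params an [unring_params] (its `pf_fraction`/`pe_axis` are set
#'   from the phantom).
#' @param conditions subset of `c("none", "sushi", "rpg")`.
#' @return `data.frame` with columns condition, roi, scalar,
#'   mean_abs_pct_error.
#' @export
run_gibbs_benchmark <- function(resolution = 128,
                                protocol = default_protocol(),
                                pf_fraction = 6 / 8,
                                params = unring_params(),
                                conditions = c("none", "sushi", "rpg")) {
  bad <- setdiff(conditions, c("none", "sushi", "rpg"))
  if (length(bad)) stop("unknown condition: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  ph <- make_shepp_logan_dmri(resolution, protocol, pf_fraction)
  if (!length(ph$ringing_rois)) stop("ringing ROIs missing", call. = FALSE)
  params$pf_fraction <- pf_fraction
  params$pe_axis <- ph$ringing$pe_axis
  mask <- vol_mask(ph$ringing)
  tm <- truth_scalar_maps(ph$clean)

  corrected <- list()
  for (cn in conditions) {
    v <- ph$ringing
    if (cn == "sushi") v$data <- pmax(sushi_unring(v$data, params), 0)
    if (cn == "rpg") v$data <- pmax(rpg_unring(v$data, params), 0)
    corrected[[cn]] <- fit_scalars(v, mask)
  }

  rows <- list()
  for (cn in conditions) {
    for (ri in seq_along(ph$ringing_rois)) {
      roi <- ph$ringing_rois[[ri]]
      for (nm in scalar_names) {
        err <- percent_error_map(corrected[[cn]][[nm]], tm[[nm]])
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cn, roi = names(ph$ringing_rois)[ri], scalar = nm,
          mean_abs_pct_error = mean(abs(err[roi]), na.rm = TRUE))
      }
    }
  }
  do.call(rbind, rows)
}
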