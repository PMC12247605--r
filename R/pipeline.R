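canonical_steps <- c("denoise", "degibbs", "external_hook", "b0_normalize",
                     "rician", "smooth", "fit")

#' Pipeline configuration
#'
#' Assembles the ordered step list and options for [run_pipeline()]. Steps
#' must appear in the canonical order: denoise, degibbs, external hook
#' (EPI-distortion / eddy / motion tools run outside this package),
#' b0 normalization, Rician bias correction, optional smoothing, fit.
#'
#' Presets: `"none"` (fit only), `"em"` (hook + b0 normalization + fit),
#' `"em-smooth"` (em + CSF-excluded smoothing), `"dv1"` (local-patch MPPCA,
#' subvoxel-shift Gibbs removal, Rician correction), `"dv2"` (adaptive-patch
#' MPPCA with shrinkage, partial-Fourier-aware Gibbs removal, Rician
#' correction).
#'
#' @param preset one of "none", "em", "em-smooth", "dv1", "dv2"; ignored
#'   when `steps` is given explicitly.
#' @param steps explicit ordered subset of the canonical steps.
#' @param denoise_mode,shrinkage,patch_size denoiser options.
#' @param pf_fraction,pe_axis Gibbs-removal geometry; with `pf_fraction < 1`
#'   the degibbs step runs the partial-Fourier (RPG) corrector, otherwise
#'   plain subvoxel shifts. `degibbs_method = "sushi"` forces the plain
#'   corrector (the v1 behavior).
#' @param degibbs_method "auto" or "sushi".
#' @param fwhm_factor smoothing FWHM in voxel units (smooth step).
#' @param csf_mask optional 3D mask excluded from smoothing.
#' @param external_hook optional `function(dwi_volume) -> dwi_volume`.
#' @param outdir optional output directory for intermediates and the report.
#' @param seed integer recorded in the provenance report.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("dv2", "dv1", "em", "em-smooth", "none"),
                            steps = NULL, denoise_mode = NULL,
                            shrinkage = NULL, patch_size = 100,
                            pf_fraction = 1, pe_axis = 2L,
                            degibbs_method = c("auto", "sushi"),
                            fwhm_factor = 1.2, csf_mask = NULL,
                            external_hook = NULL, outdir = NULL, seed = 1L) {
  preset <- match.arg(preset)
  degibbs_method <- match.arg(degibbs_method)
  if (is.null(steps)) {
    steps <- switch(preset,
      none = "fit",
      em = c("external_hook", "b0_normalize", "fit"),
      `em-smooth` = c("external_hook", "b0_normalize", "smooth", "fit"),
      dv1 = c("denoise", "degibbs", "external_hook", "b0_normalize",
              "rician", "fit"),
      dv2 = c("denoise", "degibbs", "external_hook", "b0_normalize",
              "rician", "fit"))
    if (preset == "dv1") {
      if (is.null(denoise_mode)) denoise_mode <- "local"
      if (is.null(shrinkage)) shrinkage <- FALSE
      degibbs_method <- "sushi"
    }
  }
  if (is.null(denoise_mode)) denoise_mode <- "adaptive"
  if (is.null(shrinkage)) shrinkage <- TRUE
  bad <- setdiff(steps, canonical_steps)
  if (length(bad))
    stop("unknown step: ", paste(bad, collapse = ", "), call. = FALSE)
  pos <- match(steps, canonical_steps)
  if (any(diff(pos) <= 0))
    stop("steps violate the canonical order (",
         paste(canonical_steps, collapse = " -> "), ")", call. = FALSE)
  structure(list(preset = preset, steps = steps, denoise_mode = denoise_mode,
                 shrinkage = shrinkage, patch_size = patch_size,
                 pf_fraction = pf_fraction, pe_axis = as.integer(pe_axis),
                 degibbs_method = degibbs_method, fwhm_factor = fwhm_factor,
                 csf_mask = csf_mask, external_hook = external_hook,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Two-series b0 normalization
#'
#' Rescales the second series onto the first: the mean b = 0 image of each
#' series is Gaussian-smoothed (isotropic kernel, default 3 mm standard
#' deviation, truncated at 4 sigma) and every volume of series B is
#' multiplied voxelwise by the ratio smoothed-b0(A) / smoothed-b0(B). The
#' two series are then concatenated with a merged gradient table. Voxels
#' where the smoothed series-B b0 is (near) zero keep a unit scale and are
#' reported in the `flagged` attribute.
#'
#' @param series_a,series_b [dwi_volume]s on the same grid, each with at
#'   least one b = 0 volume.
#' @param sd_mm kernel standard deviation in mm.
#' @param truncate_sd kernel truncation radius in standard deviations.
#' @return Concatenated [dwi_volume] (geometry of `series_a`).
#' @export
b0_normalize <- function(series_a, series_b, sd_mm = 3, truncate_sd = 4) {
  stopifnot(inherits(series_a, "dwi_volume"), inherits(series_b, "dwi_volume"))
  if (!all(dim(series_a$data)[1:3] == dim(series_b$data)[1:3]))
    stop("series grids differ", call. = FALSE)
  b0a <- which(series_a$grad$bvals == 0)
  b0b <- which(series_b$grad$bvals == 0)
  if (!length(b0a) || !length(b0b))
    stop("both series need at least one b = 0 volume", call. = FALSE)
  d <- dim(series_a$data)[1:3]
  mean_b0 <- function(vol, idx) {
    m <- vol$data[, , , idx, drop = FALSE]
    array(apply(m, 1:3, mean), d)
  }
  sig_vox <- sd_mm / series_a$voxel_size
  sa <- conv3_sep(mean_b0(series_a, b0a), sig_vox, truncate_sd)
  sb <- conv3_sep(mean_b0(series_b, b0b), sig_vox, truncate_sd)
  eps <- 1e-8 * max(sa)
  bad <- sb <= eps
  scale <- array(1, d)
  scale[!bad] <- sa[!bad] / sb[!bad]
  db <- series_b$data * c(scale)
  out <- dwi_volume(abind4(series_a$data, db),
                    grad = gradient_table(
                      c(series_a$grad$bvals, series_b$grad$bvals),
                      rbind(series_a$grad$bvecs, series_b$grad$bvecs)),
                    voxel_size = series_a$voxel_size,
                    pf_fraction = series_a$pf_fraction,
                    pe_axis = series_a$pe_axis, mask = series_a$mask)
  mask <- vol_mask(series_a)
  attr(out, "flagged") <- bad & mask
  attr(out, "scale_map") <- scale
  out
}

# bind two 4D arrays along the volume axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

#' Run the preprocessing pipeline end-to-end
#'
#' Executes the enabled steps in canonical order — MPPCA denoising, Gibbs
#' removal (partial-Fourier-aware when `pf_fraction < 1`), the external
#' distortion/motion hook, two-series b0 normalization, Rician bias
#' correction, optional smoothing — then fits DKI and derives the scalar
#' maps. A machine-readable provenance report records the executed order,
#' parameters, seed and package version. Deterministic for a fixed
#' configuration and seed.
#'
#' @param vol a [dwi_volume]; with b0 normalization enabled, the first
#'   series.
#' @param config a [pipeline_config()].
#' @param vol2 second series, required iff `b0_normalize` is enabled.
#' @return List with `preprocessed` ([dwi_volume]), `maps`
#'   ([scalar_maps()]), `sigma_map`, `fit` and `report`.
#' @export
run_pipeline <- function(vol, config = pipeline_config(), vol2 = NULL) {
  stopifnot(inherits(vol, "dwi_volume"), inherits(config, "pipeline_config"))
  two <- "b0_normalize" %in% config$steps
  if (two && is.null(vol2))
    stop("b0_normalize requires a second series", call. = FALSE)
  series <- if (two) list(vol, vol2) else list(vol)
  sigma_map <- NULL
  executed <- character(0)

  if ("denoise" %in% config$steps) {
    spec <- patch_spec(config$denoise_mode, patch_size = config$patch_size)
    sig <- vector("list", length(series))
    for (i in seq_along(series)) {
      dn <- denoise_volume(series[[i]], spec, shrink = config$shrinkage)
      series[[i]] <- dn$denoised
      sig[[i]] <- dn$sigma_map
    }
    sigma_map <- Reduce(`+`, sig) / length(sig)
    executed <- c(executed, "denoise")
  }
  if ("degibbs" %in% config$steps) {
    up <- unring_params(pf_fraction = config$pf_fraction,
                        pe_axis = config$pe_axis)
    use_rpg <- config$degibbs_method == "auto" && config$pf_fraction < 1
    for (i in seq_along(series)) {
      arr <- if (use_rpg) rpg_unring(series[[i]]$data, up)
             else sushi_unring(series[[i]]$data, up)
      series[[i]]$data <- pmax(arr, 0)
    }
    executed <- c(executed,
                  paste0("degibbs[", if (use_rpg) "rpg" else "sushi", "]"))
  }
  if ("external_hook" %in% config$steps) {
    if (!is.null(config$external_hook)) {
      for (i in seq_along(series)) {
        res <- config$external_hook(series[[i]])
        if (!inherits(res, "dwi_volume"))
          stop("external hook must return a dwi_volume", call. = FALSE)
        series[[i]] <- res
      }
      executed <- c(executed, "external_hook")
    } else {
      executed <- c(executed, "external_hook[disabled]")
    }
  }
  current <- if (two) {
    executed <- c(executed, "b0_normalize")
    b0_normalize(series[[1]], series[[2]])
  } else series[[1]]
  if ("rician" %in% config$steps) {
    if (is.null(sigma_map)) {
      warning("rician step without a denoise step: no noise map, skipping")
    } else {
      current <- rician_bias_correct(current, sigma_map)
      executed <- c(executed, "rician")
    }
  }
  if ("smooth" %in% config$steps) {
    current <- gaussian_smooth_csf_excluded(current, config$fwhm_factor,
                                            config$csf_mask)
    executed <- c(executed, "smooth")
  }
  fit <- wlls_fit(current)
  maps <- scalar_maps(fit)
  executed <- c(executed, "fit")

  report <- list(steps = executed,
                 parameters = list(
                   preset = config$preset, denoise_mode = config$denoise_mode,
                   shrinkage = config$shrinkage, patch_size = config$patch_size,
                   pf_fraction = config$pf_fraction, pe_axis = config$pe_axis,
                   degibbs_method = config$degibbs_method,
                   fwhm_factor = config$fwhm_factor),
                 seed = config$seed,
                 package_version = as.character(packageVersion("dkiprep")))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_dwi(current, file.path(config$outdir, "preprocessed.nii.gz"),
              file.path(config$outdir, "preprocessed.bval"),
              file.path(config$outdir, "preprocessed.bvec"))
    for (nm in scalar_names)
      write_map(maps[[nm]], file.path(config$outdir,
                                      paste0(tolower(nm), ".nii.gz")),
                current$voxel_size)
    if (!is.null(sigma_map))
      write_map(sigma_map, file.path(config$outdir, "sigma.nii.gz"),
                current$voxel_size)
  }
  list(preprocessed = current, maps = maps, sigma_map = sigma_map,
       fit = fit, report = report)
}
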