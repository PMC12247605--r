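#' Gradient table for a diffusion acquisition
#'
#' Holds one b-value (s/mm^2) and one unit direction vector per 4D volume,
#' plus an integer shell label obtained by snapping b-values to nominal
#' shells within a tolerance.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs matrix of direction vectors, either `n x 3` or `3 x n`.
#'   Vectors for `bval > 0` must have unit Euclidean norm (tolerance 1e-6);
#'   b = 0 vectors may be zero.
#' @param shell_tol b-values closer than this (s/mm^2) to a shell's running
#'   mean are merged into that shell; each b-value is then snapped to the
#'   rounded shell mean. Default 100.
#' @return An object of class `gradient_table` with elements `bvals`
#'   (snapped), `bvecs` (`n x 3`), `shell_index` (1-based, ascending b) and
#'   `shells` (nominal b per shell).
#' @export
gradient_table <- function(bvals, bvecs, shell_tol = 100) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must have three components per volume", call. = FALSE)
  if (length(bvals) != nrow(bvecs))
    stop("bvals and bvecs describe different numbers of volumes", call. = FALSE)
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative", call. = FALSE)

  # greedy shell clustering on sorted b-values
  ord <- order(bvals)
  centers <- numeric(0)
  counts <- integer(0)
  assign_raw <- integer(length(bvals))
  for (i in ord) {
    b <- bvals[i]
    hit <- which(abs(centers - b) <= shell_tol)
    if (length(hit)) {
      k <- hit[1L]
      centers[k] <- (centers[k] * counts[k] + b) / (counts[k] + 1L)
      counts[k] <- counts[k] + 1L
    } else {
      centers <- c(centers, b)
      counts <- c(counts, 1L)
      k <- length(centers)
    }
    assign_raw[i] <- k
  }
  sh_ord <- order(centers)
  rank <- match(seq_along(centers), sh_ord)
  shell_index <- rank[assign_raw]
  shells <- round(centers[sh_ord])
  snapped <- shells[shell_index]

  nrm <- sqrt(rowSums(bvecs^2))
  dw <- snapped > 0
  if (any(dw & abs(nrm - 1) > 1e-6))
    stop("diffusion-weighted bvecs must be unit vectors", call. = FALSE)

  structure(list(bvals = snapped, bvecs = bvecs,
                 shell_index = shell_index, shells = shells),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("gradient table:", length(x$bvals), "volumes\n")
  for (s in seq_along(x$shells))
    cat(sprintf("  b = %g s/mm^2: %d volumes\n", x$shells[s],
                sum(x$shell_index == s)))
  invisible(x)
}

#' 4D diffusion-weighted image volume
#'
#' The shared data model: a non-negative 4D magnitude array with its gradient
#' table, voxel geometry, partial-Fourier fraction and phase-encode axis.
#' Voxel coordinates are 1-based array indices throughout the package.
#'
#' @param data 4D numeric array (x, y, z, volume), finite and non-negative.
#' @param grad a [gradient_table], or `NULL` if `bvals`/`bvecs` are given.
#' @param bvals,bvecs passed to [gradient_table()] when `grad` is `NULL`.
#' @param voxel_size length-3 voxel size in mm.
#' @param pf_fraction partial-Fourier fraction, one of 1, 7/8, 6/8.
#' @param pe_axis phase-encode axis index (1, 2 or 3).
#' @param mask optional 3D logical brain mask.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, grad = NULL, bvals = NULL, bvecs = NULL,
                       voxel_size = c(1, 1, 1), pf_fraction = 1,
                       pe_axis = 2L, mask = NULL) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array", call. = FALSE)
  if (any(!is.finite(data)))
    stop("data contains non-finite values", call. = FALSE)
  if (any(data < 0))
    stop("magnitude data must be non-negative", call. = FALSE)
  if (is.null(grad)) grad <- gradient_table(bvals, bvecs)
  if (dim(data)[4L] != length(grad$bvals))
    stop("number of volumes does not match the gradient table", call. = FALSE)
  if (!any(abs(pf_fraction - c(1, 7 / 8, 6 / 8)) < 1e-9))
    stop("pf_fraction must be one of 1, 7/8, 6/8", call. = FALSE)
  if (!pe_axis %in% 1:3)
    stop("pe_axis must be 1, 2 or 3", call. = FALSE)
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dim(data)[1:3])
    if (any(is.na(mask))) stop("mask contains NA", call. = FALSE)
  }
  structure(list(data = data, grad = grad,
                 voxel_size = as.numeric(voxel_size),
                 pf_fraction = pf_fraction, pe_axis = as.integer(pe_axis),
                 mask = mask),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dwi_volume: %d x %d x %d, %d volumes, voxel %s mm, PF %s\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = "x"),
              format(x$pf_fraction)))
  invisible(x)
}

# signals as an n_vol x n_vox matrix (volumes contiguous per voxel)
flat_signal <- function(vol) {
  d <- dim(vol$data)
  t(matrix(vol$data, prod(d[1:3]), d[4L]))
}

vol_mask <- function(vol) {
  if (is.null(vol$mask)) array(TRUE, dim(vol$data)[1:3]) else vol$mask
}

#' Read a diffusion-weighted series from NIfTI + FSL bval/bvec files
#'
#' @param image_path 4D NIfTI image (.nii or .nii.gz).
#' @param bval_path,bvec_path FSL-style whitespace-delimited text files (one
#'   row of b-values; three rows of direction components).
#' @param pf_fraction,pe_axis acquisition geometry, see [dwi_volume()].
#' @param shell_tol shell-snapping tolerance in s/mm^2, see [gradient_table()].
#' @return A [dwi_volume].
#' @export
read_dwi <- function(image_path, bval_path, bvec_path, pf_fraction = 1,
                     pe_axis = 2L, shell_tol = 100) {
  img <- RNifti::readNifti(image_path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4L)
    stop("image is not a 4D NIfTI volume", call. = FALSE)
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  if (nrow(bvecs) != 3L)
    stop("bvec file must contain three rows", call. = FALSE)
  if (length(bvals) != ncol(bvecs))
    stop("bval and bvec files disagree on the number of volumes",
         call. = FALSE)
  if (length(bvals) != dim(data)[4L])
    stop("gradient files do not match the number of image volumes",
         call. = FALSE)
  vox <- RNifti::pixdim(img)[1:3]
  dwi_volume(data, grad = gradient_table(bvals, t(bvecs), shell_tol),
             voxel_size = vox, pf_fraction = pf_fraction, pe_axis = pe_axis)
}

#' Write a diffusion-weighted series as NIfTI + FSL bval/bvec files
#'
#' @param vol a [dwi_volume].
#' @param image_path,bval_path,bvec_path output paths.
#' @return Invisibly, `image_path`.
#' @export
write_dwi <- function(vol, image_path, bval_path, bvec_path) {
  stopifnot(inherits(vol, "dwi_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$voxel_size, 1)  # 4D: volume "pixdim" is 1
  RNifti::writeNifti(img, image_path)
  writeLines(paste(format(vol$grad$bvals, trim = TRUE), collapse = " "),
             bval_path)
  bv <- t(vol$grad$bvecs)
  writeLines(apply(bv, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(image_path)
}

#' Write a 3D scalar map as NIfTI
#'
#' @param map 3D numeric array.
#' @param path output path.
#' @param voxel_size length-3 voxel size in mm.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(map), dim = dim(map)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
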