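#' Parameters for subvoxel-shift Gibbs removal
#'
#' @param nshifts subvoxel shifts tested on each side of zero (default 20;
#'   shifts cover -1/2..1/2 voxel).
#' @param k1,k2 inner/outer bounds (voxels) of the total-variation
#'   neighborhood used to score each shift (defaults 1 and 3).
#' @param pf_fraction partial-Fourier fraction: 1, 7/8 or 6/8.
#' @param pe_axis phase-encode axis index.
#' @return An object of class `unring_params`.
#' @export
unring_params <- function(nshifts = 20, k1 = 1, k2 = 3, pf_fraction = 1,
                          pe_axis = 1L) {
  if (nshifts < 2) stop("nshifts must be at least 2", call. = FALSE)
  if (!(k1 >= 1 && k1 < k2)) stop("need 1 <= k1 < k2", call. = FALSE)
  if (!any(abs(pf_fraction - c(1, 7 / 8, 6 / 8)) < 1e-9)) {
    if (abs(pf_fraction - 5 / 8) < 1e-9)
      stop("5/8 partial Fourier is not supported: correcting for 5/8 partial Fourier may result in unreasonably smoothed maps",
           call. = FALSE)
    stop("pf_fraction must be one of 1, 7/8, 6/8", call. = FALSE)
  }
  structure(list(nshifts = as.integer(nshifts), k1 = as.integer(k1),
                 k2 = as.integer(k2), pf_fraction = pf_fraction,
                 pe_axis = as.integer(pe_axis)),
            class = "unring_params")
}

# in-plane axes for slice-wise processing: the PE axis and its partner
# (frequency-encode) axis; the remaining axis indexes slices
plane_axes <- function(pe_axis) {
  fe <- if (pe_axis <= 2L) setdiff(1:2, pe_axis)[1L] else 1L
  sort(c(pe_axis, fe))
}

# apply a slice-wise 2D operation: arr is 2D/3D/4D; fun takes a 3D stack
# (rows x cols x nz*nvol, spatial slice fastest) plus the slice/volume
# counts, and returns a stack of the same shape. Volumes (4th dimension)
# stay grouped so the operation can share state across them.
apply_in_plane <- function(arr, pe_axis, fun) {
  d <- dim(arr)
  nd <- length(d)
  if (nd == 2L) {
    st <- array(arr, dim = c(d, 1L))
    return(array(fun(st, 1L, 1L), dim = d))
  }
  pl <- plane_axes(pe_axis)
  rest <- setdiff(seq_len(nd), pl)
  perm <- c(pl, rest)
  ap <- aperm(arr, perm)
  nz <- d[rest[1L]]
  nvol <- if (nd == 4L) d[rest[2L]] else 1L
  st <- array(ap, dim = c(d[pl], nz * nvol))
  out <- fun(st, nz, nvol)
  out <- array(out, dim = d[perm])
  aperm(out, order(perm))
}

#' Subvoxel-shift (SuShi) Gibbs-ringing removal
#'
#' For each in-plane axis, voxel values are re-interpolated at the subvoxel
#' shift that minimizes local oscillation (one-sided total variation within
#' the `[k1, k2]` neighbor band). The two axis passes act on the pair of
#' complementary spectrally weighted images, so each pass only touches
#' ringing oriented along its axis. 3D (and 4D) input is processed
#' slice-wise in the plane containing the phase- and frequency-encode axes.
#'
#' @param image 2D, 3D or 4D numeric array.
#' @param params an [unring_params].
#' @return Array of the same shape.
#' @export
sushi_unring <- function(image, params = unring_params()) {
  if (any(!is.finite(image))) stop("image contains non-finite values", call. = FALSE)
  apply_in_plane(image, params$pe_axis, function(st, nz, nvol)
    .unring_stack_cpp(st, nz, nvol, params$nshifts, params$k1, params$k2, 0L))
}

# restricted pass: unring only along the PE axis (used by the
# partial-Fourier stages); restrict code 1 = stack rows, 2 = stack cols
sushi_unring_pe <- function(image, params) {
  pl <- plane_axes(params$pe_axis)
  restrict <- if (pl[1L] == params$pe_axis) 1L else 2L
  apply_in_plane(image, params$pe_axis, function(st, nz, nvol)
    .unring_stack_cpp(st, nz, nvol, params$nshifts, params$k1, params$k2,
                      restrict))
}

# FFT (sinc, periodic) resampling along one axis: zero-pad the spectrum by
# integer factor `up`, then keep every `down`-th sample starting at phase 1
resample_axis_fft <- function(arr, axis, up, down) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  ap <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(ap, n, prod(d) / n)
  if (up > 1L) {
    FF <- mvfft(m)
    nf <- n * up
    F2 <- matrix(0 + 0i, nf, ncol(m))
    h <- n %/% 2L
    F2[seq_len(h + 1L), ] <- FF[seq_len(h + 1L), ]
    if (n > h + 1L) F2[(nf - (n - h - 1L) + 1L):nf, ] <- FF[(h + 2L):n, ]
    if (n %% 2L == 0L) {  # split the Nyquist bin symmetrically
      F2[h + 1L, ] <- FF[h + 1L, ] / 2
      F2[nf - h + 1L, ] <- FF[h + 1L, ] / 2
    }
    m <- Re(mvfft(F2, inverse = TRUE)) / n
    n <- nf
  }
  if (down > 1L) {
    m <- m[seq(1L, n, by = down), , drop = FALSE]
    n <- nrow(m)
  }
  out <- array(m, dim = c(n, d[perm][-1L]))
  aperm(out, order(perm))
}

#' Gibbs removal for partial-Fourier (zero-filled) acquisitions
#'
#' Two-stage correction. A standard subvoxel-shift pass removes the
#' Nyquist-frequency ringing from symmetric k-space truncation. The residual
#' ringing from the asymmetric partial-Fourier cutoff oscillates at a lower
#' frequency (pi/2 for 6/8, 3*pi/4 for 7/8 of Nyquist), so the image is
#' resampled along the phase-encode axis onto a grid whose spacing maps that
#' frequency onto Nyquist, unrung there along the PE axis only, and
#' resampled back: for 6/8 the two parity-interleaved subgrids (spacing 2)
#' are corrected and re-interleaved; for 7/8 the image is sinc-upsampled x3,
#' decimated by 4 (spacing 4/3), corrected, and sinc-resampled back.
#'
#' @param image 2D, 3D or 4D numeric array.
#' @param params an [unring_params]; `pf_fraction = 1` delegates to
#'   [sushi_unring()].
#' @return Array of the same shape.
#' @export
rpg_unring <- function(image, params = unring_params(pf_fraction = 6 / 8)) {
  if (any(!is.finite(image))) stop("image contains non-finite values", call. = FALSE)
  if (abs(params$pf_fraction - 1) < 1e-9) return(sushi_unring(image, params))

  out <- sushi_unring(image, params)
  d <- dim(out)
  if (is.null(d)) d <- length(out)
  ax <- params$pe_axis
  n <- d[ax]
  kc <- 2 * params$pf_fraction - 1  # PF cutoff as a fraction of Nyquist

  if (abs(params$pf_fraction - 6 / 8) < 1e-9) {
    even <- seq(1L, n, by = 2L)
    odd <- seq(2L, n, by = 2L)
    stage2 <- out
    sub_e <- slice_axis(stage2, ax, even)
    sub_o <- slice_axis(stage2, ax, odd)
    sub_e <- sushi_unring_pe(sub_e, params)
    sub_o <- sushi_unring_pe(sub_o, params)
    stage2 <- assign_axis(stage2, ax, even, sub_e)
    stage2 <- assign_axis(stage2, ax, odd, sub_o)
  } else {  # 7/8
    if (n %% 4L != 0L)
      stop("7/8 partial-Fourier correction needs the PE-axis length to be a multiple of 4",
           call. = FALSE)
    rs <- resample_axis_fft(out, ax, up = 3L, down = 4L)
    rs <- sushi_unring_pe(rs, params)
    stage2 <- resample_axis_fft(rs, ax, up = 4L, down = 3L)
  }
  # the asymmetric-truncation ringing lives in the band just above the PF
  # cutoff frequency; confining the second-stage correction there discards
  # the resampled pass's out-of-band interpolation noise
  out + bandpass_axis(stage2 - out, ax, lo = kc - 0.05, hi = kc + 0.30,
                      taper = 0.08)
}

# smooth (raised-cosine) bandpass of an array along one axis; lo/hi/taper in
# units of the Nyquist frequency
bandpass_axis <- function(arr, axis, lo, hi, taper = 0.1) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  ap <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(ap, n, prod(d) / n)
  f <- abs(c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n / 2))
  ramp <- function(x) ifelse(x <= 0, 0, ifelse(x >= 1, 1, 0.5 - 0.5 * cos(pi * x)))
  w <- ramp((f - lo) / taper) * ramp((hi - f) / taper)
  filt <- Re(mvfft(mvfft(m) * w, inverse = TRUE)) / n
  aperm(array(filt, d[perm]), order(perm))
}

# index/assign along one axis of an n-d array
slice_axis <- function(arr, axis, idx) {
  d <- dim(arr)
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(arr), args, list(drop = FALSE)))
}

assign_axis <- function(arr, axis, idx, value) {
  d <- dim(arr)
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[<-`, c(list(arr), args, list(value)))
}
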