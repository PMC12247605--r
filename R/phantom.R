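#' Clinical-protocol gradient table
#'
#' The default multi-shell acquisition scheme: 5 b = 0 images plus shells at
#' b = 250 s/mm^2 (4 directions), b = 1000 s/mm^2 (20 directions) and
#' b = 2000 s/mm^2 (60 directions). Directions are a deterministic
#' golden-angle spiral per shell, rotated between shells so no two shells
#' share a direction.
#'
#' @param nb0,n250,n1000,n2000 volumes per shell.
#' @return A [gradient_table].
#' @export
default_protocol <- function(nb0 = 5L, n250 = 4L, n1000 = 20L, n2000 = 60L) {
  bvals <- c(rep(0, nb0), rep(250, n250), rep(1000, n1000), rep(2000, n2000))
  bvecs <- rbind(matrix(0, nb0, 3),
                 sphere_spiral(n250, 0.15),
                 sphere_spiral(n1000, 0.35),
                 sphere_spiral(n2000, 0.55))
  gradient_table(bvals, bvecs)
}

# golden-angle spiral on the sphere; `offset` decorrelates shells
sphere_spiral <- function(n, offset = 0) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  ga <- pi * (3 - sqrt(5))
  phi <- ga * (i + offset * n)
  cbind(r * cos(phi), r * sin(phi), z)
}

# diffusion tensor (6-vector: xx, xy, xz, yy, yz, zz) for an axially
# symmetric medium with principal axis u
dt_axial <- function(u, l_par, l_perp) {
  u <- u / sqrt(sum(u^2))
  D <- l_perp * diag(3) + (l_par - l_perp) * tcrossprod(u)
  c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
}

# vectorized forms: axes is n x 3 (unit rows), l_par/l_perp/k_par/k_perp are
# length-n; returns n x 6 / n x 15 matrices in the package's coefficient
# orders (kt already MD^2-scaled)
dt_axial_mat <- function(axes, l_par, l_perp) {
  d <- l_par - l_perp
  cbind(l_perp + d * axes[, 1]^2, d * axes[, 1] * axes[, 2],
        d * axes[, 1] * axes[, 3], l_perp + d * axes[, 2]^2,
        d * axes[, 2] * axes[, 3], l_perp + d * axes[, 3]^2)
}

kt_axial_mat <- function(axes, k_par, k_perp, l_par, l_perp) {
  md <- (l_par + 2 * l_perp) / 3
  w_par <- k_par * l_par^2 / md^2
  w_perp <- k_perp * l_perp^2 / md^2
  d <- w_par - w_perp
  idx <- list(c(1, 1, 1, 1), c(1, 1, 1, 2), c(1, 1, 1, 3), c(1, 1, 2, 2),
              c(1, 1, 2, 3), c(1, 1, 3, 3), c(1, 2, 2, 2), c(1, 2, 2, 3),
              c(1, 2, 3, 3), c(1, 3, 3, 3), c(2, 2, 2, 2), c(2, 2, 2, 3),
              c(2, 2, 3, 3), c(2, 3, 3, 3), c(3, 3, 3, 3))
  delta <- function(a, b) as.numeric(a == b)
  out <- matrix(0, length(k_par), 15L)
  for (c in seq_len(15L)) {
    ix <- idx[[c]]
    i <- ix[1]; j <- ix[2]; k <- ix[3]; l <- ix[4]
    Dl <- (delta(i, j) * delta(k, l) + delta(i, k) * delta(j, l) +
             delta(i, l) * delta(j, k)) / 3
    out[, c] <- w_perp * Dl +
      d * axes[, i] * axes[, j] * axes[, k] * axes[, l]
  }
  out * md^2
}

# fully symmetric isotropic basis tensor Delta_ijkl and axial term u^4,
# combined so that W(n) = w_perp + (w_par - w_perp) * (n.u)^4; returns the
# 15 components MD^2-scaled (the model's fitted parameterization)
kt_axial <- function(u, k_par, k_perp, l_par, l_perp) {
  u <- u / sqrt(sum(u^2))
  md <- (l_par + 2 * l_perp) / 3
  w_par <- k_par * l_par^2 / md^2
  w_perp <- k_perp * l_perp^2 / md^2
  idx <- list(c(1, 1, 1, 1), c(1, 1, 1, 2), c(1, 1, 1, 3), c(1, 1, 2, 2),
              c(1, 1, 2, 3), c(1, 1, 3, 3), c(1, 2, 2, 2), c(1, 2, 2, 3),
              c(1, 2, 3, 3), c(1, 3, 3, 3), c(2, 2, 2, 2), c(2, 2, 2, 3),
              c(2, 2, 3, 3), c(2, 3, 3, 3), c(3, 3, 3, 3))
  delta <- function(a, b) as.numeric(a == b)
  comp <- vapply(idx, function(ix) {
    i <- ix[1]; j <- ix[2]; k <- ix[3]; l <- ix[4]
    Dl <- (delta(i, j) * delta(k, l) + delta(i, k) * delta(j, l) +
             delta(i, l) * delta(j, k)) / 3
    w_perp * Dl + (w_par - w_perp) * u[i] * u[j] * u[k] * u[l]
  }, numeric(1))
  md^2 * comp
}

# forward DKI signal for one region over a whole gradient table
forward_signal <- function(s0, dt, kt, grad) {
  b <- grad$bvals / 1000
  n <- grad$bvecs
  dn <- dt_form_dirs(dt, n)
  kn <- kt_form_dirs(kt, n)
  s0 * exp(-b * dn + b^2 / 6 * kn)
}

# 22-coefficient truth vector in the fit parameterization
region_coef <- function(p) c(log(p$s0), p$dt, p$kt)

#' Multi-shell piecewise-anatomical noise phantom
#'
#' A 3D brain-like label field — thin white-matter tracts of varying
#' orientation (a commissural x-oriented slab bordering the ventricle, two
#' association slabs, a z-oriented projection column), surrounding grey
#' matter, and central CSF — each assigned literature-plausible DKI
#' parameters, with noiseless signals generated by the forward kurtosis
#' model under the clinical protocol. Tracts are deliberately only a few
#' voxels thick, as real tracts are at 2.5 mm resolution, their fiber axis
#' fans along the tract, and tissue parameters carry a smooth deterministic
#' voxelwise texture at in-vivo amplitudes (5-10 percent diffusivity, 10-15
#' percent kurtosis, a few degrees of orientation dispersion) so that patch
#' matrices are, as in real data, never exactly low-rank.
#'
#' @param grid_shape length-3 grid (default `c(64, 64, 16)`).
#' @param protocol a [gradient_table] (>= 22 volumes; default
#'   [default_protocol()]).
#' @param voxel_size voxel size in mm (default 2.5 iso).
#' @param texture_seed integer seed for the voxel-scale parameter
#'   heterogeneity; the phantom is bit-reproducible for a fixed value.
#' @return An object of class `phantom_truth`: `truth` ([dwi_volume] with
#'   the brain mask attached), `region_labels` (3D integer), `region_params`
#'   (per-label base parameters: `s0`, `dt`, `kt`, `name`), `coef_true`
#'   (22 x n_vox voxelwise truth coefficients, the exact forward-model
#'   parameters of every voxel), `wm_mask`, `csf_mask`.
#' @export
make_multishell_phantom <- function(grid_shape = c(64, 64, 16),
                                    protocol = default_protocol(),
                                    voxel_size = c(2.5, 2.5, 2.5),
                                    texture_seed = 42L) {
  if (length(protocol$bvals) < 22L)
    stop("the protocol must provide at least 22 volumes", call. = FALSE)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  u <- (slice.index(array(0, grid_shape), 1) - 0.5) / nx
  v <- (slice.index(array(0, grid_shape), 2) - 0.5) / ny
  w <- (slice.index(array(0, grid_shape), 3) - 0.5) / nz

  brain <- ((u - 0.5) / 0.44)^2 + ((v - 0.5) / 0.44)^2 + ((w - 0.5) / 0.42)^2 <= 1
  lab <- array(0L, grid_shape)
  lab[brain] <- 2L  # GM base
  tracts <- list(
    # commissural slab bordering the ventricle; fibers fan in the x-y plane
    list(sel = brain & abs(v - 0.64) <= 0.035 & abs(u - 0.5) <= 0.30 &
           abs(w - 0.5) <= 0.12,
         along = u, axdim = 1L, axis0 = c(1, 0, 0), fan = c(0, 1, 0),
         fan_deg = 25),
    # two association slabs; fibers fan in the y-z plane
    list(sel = brain & abs(u - 0.27) <= 0.030 & abs(v - 0.5) <= 0.33 &
           abs(w - 0.5) <= 0.12,
         along = v, axdim = 2L, axis0 = c(0, 1, 0), fan = c(0, 0, 1),
         fan_deg = 20),
    list(sel = brain & abs(u - 0.73) <= 0.030 & abs(v - 0.5) <= 0.33 &
           abs(w - 0.5) <= 0.12,
         along = v, axdim = 2L, axis0 = c(1, 1, 0) / sqrt(2),
         fan = c(0, 0, 1), fan_deg = 20),
    # projection column; fibers tilt in the x-z plane along their course
    list(sel = brain & ((u - 0.5) / 0.06)^2 + ((v - 0.26) / 0.05)^2 <= 1 &
           abs(w - 0.5) <= 0.35,
         along = w, axdim = 3L, axis0 = c(0, 0, 1), fan = c(1, 0, 0),
         fan_deg = 15))

  params <- list(
    list(name = "CSF", s0 = 2200,
         dt = dt_axial(c(1, 0, 0), 3.0, 3.0),
         kt = kt_axial(c(1, 0, 0), 0, 0, 3.0, 3.0)),
    list(name = "GM", s0 = 1150,
         dt = dt_axial(c(1, 0, 0), 0.95, 0.95),
         kt = kt_axial(c(1, 0, 0), 0.8, 0.8, 0.95, 0.95)))

  # per-voxel base parameters
  nvox <- prod(grid_shape)
  base_lp <- base_lr <- base_kp <- base_kr <- base_s0 <- rep(NA_real_, nvox)
  base_ax <- base_fan <- base_crs <- matrix(0, nvox, 3L)
  assign_base <- function(sel, lp, lr, kp, kr, s0, ax, fan) {
    base_lp[sel] <<- lp; base_lr[sel] <<- lr
    base_kp[sel] <<- kp; base_kr[sel] <<- kr; base_s0[sel] <<- s0
    base_ax[sel, ] <<- matrix(ax, length(sel), 3L, byrow = TRUE)
    base_fan[sel, ] <<- matrix(fan, length(sel), 3L, byrow = TRUE)
    crs <- c(ax[2] * fan[3] - ax[3] * fan[2], ax[3] * fan[1] - ax[1] * fan[3],
             ax[1] * fan[2] - ax[2] * fan[1])
    base_crs[sel, ] <<- matrix(crs, length(sel), 3L, byrow = TRUE)
  }
  assign_base(which(lab == 2L), 0.95, 0.95, 0.8, 0.8, 1150,
              c(1, 0, 0), c(0, 1, 0))

  # white-matter tracts: short blocks (~2 voxels along the tract) whose
  # fiber orientation fans across the tract, as in real fanning bundles
  block_len <- 2L
  for (ti in seq_along(tracts)) {
    tr <- tracts[[ti]]
    sel <- which(tr$sel)
    if (!length(sel)) next
    pos <- tr$along[sel]
    blk <- as.integer(floor(pos * grid_shape[tr$axdim] / block_len))
    ublk <- sort(unique(blk))
    for (bi in seq_along(ublk)) {
      f <- (bi - 1) / max(1L, length(ublk) - 1L)
      ang <- (2 * f - 1) * tr$fan_deg * pi / 180
      ax <- cos(ang) * tr$axis0 + sin(ang) * tr$fan
      ax <- ax / sqrt(sum(ax^2))
      bsel <- sel[blk == ublk[bi]]
      params[[length(params) + 1L]] <- list(
        name = sprintf("WM%d.%02d", ti, bi), s0 = 1000,
        dt = dt_axial(ax, 1.7, 0.45), kt = kt_axial(ax, 0.7, 1.8, 1.7, 0.45))
      lab[bsel] <- length(params)
      assign_base(bsel, 1.7, 0.45, 0.7, 1.8, 1000, ax, tr$fan)
    }
  }
  csf_sel <- which(((u - 0.5) / 0.09)^2 + ((v - 0.47) / 0.14)^2 +
                     ((w - 0.5) / 0.30)^2 <= 1 & brain)
  lab[csf_sel] <- 1L
  assign_base(csf_sel, 3.0, 3.0, 0, 0, 2200, c(1, 0, 0), c(0, 1, 0))

  # peri-ventricular partial-volume rim: white-matter voxels sharing a face
  # with CSF carry intermediate WM/CSF parameters (roughly a half-and-half
  # mixture), as voxel-scale partial volume produces at every ventricle
  # boundary. Their high-b signal sits near the noise floor, which is where
  # the characteristic kurtosis "black voxels" of clinical maps originate.
  is_csf <- array(lab == 1L, grid_shape)
  near_csf <- array(FALSE, grid_shape)
  n1 <- grid_shape[1]; n2 <- grid_shape[2]; n3 <- grid_shape[3]
  near_csf[-n1, , ] <- near_csf[-n1, , ] | is_csf[-1, , ]
  near_csf[-1, , ] <- near_csf[-1, , ] | is_csf[-n1, , ]
  near_csf[, -n2, ] <- near_csf[, -n2, ] | is_csf[, -1, ]
  near_csf[, -1, ] <- near_csf[, -1, ] | is_csf[, -n2, ]
  near_csf[, , -n3] <- near_csf[, , -n3] | is_csf[, , -1]
  near_csf[, , -1] <- near_csf[, , -1] | is_csf[, , -n3]
  rim_sel <- which(lab >= 3L & near_csf)
  if (length(rim_sel)) {
    params[[length(params) + 1L]] <- list(
      name = "WMpv", s0 = 1500,
      dt = dt_axial(c(1, 0, 0), 2.6, 1.8),
      kt = kt_axial(c(1, 0, 0), 0.4, 0.6, 2.6, 1.8))
    lab[rim_sel] <- length(params)
    assign_base(rim_sel, 2.6, 1.8, 0.4, 0.6, 1500, c(1, 0, 0), c(0, 1, 0))
  }

  # smooth deterministic parameter texture in tissue (not CSF): real brain
  # parameter maps vary continuously at the gyral/tract scale, and this
  # texture is what keeps patch Casorati matrices from being exactly
  # low-rank (without it, MPPCA denoising becomes unrealistically exact).
  # Amplitudes follow in-vivo within-ROI coefficients of variation
  # (~5-10 percent for diffusivities, ~10-15 percent for kurtosis, a few
  # degrees of orientation dispersion).
  sfield <- function(f, ph) {
    0.7 * sin(2 * pi * (f[1] * u + f[2] * v + f[3] * w) + ph) +
      0.3 * sin(2 * pi * (f[4] * u + f[5] * v + f[6] * w) + 2.1 * ph)
  }
  m_s0 <- c(sfield(c(2.3, 1.1, 0.6, 9.2, 5.1, 2.3), 0.4))
  m_lp <- c(sfield(c(1.7, 2.9, 0.8, 6.4, 8.3, 3.1), 1.1))
  m_lr <- c(sfield(c(3.1, 1.4, 1.1, 7.9, 4.2, 2.7), 2.0))
  m_kp <- c(sfield(c(2.6, 2.2, 0.5, 5.7, 9.4, 1.9), 0.7))
  m_kr <- c(sfield(c(1.2, 3.4, 0.9, 8.8, 6.1, 2.5), 2.7))
  m_d1 <- c(sfield(c(2.9, 1.8, 0.7, 7.2, 5.8, 3.3), 1.6))
  m_d2 <- c(sfield(c(1.5, 2.5, 1.2, 6.8, 7.5, 2.1), 0.2))

  # voxel-scale heterogeneity: independent per-voxel parameter perturbations
  # (uniform, zero mean) on top of the smooth fields, from a fixed seed so
  # the phantom is bit-reproducible. Sub-voxel tissue heterogeneity is a
  # few percent in vivo, and a phantom derived from measured data would
  # carry it implicitly; without it, patch matrices are low-rank and
  # denoising becomes unrealistically exact.
  i_tex <- with_seed(texture_seed, matrix(runif(nvox * 7L, -1, 1), nvox, 7L))

  tissue <- which(lab >= 2L)
  lp <- base_lp[tissue] * (1 + 0.07 * m_lp[tissue] + 0.04 * i_tex[tissue, 1])
  lr <- base_lr[tissue] * (1 + 0.07 * m_lr[tissue] + 0.04 * i_tex[tissue, 2])
  kp <- base_kp[tissue] * (1 + 0.12 * m_kp[tissue] + 0.08 * i_tex[tissue, 3])
  kr <- base_kr[tissue] * (1 + 0.12 * m_kr[tissue] + 0.08 * i_tex[tissue, 4])
  s0 <- base_s0[tissue] * (1 + 0.06 * m_s0[tissue] + 0.03 * i_tex[tissue, 5])
  dither <- tan(8 * pi / 180)
  dither_iid <- tan(3 * pi / 180)
  axes <- base_ax[tissue, ] +
    (dither * m_d1[tissue] + dither_iid * i_tex[tissue, 6]) * base_fan[tissue, ] +
    (dither * m_d2[tissue] + dither_iid * i_tex[tissue, 7]) * base_crs[tissue, ]
  axes <- axes / sqrt(rowSums(axes^2))

  coef_true <- matrix(NA_real_, 22L, nvox)
  coef_true[, tissue] <- rbind(log(s0),
                               t(dt_axial_mat(axes, lp, lr)),
                               t(kt_axial_mat(axes, kp, kr, lp, lr)))
  if (length(csf_sel))
    coef_true[, csf_sel] <- region_coef(params[[1L]])

  nvol <- length(protocol$bvals)
  A <- build_design_matrix(protocol)
  flat <- matrix(0, nvox, nvol)
  inb <- which(lab > 0L)
  flat[inb, ] <- t(exp(A %*% coef_true[, inb]))
  data <- array(flat, c(grid_shape, nvol))
  truth <- dwi_volume(data, grad = protocol, voxel_size = voxel_size,
                      mask = lab > 0L)
  structure(list(truth = truth, region_labels = lab, region_params = params,
                 coef_true = coef_true,
                 wm_mask = lab >= 3L, csf_mask = lab == 1L),
            class = "phantom_truth")
}

#' Rician noise model
#'
#' @param snr target signal-to-noise ratio (reference b = 0 signal divided
#'   by sigma). The benchmark grid uses snr in 10, 15, 20, 25, 30, 60.
#' @param sigma noise standard deviation in signal units; if `NULL` it is
#'   derived from the phantom when noise is added.
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(snr, sigma = NULL, seed = 1L) {
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  structure(list(snr = snr, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

# reference level for the SNR definition: mean white-matter b = 0 signal
phantom_sigma <- function(phantom, snr) {
  b0 <- phantom$truth$data[, , , which(phantom$truth$grad$bvals == 0)[1]]
  mean(b0[phantom$wm_mask]) / snr
}

#' Add Rician noise to a noiseless volume
#'
#' Per voxel and volume, `Sm = sqrt((Sr + sigma e1)^2 + (sigma e2)^2)` with
#' independent standard normal draws e1, e2 (the imaginary signal component
#' of the ground truth is zero). Reproducible from the model's seed; the
#' global RNG state is untouched.
#'
#' @param truth a noiseless [dwi_volume] or [make_multishell_phantom()]
#'   result (whose WM mask then defines the SNR reference signal).
#' @param noise a [noise_model()].
#' @return A noisy [dwi_volume].
#' @export
add_rician_noise <- function(truth, noise) {
  if (inherits(truth, "phantom_truth")) {
    if (is.null(noise$sigma)) noise$sigma <- phantom_sigma(truth, noise$snr)
    truth <- truth$truth
  }
  stopifnot(inherits(truth, "dwi_volume"))
  if (is.null(noise$sigma))
    stop("sigma is not set; pass a phantom or specify sigma", call. = FALSE)
  if (noise$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  n <- length(truth$data)
  noisy <- with_seed(noise$seed, {
    e1 <- rnorm(n)
    e2 <- rnorm(n)
    sqrt((truth$data + noise$sigma * e1)^2 + (noise$sigma * e2)^2)
  })
  truth$data <- array(noisy, dim = dim(truth$data))
  truth
}

# --- Shepp-Logan diffusion phantom ------------------------------------------

# standard ellipse set (center, semi-axes, rotation in degrees); regions are
# painted in order so later ellipses sit on top
shepp_ellipses <- function() {
  data.frame(
    x0 = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0 = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.605, -0.605),
    a = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0))
}

shepp_labels <- function(nx, ny) {
  ell <- shepp_ellipses()
  x <- matrix(rep((seq_len(nx) - 0.5) / nx * 2 - 1, ny), nx, ny)
  y <- matrix(rep((seq_len(ny) - 0.5) / ny * 2 - 1, each = nx), nx, ny)
  lab <- matrix(0L, nx, ny)
  for (e in seq_len(nrow(ell))) {
    th <- ell$phi[e] * pi / 180
    xr <- (x - ell$x0[e]) * cos(th) + (y - ell$y0[e]) * sin(th)
    yr <- -(x - ell$x0[e]) * sin(th) + (y - ell$y0[e]) * cos(th)
    lab[(xr / ell$a[e])^2 + (yr / ell$b[e])^2 <= 1] <- e
  }
  lab
}

# DKI parameters per Shepp-Logan region: anisotropic with nonzero kurtosis
# everywhere inside the head so percent error is defined for all seven
# scalars; orientations and intensities vary between ellipses
shepp_region_params <- function() {
  mk <- function(s0, u, lp, lr, kp, kr)
    list(s0 = s0, dt = dt_axial(u, lp, lr), kt = kt_axial(u, kp, kr, lp, lr))
  list(
    mk(2000, c(0, 0, 1), 0.9, 0.35, 0.8, 1.9),    # 1 skull ring: bright, anisotropic
    mk(1000, c(0, 0, 1), 1.7, 0.45, 0.7, 1.8),    # 2 brain bulk: WM-like, through-plane axis
    mk(1800, c(0, 1, 0), 2.9, 2.7, 0.15, 0.2),    # 3 right ventricle: CSF-like
    mk(1800, c(0, 1, 0), 2.9, 2.7, 0.15, 0.2),    # 4 left ventricle
    mk(1800, c(1, 1, 0) / sqrt(2), 2.9, 2.6, 0.15, 0.2),  # 5 upper mass: CSF-like cistern
    mk(900, c(0, 1, 0), 1.6, 0.5, 0.7, 1.6),      # 6-10 small features
    mk(900, c(1, 0, 0), 1.6, 0.5, 0.7, 1.6),
    mk(1100, c(0, 1, 0), 1.2, 0.5, 0.9, 1.5),
    mk(1100, c(1, 0, 0), 1.2, 0.5, 0.9, 1.5),
    mk(1100, c(1, 1, 0) / sqrt(2), 1.2, 0.5, 0.9, 1.5))
}

# rectangular ROI in phantom coordinates ([-1, 1]^2) -> logical matrix
rect_roi <- function(nx, ny, x_rng, y_rng) {
  x <- (seq_len(nx) - 0.5) / nx * 2 - 1
  y <- (seq_len(ny) - 0.5) / ny * 2 - 1
  outer(x >= x_rng[1] & x <= x_rng[2], y >= y_rng[1] & y <= y_rng[2])
}

#' Shepp-Logan diffusion phantom with simulated Gibbs ringing
#'
#' Each ellipse of the Shepp-Logan head model is assigned DKI parameters and
#' per-volume noiseless images are rendered on a high-resolution grid,
#' Fourier transformed, centrally truncated to the target grid (symmetric
#' truncation ringing) and zero-filled on the negative-frequency side of the
#' phase-encode axis to the requested partial-Fourier fraction (asymmetric
#' ringing); the magnitude of the inverse transform is the corrupted volume.
#' The clean target-resolution truth is rendered directly from the region
#' parameters. Four rectangular ROIs straddle high-contrast edges where the
#' ringing concentrates.
#'
#' @param resolution target in-plane grid size (default 128).
#' @param protocol a [gradient_table] (default [default_protocol()]).
#' @param pf_fraction 1, 7/8 or 6/8 (default 6/8); others are unsupported.
#' @param oversample high-resolution factor (>= 4 for a faithful truth;
#'   1 with `pf_fraction = 1` reproduces the identity path).
#' @return List with `clean` (a `phantom_truth`, z-extent 1), `ringing`
#'   (corrupted [dwi_volume]) and `ringing_rois` (list of four 3D masks).
#' @export
make_shepp_logan_dmri <- function(resolution = 128, protocol = default_protocol(),
                                  pf_fraction = 6 / 8, oversample = 4) {
  if (!any(abs(pf_fraction - c(1, 7 / 8, 6 / 8)) < 1e-9))
    stop("pf_fraction must be one of 1, 7/8, 6/8", call. = FALSE)
  nl <- as.integer(resolution)
  nh <- as.integer(resolution * oversample)
  lab_hi <- shepp_labels(nh, nh)
  lab_lo <- shepp_labels(nl, nl)
  params <- shepp_region_params()
  nvol <- length(protocol$bvals)
  sig <- vapply(params, function(p) forward_signal(p$s0, p$dt, p$kt, protocol),
                numeric(nvol))  # nvol x 10

  ring <- array(0, c(nl, nl, 1L, nvol))
  clean <- array(0, c(nl, nl, 1L, nvol))
  lut_hi <- rbind(0, t(sig))   # label 0 -> 0 signal
  keep <- pf_keep_indices(nl, pf_fraction)
  ctr <- crop_indices(nh, nl)
  for (vv in seq_len(nvol)) {
    hi <- matrix(lut_hi[lab_hi + 1L, vv], nh, nh)
    F <- fft(hi)
    Fc <- F[ctr, ctr] * (nl / nh)^2
    Fc[!keep, ] <- 0  # zero-fill along the PE (first) axis
    img <- fft(Fc, inverse = TRUE) / nl^2
    ring[, , 1L, vv] <- Mod(img)
    clean[, , 1L, vv] <- matrix(lut_hi[lab_lo + 1L, vv], nl, nl)
  }

  grad <- protocol
  truth <- dwi_volume(clean, grad = grad, voxel_size = c(2, 2, 2),
                      pf_fraction = 1, pe_axis = 1L,
                      mask = array(lab_lo > 0L, c(nl, nl, 1L)))
  ringing <- dwi_volume(ring, grad = grad, voxel_size = c(2, 2, 2),
                        pf_fraction = pf_fraction, pe_axis = 1L,
                        mask = array(lab_lo > 0L, c(nl, nl, 1L)))
  # boxes drawn where the uncorrected error maps show the strongest ringing:
  # the oscillation bands flanking the lateral high-contrast boundaries
  # (ringing from the 6/8 partial Fourier runs along the horizontal axis),
  # offset from the boundary voxels themselves
  rois <- list(
    right_caudal = rect_roi(nl, nl, c(0.47, 0.55), c(-0.42, -0.21)),
    right_rostral = rect_roi(nl, nl, c(0.47, 0.55), c(-0.21, 0.00)),
    right_band = rect_roi(nl, nl, c(0.47, 0.60), c(-0.36, -0.12)),
    left_band = rect_roi(nl, nl, c(-0.63, -0.49), c(-0.30, 0.00)))
  rois <- lapply(rois, function(r) array(r & lab_lo == 2L, c(nl, nl, 1L)))
  list(clean = structure(list(truth = truth, region_labels = array(lab_lo, c(nl, nl, 1L)),
                              region_params = params,
                              wm_mask = array(lab_lo == 2L, c(nl, nl, 1L)),
                              csf_mask = array(lab_lo %in% c(3L, 4L), c(nl, nl, 1L))),
                         class = "phantom_truth"),
       ringing = ringing, ringing_rois = rois)
}

# central crop of an unshifted fft spectrum from nh to nl samples: keep the
# nl/2 + 1 lowest non-negative and nl/2 - 1 highest (negative) frequencies
crop_indices <- function(nh, nl) {
  if (nh == nl) return(seq_len(nl))
  h <- nl %/% 2L
  c(seq_len(h + 1L), seq(nh - (nl - h - 1L) + 1L, nh))
}

pf_keep_indices <- function(n, pf) {
  # frequencies in fft order 0..n/2, -(n/2-1)..-1; the zero-filled portion is
  # the most negative (1 - pf) of the full range
  k <- c(seq(0L, n %/% 2L), seq(-(n - n %/% 2L - 1L), -1L))
  kmin <- -(2 * pf - 1) * (n / 2)
  k >= kmin
}
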