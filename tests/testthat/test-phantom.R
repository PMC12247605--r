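test_that("the default protocol matches the clinical shell structure", {
  gt <- proto()
  expect_length(gt$bvals, 89L)
  expect_equal(gt$shells, c(0, 250, 1000, 2000))
  expect_equal(as.integer(table(gt$shell_index)), c(5L, 4L, 20L, 60L))
  dw <- gt$bvals > 0
  expect_equal(sqrt(rowSums(gt$bvecs[dw, ]^2)), rep(1, sum(dw)),
               tolerance = 1e-12)
})

test_that("phantom truth maps reflect the constructed tissue parameters", {
  ph <- small_phantom()
  tm <- dkiprep:::truth_scalar_maps(ph)
  csf <- ph$csf_mask
  expect_true(all(abs(tm$FA[csf]) < 1e-12))
  expect_true(all(abs(tm$MK[csf]) < 1e-12))
  expect_equal(unique(round(tm$MD[csf], 10)), 3)
  # WM tract cores: literature-plausible anisotropic values with a few
  # percent of within-tract modulation (the peri-ventricular rim region is
  # deliberately faster and less anisotropic)
  nm <- vapply(ph$region_params, `[[`, character(1), "name")
  rim <- which(nm == "WMpv")
  core <- ph$wm_mask & !(ph$region_labels %in% rim)
  expect_true(all(tm$AD[core] > 1.50 & tm$AD[core] < 1.90))
  expect_true(all(tm$RD[core] > 0.39 & tm$RD[core] < 0.51))
  expect_true(all(tm$FA[core] > 0.55))
  expect_true(all(tm$RK[core] > 1.4 & tm$RK[core] < 2.2))
  if (length(rim)) {
    rv <- ph$region_labels == rim
    expect_true(all(tm$MD[rv] > 1.8 & tm$MD[rv] < 2.4))
  }
  # masks are subsets of the labeled domain
  expect_true(all(ph$region_labels[ph$wm_mask] > 0))
  expect_true(all(ph$region_labels[ph$csf_mask] > 0))
})

test_that("fitting the noiseless truth recovers the voxelwise parameters", {
  ph <- small_phantom()
  fit <- wlls_fit(ph$truth)
  inb <- which(ph$region_labels > 0L)
  err <- abs(fit$coef[, inb] - ph$coef_true[, inb])
  expect_lt(max(err) / max(abs(ph$coef_true[, inb])), 1e-8)
  # truth signals equal the forward model by construction
  expect_error(make_multishell_phantom(protocol = gradient_table(
    c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))), "22")
})

test_that("the Rician noise generator matches its analytic moments", {
  # Sr = 0: magnitudes are Rayleigh(sigma); mean = sigma sqrt(pi/2)
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  n <- 50000
  truth <- dwi_volume(array(0, c(n, 1, 1, 2)), grad = gt)
  noisy <- add_rician_noise(truth, noise_model(10, sigma = 1, seed = 4))
  m <- mean(noisy$data)
  se <- sd(noisy$data) / sqrt(2 * n)
  expect_lt(abs(m - sqrt(pi / 2)), 3 * se)

  # distribution check: Kolmogorov-Smirnov against Rayleigh(sigma)
  x <- noisy$data[seq_len(10000)]
  ks <- suppressWarnings(stats::ks.test(x, function(q) 1 - exp(-q^2 / 2)))
  expect_gt(ks$p.value, 0.01)

  # near-zero sigma limit: Sm -> Sr
  ph <- small_phantom()
  tiny <- add_rician_noise(ph, noise_model(1e9, seed = 2))
  expect_lt(max(abs(tiny$data - ph$truth$data)) / max(ph$truth$data), 1e-6)
  expect_error(add_rician_noise(ph$truth, noise_model(10, sigma = -1)),
               "positive")
})

test_that("noise realizations are reproducible and leave the RNG alone", {
  ph <- small_phantom()
  set.seed(500)
  before <- .Random.seed
  a <- add_rician_noise(ph, noise_model(20, seed = 9))
  expect_identical(.Random.seed, before)
  b <- add_rician_noise(ph, noise_model(20, seed = 9))
  expect_identical(a$data, b$data)
  c <- add_rician_noise(ph, noise_model(20, seed = 10))
  expect_false(identical(a$data, c$data))
})

test_that("the noiseless fit equals the truth at effectively infinite SNR", {
  ph <- small_phantom()
  tm <- dkiprep:::truth_scalar_maps(ph)
  maps <- lapply(1:3, function(r) {
    noisy <- add_rician_noise(ph, noise_model(1e6, seed = r))
    scalar_maps(wlls_fit(noisy))$MD
  })
  med <- median_over_realizations(maps)
  wm <- ph$wm_mask
  expect_lt(max(abs(med[wm] - tm$MD[wm]) / tm$MD[wm]), 1e-4)
})

test_that("the Shepp-Logan generator produces the documented artifacts", {
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  # identity path: no oversampling, no partial Fourier
  sh0 <- make_shepp_logan_dmri(64, gt, pf_fraction = 1, oversample = 1)
  expect_equal(sh0$ringing$data, sh0$clean$truth$data, tolerance = 1e-10)

  # ellipses of varying intensity
  s0s <- vapply(dkiprep:::shepp_region_params(), `[[`, numeric(1), "s0")
  expect_gt(length(unique(s0s)), 3)

  sh <- make_shepp_logan_dmri(128, gt, pf_fraction = 6 / 8)
  expect_length(sh$ringing_rois, 4L)
  expect_true(all(vapply(sh$ringing_rois, sum, numeric(1)) > 0))

  # ringing: oscillation near a high-contrast edge exceeds the
  # no-truncation baseline along the PE (horizontal) axis
  shf <- make_shepp_logan_dmri(128, gt, pf_fraction = 1, oversample = 1)
  lab <- sh$clean$region_labels[, , 1]
  row <- 64
  inside <- which(lab[, row] == 2L)
  seg <- inside[5:20]
  osc_pf <- tv(diff(sh$ringing$data[seg, row, 1, 1]))
  osc_base <- tv(diff(shf$ringing$data[seg, row, 1, 1]))
  expect_gt(osc_pf, osc_base)

  expect_error(make_shepp_logan_dmri(64, gt, pf_fraction = 5 / 8),
               "pf_fraction")
})

test_that("phantom construction is deterministic", {
  a <- make_multishell_phantom(c(16, 16, 6))
  b <- make_multishell_phantom(c(16, 16, 6))
  expect_identical(a$truth$data, b$truth$data)
  expect_identical(a$region_labels, b$region_labels)
})
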