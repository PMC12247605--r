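test_that("the design matrix encodes the log-kurtosis model", {
  gt <- proto()
  A <- build_design_matrix(gt)
  expect_identical(dim(A), c(89L, 22L))
  # b = 0 rows are pure intercept
  b0 <- gt$bvals == 0
  expect_true(all(A[b0, -1] == 0) && all(A[b0, 1] == 1))
  # n = (1, 0, 0), b = 1 ms/um^2: the D block loads only the xx column
  gt1 <- gradient_table(c(0, rep(1000, 6)),
                        rbind(matrix(0, 1, 3), c(1, 0, 0),
                              dkiprep:::sphere_spiral(5)))
  A1 <- build_design_matrix(gt1, "dti")
  expect_equal(A1[2, ], c(1, -1, 0, 0, 0, 0, 0))
  # full-rank for the clinical protocol
  expect_identical(qr(A)$rank, 22L)
  # model preconditions
  expect_error(build_design_matrix(gt1, "dki"), "22 volumes")
  expect_error(build_design_matrix(gradient_table(
    c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0))), "dti"), "7 volumes")
  single <- gradient_table(c(0, rep(1000, 30)),
                           rbind(matrix(0, 1, 3), dkiprep:::sphere_spiral(30)))
  expect_error(build_design_matrix(single, "dki"), "shells")
})

test_that("a noiseless isotropic signal fits exactly", {
  gt <- mini_proto()
  dt <- c(1, 0, 0, 1, 0, 1)
  kt <- rep(0, 15)
  vol <- forward_vol(100, dt, kt, gt)
  maps <- scalar_maps(wlls_fit(vol))
  for (nm in c("MD", "AD", "RD")) expect_equal(unique(c(maps[[nm]])), 1,
                                               tolerance = 1e-8)
  for (nm in c("FA", "MK", "AK", "RK")) expect_lt(max(abs(maps[[nm]])), 1e-8)
})

test_that("forward-simulated tensors are recovered to 1e-8 relative error", {
  gt <- proto()
  A <- build_design_matrix(gt)
  set.seed(21)
  for (i in 1:100) {
    tp <- random_tensor_pair()
    beta <- c(log(150), tp$dt, tp$kt)
    sig <- exp(drop(A %*% beta))
    vol <- dwi_volume(array(rep(sig, each = 1), c(1, 1, 1, length(sig))),
                      grad = gt)
    fit <- wlls_fit(vol)
    expect_lt(max(abs(fit$coef[, 1] - beta)) / max(abs(beta)), 1e-8)
  }
})

test_that("scalar maps match the closed forms", {
  # eigenvalues (1.7, 0.3, 0.3): FA = 1.4/sqrt(1.96 + 1.96/2)... = 0.7995
  dt <- c(1.7, 0, 0, 0.3, 0, 0.3)
  kt <- rep(0, 15)
  gt <- mini_proto()
  maps <- scalar_maps(wlls_fit(forward_vol(100, dt, kt, gt)))
  l <- c(1.7, 0.3, 0.3)
  fa_true <- sqrt(0.5 * sum((l - rev(l))^2 + 0) )
  fa_true <- sqrt(0.5 * ((l[1] - l[2])^2 + (l[1] - l[3])^2 + (l[2] - l[3])^2) /
                    sum(l^2))
  expect_equal(maps$FA[1, 1, 1], fa_true, tolerance = 1e-8)
  expect_equal(fa_true, 0.7990, tolerance = 1e-4)
  expect_equal(maps$MD[1, 1, 1], mean(l), tolerance = 1e-8)
  expect_equal(maps$MD[1, 1, 1], 0.7667, tolerance = 1e-4)
  expect_equal(maps$AD[1, 1, 1], 1.7, tolerance = 1e-8)
  expect_equal(maps$RD[1, 1, 1], 0.3, tolerance = 1e-8)

  # isotropic kurtosis W = 1 (equal parallel and perpendicular kurtosis):
  # every apparent kurtosis equals 1
  md <- 1.2
  dt_i <- c(md, 0, 0, md, 0, md)
  kt_i <- dkiprep:::kt_axial(c(1, 0, 0), 1, 1, md, md)
  maps_i <- scalar_maps(wlls_fit(forward_vol(100, dt_i, kt_i, gt)))
  expect_equal(maps_i$MK[1, 1, 1], 1, tolerance = 1e-3)
  expect_equal(maps_i$AK[1, 1, 1], 1, tolerance = 1e-6)
  expect_equal(maps_i$RK[1, 1, 1], 1, tolerance = 1e-6)
})

test_that("scalar maps are equivariant under joint rotation", {
  set.seed(31)
  gt <- proto()
  tp <- random_tensor_pair()
  vol <- forward_vol(120, tp$dt, tp$kt, gt, grid = c(1, 1, 1))
  m0 <- scalar_maps(wlls_fit(vol))
  # random rotation via QR of a Gaussian matrix
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  gt_r <- gradient_table(gt$bvals, t(Q %*% t(gt$bvecs)))
  vol_r <- dwi_volume(vol$data, grad = gt_r)
  m1 <- scalar_maps(wlls_fit(vol_r))
  for (nm in c("MD", "AD", "RD", "FA", "MK", "AK", "RK"))
    expect_equal(m1[[nm]][1, 1, 1], m0[[nm]][1, 1, 1], tolerance = 1e-6)
})

test_that("two-pass weighting does not hurt accuracy at moderate SNR", {
  ph <- small_phantom()
  noisy <- add_rician_noise(ph, noise_model(15, seed = 77))
  mask <- dkiprep:::vol_mask(ph$truth)
  tm <- dkiprep:::truth_scalar_maps(ph)
  rmse <- function(method) {
    m <- scalar_maps(wlls_fit(noisy, method = method))
    v <- m$MD[mask] - tm$MD[mask]
    sqrt(mean(v[is.finite(v)]^2))
  }
  expect_lte(rmse("wlls"), rmse("lls"))
})

test_that("outlier accounting follows the physical bounds", {
  dims <- c(5, 5, 4)
  mk_maps <- function(...) {
    vals <- list(...)
    out <- lapply(dkiprep:::scalar_names, function(nm)
      array(if (!is.null(vals[[nm]])) vals[[nm]] else 0.5, dims))
    names(out) <- dkiprep:::scalar_names
    out$valid <- array(TRUE, dims)
    class(out) <- "scalar_maps"
    out
  }
  roi <- array(TRUE, dims)
  clean <- mk_maps()
  os <- outlier_stats(clean, roi)
  expect_true(all(os$per_map == 0) && os$average == 0)

  one_bad <- mk_maps()
  one_bad$MD[1, 1, 1] <- -0.1
  os2 <- outlier_stats(one_bad, roi)
  expect_equal(unname(os2$per_map["MD"]), 100 / prod(dims))
  expect_equal(os2$average, 100 / prod(dims) / 7)

  # K > -2 bound: -2.5 is an outlier, -1.9 is not; FA in (0, 1)
  kk <- mk_maps()
  kk$MK[1, 1, 1] <- -2.5
  kk$MK[2, 1, 1] <- -1.9
  kk$FA[1, 1, 1] <- 1.2
  os3 <- outlier_stats(kk, roi)
  expect_equal(unname(os3$per_map["MK"]), 100 / prod(dims))
  expect_equal(unname(os3$per_map["FA"]), 100 / prod(dims))
  expect_error(outlier_stats(kk, array(FALSE, dims)), "empty")
})
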