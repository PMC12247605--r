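test_that("a noiseless rank-1 Casorati matrix passes through unchanged", {
  set.seed(11)
  X <- outer(runif(100, 1, 2), runif(90, 1, 2))
  res <- mp_denoise_matrix(X)
  expect_identical(res$npars, 1L)
  expect_lt(res$sigma, 1e-8 * norm(X, "F"))
  expect_lt(max(abs(res$X_hat - X)), 1e-10 * max(X))
})

test_that("the MP criterion recovers the generative noise level", {
  # Monte-Carlo oracle: i.i.d. Gaussian noise with known sigma = 1
  set.seed(7)
  sig <- replicate(50, mp_denoise_matrix(matrix(rnorm(100 * 90), 100, 90))$sigma)
  expect_lt(abs(mean(sig) - 1), 0.05)
})

test_that("denoising a noisy low-rank matrix reduces the Frobenius error", {
  set.seed(3)
  L <- matrix(rnorm(100 * 3), 100, 3) %*% (3 * matrix(rnorm(3 * 90), 3, 90))
  X <- L + matrix(rnorm(100 * 90), 100, 90)
  e0 <- norm(X - L, "F")
  for (shrink in c(FALSE, TRUE)) {
    Xh <- mp_denoise_matrix(X, shrink = shrink)$X_hat
    expect_lt(norm(Xh - L, "F"), e0)
  }
  expect_error(mp_denoise_matrix(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("adaptive patch selection follows the documented bilateral score", {
  # homogeneous volume: the intensity term vanishes and the patch is the
  # spatially nearest voxels, ties broken by lexicographic index
  grid <- c(9, 9, 9)
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  vol <- dwi_volume(array(1, c(grid, 2)), gt)
  spec <- patch_spec(patch_size = 27, search_window = 3)
  idx <- select_adaptive_patch(vol, c(5, 5, 5), spec)
  expect_identical(nrow(idx), 27L)
  expect_identical(idx[1, ], c(5L, 5L, 5L))
  d2 <- rowSums((idx - 5)^2)
  # all selected voxels at least as close as any unselected one
  all_d2 <- rowSums((as.matrix(expand.grid(1:9, 1:9, 1:9)) - 5)^2)
  expect_lte(max(d2), sort(all_d2)[27] + 1e-12)

  # two-tissue volume: brute-force oracle ranking of the documented score
  set.seed(5)
  arr <- array(1, c(grid, 2))
  tissue2 <- as.matrix(expand.grid(1:9, 1:9, 1:9))[, 1] > 5  # x > 5 plane
  arr[cbind(as.matrix(expand.grid(1:9, 1:9, 1:9))[tissue2, ], 1)] <- 4
  arr[cbind(as.matrix(expand.grid(1:9, 1:9, 1:9))[tissue2, ], 2)] <- 4
  vol2 <- dwi_volume(arr, gt)
  spec2 <- patch_spec(patch_size = 60, search_window = 4)
  center <- c(3L, 5L, 5L)
  idx2 <- select_adaptive_patch(vol2, center, spec2)
  # oracle: rank all candidates by dist/max + idiff/max, ties by index
  cand <- as.matrix(expand.grid(1:9, 1:9, 1:9))
  keep <- apply(abs(sweep(cand, 2, center)), 1, max) <= 4
  cand <- cand[keep, , drop = FALSE]
  dist <- sqrt(rowSums(sweep(cand, 2, center)^2))
  sig_c <- arr[center[1], center[2], center[3], ]
  idiff <- apply(cand, 1, function(v) mean(abs(arr[v[1], v[2], v[3], ] - sig_c)))
  score <- dist / max(dist) + idiff / max(idiff)
  lin <- cand[, 1] + 9 * (cand[, 2] - 1) + 81 * (cand[, 3] - 1)
  ord <- order(score, lin)
  oracle <- cand[ord[1:60], , drop = FALSE]
  expect_setequal(idx2[, 1] + 9 * (idx2[, 2] - 1) + 81 * (idx2[, 3] - 1),
                  oracle[, 1] + 9 * (oracle[, 2] - 1) + 81 * (oracle[, 3] - 1))
  # with >= 60 same-tissue voxels available, only same-tissue voxels enter
  expect_true(all(arr[cbind(idx2, 1)] == 1))
  # patch_size voxels are returned and the center is outside-mask-safe
  expect_identical(nrow(idx2), 60L)
  vol3 <- vol2
  vol3$mask <- array(FALSE, grid)
  expect_error(select_adaptive_patch(vol3, center, spec2), "mask")
})

test_that("requesting the default 100-voxel patch returns 100 voxels", {
  ph <- small_phantom()
  idx <- select_adaptive_patch(ph$truth, c(12, 12, 4), patch_spec())
  expect_identical(nrow(idx), 100L)
})

test_that("volume denoising is exact on noiseless input and reduces RMSE on noisy input", {
  ph <- small_phantom()
  mask4 <- rep(dkiprep:::vol_mask(ph$truth), dim(ph$truth$data)[4])
  for (mode in c("adaptive", "local")) {
    dn <- denoise_volume(ph$truth, patch_spec(mode))
    rel <- abs(dn$denoised$data - ph$truth$data) /
      pmax(abs(ph$truth$data), 1e-12)
    expect_lt(max(rel[mask4]), 1e-6)
    expect_lt(max(dn$sigma_map), 1e-8 * max(ph$truth$data))
  }

  noisy <- add_rician_noise(ph, noise_model(20, seed = 101))
  rmse0 <- sqrt(mean((noisy$data - ph$truth$data)[mask4]^2))
  rmse <- c()
  for (mode in c("adaptive", "local")) {
    dn <- denoise_volume(noisy, patch_spec(mode))
    rmse[mode] <- sqrt(mean((dn$denoised$data - ph$truth$data)[mask4]^2))
    expect_lt(rmse[mode], rmse0)
  }
  # adaptive patches pool same-tissue voxels: at least as good as the local box
  expect_lte(rmse["adaptive"], rmse["local"])

  expect_error(denoise_volume(dwi_volume(ph$truth$data, ph$truth$grad,
                                         mask = array(FALSE, dim(ph$truth$data)[1:3])),
                              patch_spec()), "mask")
})

test_that("component and sigma maps respect their bounds on noisy input", {
  ph <- small_phantom()
  noisy <- add_rician_noise(ph, noise_model(15, seed = 5))
  dn <- denoise_volume(noisy, patch_spec())
  m <- dkiprep:::vol_mask(ph$truth)
  expect_true(all(dn$sigma_map[m] >= 0))
  nvol <- dim(ph$truth$data)[4]
  expect_true(all(dn$ncomponents_map[m] >= 0 &
                    dn$ncomponents_map[m] <= min(100, nvol)))
  expect_true(all(is.finite(dn$denoised$data)))
})

test_that("sigma recovery holds across two orders of magnitude", {
  gt <- mini_proto()
  nvol <- length(gt$bvals)
  for (sigma in c(0.1, 1, 10)) {
    arr <- withr::with_seed(1234, array(abs(rnorm(12 * 12 * 6 * nvol, 100, sigma)),
                                        c(12, 12, 6, nvol)))
    vol <- dwi_volume(arr, gt)
    dn <- denoise_volume(vol, patch_spec(search_window = 5))
    med <- median(dn$sigma_map)
    expect_lt(abs(med - sigma) / sigma, 0.10)
  }
})

test_that("fewer than 8 volumes triggers the reliability warning", {
  gt <- gradient_table(c(0, rep(1000, 6)),
                       rbind(matrix(0, 1, 3), dkiprep:::sphere_spiral(6)))
  vol <- dwi_volume(array(runif(5 * 5 * 5 * 7, 1, 2), c(5, 5, 5, 7)), gt)
  expect_warning(denoise_volume(vol, patch_spec(patch_size = 10,
                                                search_window = 2)),
                 "unreliable")
})

test_that("Rician bias correction implements the method of moments", {
  expect_equal(rician_bias_correct(array(5, c(1, 1, 1, 1)),
                                   array(3, c(1, 1, 1)))[1], 4)
  arr <- array(runif(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  expect_identical(rician_bias_correct(arr, array(0, c(4, 4, 4))), arr)
  expect_error(rician_bias_correct(arr, array(-1, c(4, 4, 4))),
               "non-negative")

  # analytic Rician-moments oracle at Sr = 0, sigma = 1: M^2 ~ 2 Exp(1/2),
  # E[max(M^2 - 1, 0)] = 2 exp(-1/2); the uncorrected second moment is 2
  set.seed(99)
  n <- 1e5
  M <- sqrt(rnorm(n)^2 + rnorm(n)^2)
  corr <- rician_bias_correct(array(M, c(n, 1, 1, 1)), array(1, c(n, 1, 1)))
  expect_equal(mean(corr^2), 2 * exp(-0.5), tolerance = 0.02)
  # bias toward sigma^2 is reduced relative to the uncorrected 2 sigma^2
  expect_lt(abs(mean(corr^2) - 1), abs(mean(M^2) - 1))
})
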