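# 1D band-limited step: ideal step rendered through truncated Fourier
# coefficients (the classic Gibbs configuration)
gibbs_step_1d <- function(n = 64, hi = 512, lo = 0, hi_val = 1) {
  x <- c(rep(lo, hi / 2), rep(hi_val, hi / 2))
  F <- fft(x)
  keep <- c(1:(n / 2 + 1), (hi - (n / 2 - 1) + 1):hi)
  Re(fft(F[keep] * (n / hi), inverse = TRUE)) / n
}

test_that("constant images are untouched and parameters are validated", {
  p <- unring_params()
  img <- matrix(7, 32, 32)
  expect_equal(sushi_unring(img, p), img, tolerance = 1e-12)
  expect_error(unring_params(nshifts = 1), "nshifts")
  expect_error(unring_params(k1 = 3, k2 = 3), "k1")
  expect_error(unring_params(pf_fraction = 5 / 8), "5/8")
  expect_error(unring_params(pf_fraction = 0.9), "pf_fraction")
  expect_error(sushi_unring(matrix(c(1, NA, 1, 1), 2, 2), p), "finite")
})

test_that("unringing lowers total variation around a truncated step edge", {
  lo <- gibbs_step_1d()
  un <- dkiprep:::.unring_cols_cpp(cbind(lo), 20L, 1L, 3L)[, 1]
  band <- (32 - 3):(32 + 3)
  expect_lt(tv(un[band]), tv(lo[band]))
})

test_that("smooth band-limited signals are preserved", {
  n <- 64
  s <- 3 + sin(2 * pi * 2 * (0:(n - 1)) / n)
  un <- dkiprep:::.unring_cols_cpp(cbind(s), 20L, 1L, 3L)[, 1]
  expect_lt(sqrt(mean((un - s)^2)) / sqrt(mean(s^2)), 0.01)
})

test_that("partial-Fourier handling: delegation, support and rejection", {
  img <- gibbs_step_1d(32) %o% rep(1, 8)
  p1 <- unring_params(pf_fraction = 1, pe_axis = 1)
  expect_identical(rpg_unring(img, p1), sushi_unring(img, p1))
  for (pf in c(6 / 8, 7 / 8)) {
    pp <- unring_params(pf_fraction = pf, pe_axis = 1)
    out <- rpg_unring(img, pp)
    expect_identical(dim(out), dim(img))
  }
  expect_error(unring_params(pf_fraction = 5 / 8), "smoothed")
})

test_that("RPG beats SuShi on the 6/8 partial-Fourier Shepp-Logan phantom", {
  gt <- gradient_table(c(0, 1000, 2000),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  sh <- make_shepp_logan_dmri(128, gt, pf_fraction = 6 / 8)
  p <- unring_params(pf_fraction = 6 / 8, pe_axis = 1)
  msk <- rep(dkiprep:::vol_mask(sh$ringing), 3)
  truth <- sh$clean$truth$data
  su <- sushi_unring(sh$ringing$data, p)
  rp <- rpg_unring(sh$ringing$data, p)
  rms <- function(a) sqrt(mean((a - truth)[msk]^2))
  expect_lt(rms(su), rms(sh$ringing$data))
  expect_lt(rms(rp), rms(su))
  # DC preservation: image mean moves by well under half a percent
  expect_lt(abs(mean(su) - mean(sh$ringing$data)) / mean(sh$ringing$data), 0.005)
  expect_lt(abs(mean(rp) - mean(sh$ringing$data)) / mean(sh$ringing$data), 0.005)
})

test_that("repeated unringing does not run away", {
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  sh <- make_shepp_logan_dmri(128, gt, pf_fraction = 1)
  p <- unring_params(pf_fraction = 1, pe_axis = 1)
  x <- sh$ringing$data
  s1 <- sushi_unring(x, p)
  s2 <- sushi_unring(s1, p)
  s3 <- sushi_unring(s2, p)
  d1 <- sqrt(mean((s1 - x)^2))
  d2 <- sqrt(mean((s2 - s1)^2))
  d3 <- sqrt(mean((s3 - s2)^2))
  # successive changes decay monotonically (edge voxels keep being
  # re-interpolated, but the corrections shrink rather than grow)
  expect_lt(d2, d1)
  expect_lt(d3, d2)

  # a smooth ringing-free image is left close to untouched
  g <- outer(exp(-((1:64 - 24)^2) / 200), exp(-((1:64 - 40)^2) / 300)) * 100
  g1 <- sushi_unring(g, p)
  expect_lt(sqrt(mean((g1 - g)^2)) / sqrt(mean(g^2)), 0.01)
})
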