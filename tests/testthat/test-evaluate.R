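test_that("percentage error maps are signed and flag zero truth", {
  truth <- array(2, c(3, 3, 3))
  expect_true(all(percent_error_map(truth, truth) == 0))
  expect_true(all(percent_error_map(1.1 * truth, truth) - 10 < 1e-12))
  z <- truth; z[1, 1, 1] <- 0
  pe <- percent_error_map(truth, z)
  expect_true(is.na(pe[1, 1, 1]))
  expect_error(percent_error_map(truth, array(1, c(2, 2, 2))), "differ")
})

test_that("the median over realizations is outlier-robust and variance-reducing", {
  m1 <- array(1, c(2, 2, 2)); m2 <- array(2, c(2, 2, 2)); m3 <- array(100, c(2, 2, 2))
  expect_equal(median_over_realizations(list(m1, m2, m3)), m2)
  expect_equal(median_over_realizations(list(m1)), m1)
  expect_error(median_over_realizations(list()), "no maps")

  set.seed(8)
  maps <- lapply(1:21, function(i) array(rnorm(64), c(4, 4, 4)))
  med <- median_over_realizations(maps)
  expect_lt(var(c(med)), min(vapply(maps, function(m) var(c(m)), numeric(1))))
})

test_that("CSF-excluded smoothing implements normalized masked convolution", {
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  const <- dwi_volume(array(3, c(9, 9, 9, 2)), gt)
  sm <- gaussian_smooth_csf_excluded(const, 1.2, csf_mask = NULL)
  expect_equal(sm$data, const$data, tolerance = 1e-12)

  # unit impulse reproduces the truncated discrete Gaussian with
  # sigma = FWHM / (2 sqrt(2 log 2)) per axis
  arr <- array(0, c(15, 15, 15, 1)); arr[8, 8, 8, 1] <- 1
  out <- gaussian_smooth_csf_excluded(arr, 1.2)
  sig <- 1.2 / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sig))
  k <- exp(-(-r:r)^2 / (2 * sig^2)); k <- k / sum(k)
  expect_equal(out[8 + (-r:r), 8, 8, 1], k * k[r + 1]^2, tolerance = 1e-12)

  # CSF voxels neither receive nor contribute
  csf <- array(FALSE, c(15, 15, 15)); csf[9, 8, 8] <- TRUE
  arr2 <- array(1, c(15, 15, 15, 1)); arr2[9, 8, 8, 1] <- 1000
  out2 <- gaussian_smooth_csf_excluded(arr2, 1.2, csf)
  expect_equal(out2[9, 8, 8, 1], 1000)        # untouched
  expect_equal(out2[8, 8, 8, 1], 1, tolerance = 1e-9)  # big value kept out
  expect_error(gaussian_smooth_csf_excluded(arr2, 0), "positive")
})

test_that("quadratic age fits classify curvature and inflection correctly", {
  x <- seq(25, 75, by = 2)
  f <- quadratic_age_fit(x, -(x - 50)^2 + 30)
  expect_equal(f$concavity, "concave")
  expect_equal(f$inflection_age, 50, tolerance = 1e-8)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-8)
  expect_lt(f$bonferroni_p, 1e-10)

  g <- quadratic_age_fit(x, 2 * x + 1)
  expect_equal(g$concavity, "monotone-increasing")
  expect_true(is.na(g$inflection_age))
  h <- quadratic_age_fit(x, -0.5 * x + 100)
  expect_equal(h$concavity, "monotone-decreasing")

  # adjusted R^2 equals the textbook formula on a noisy fixture
  set.seed(12)
  y <- 0.002 * (x - 40)^2 + rnorm(length(x), sd = 0.6)
  q <- quadratic_age_fit(x, y)
  fit <- lm(y ~ x + I(x^2))
  r2 <- summary(fit)$r.squared
  n <- length(x)
  expect_equal(q$adjusted_r2, 1 - (1 - r2) * (n - 1) / (n - 3),
               tolerance = 1e-10)
  # Bonferroni cap and scaling
  expect_equal(q$bonferroni_p, min(1, q$p_value * 28))
  expect_gte(q$bonferroni_p, q$p_value)
  expect_error(quadratic_age_fit(c(50, 50, 50, 50), 1:4), "degenerate")
  expect_error(quadratic_age_fit(c(25, 75), c(1, 2)), "4 points")
})

test_that("benchmark configuration errors are caught", {
  expect_error(run_denoise_benchmark(small_phantom(), snrs = 20,
                                     conditions = "magic", nreps = 1),
               "unknown condition")
  expect_error(run_gibbs_benchmark(conditions = "magic"),
               "unknown condition")
})
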