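test_that("ROI noise matches known fields and validates its inputs", {
  flat <- as_test_image(matrix(3.2, 128, 128))
  big_roi <- roi_circle(0, 0, 10)
  expect_equal(roi_noise(flat, big_roi), 0)
  set.seed(11)
  gauss <- as_test_image(matrix(rnorm(128 * 128, 50, 10), 128, 128))
  n_vox <- length(roi_pixels(gauss, roi_circle(0, 0, 16)))
  expect_gt(n_vox, 9000)
  expect_equal(roi_noise(gauss, roi_circle(0, 0, 16)), 10, tolerance = 0.03)
  expect_error(roi_noise(flat, roi_circle(0, 0, 19)), "outside")
  expect_error(roi_noise(flat, roi_circle(0, 0, 0.5)), "at least")
  # denoising reduces measured ROI noise
  expect_lt(roi_noise(denoise(gauss, 1), big_roi),
            roi_noise(gauss, big_roi))
})

test_that("contrast is a difference of ROI means with overlap protection", {
  set.seed(4)
  img <- as_test_image(matrix(rnorm(128 * 128, 0, 1), 128, 128))
  roi_a <- roi_circle(-8, 0, 3)
  roi_b <- roi_circle(8, 0, 3)
  expect_equal(roi_contrast(img, roi_a, roi_b),
               mean(roi_pixels(img, roi_a)) - mean(roi_pixels(img, roi_b)))
  expect_identical(roi_contrast(img, roi_a, roi_a), 0)
  expect_error(roi_contrast(img, roi_a, roi_circle(-7, 0, 3)), "overlap")
})

test_that("the Hotelling template solves the pooled-covariance system", {
  set.seed(21)
  A <- matrix(rnorm(4000), ncol = 2)
  B <- matrix(rnorm(4000), ncol = 2)
  # equal means give the zero template
  w0 <- hotelling_template(A, A + matrix(0, nrow(A), 2))
  expect_equal(w0, c(0, 0))
  # direct 2x2 inversion oracle
  B2 <- sweep(B, 2, c(2, -1), "+")
  S <- (stats::cov(A) + stats::cov(B2)) / 2
  Sr <- S + 1e-6 * sum(diag(S)) / 2 * diag(2)
  dmu <- colMeans(A) - colMeans(B2)
  oracle <- c(solve(Sr) %*% dmu)
  expect_equal(hotelling_template(A, B2), oracle, tolerance = 1e-10)
  # near-identity pooled covariance returns roughly the mean difference
  expect_equal(hotelling_template(A, B2), dmu, tolerance = 0.15)
  expect_error(hotelling_template(A[1, , drop = FALSE], B2), "at least 2")
  expect_error(hotelling_template(A, B2[, 1, drop = FALSE]), "same number")
})

test_that("separability matches the closed-form Gaussian dprime", {
  # classes N((0,0), I) and N((3,4), I): dprime = sqrt(3^2+4^2) = 5
  set.seed(31)
  n <- 1e5
  A <- matrix(rnorm(2 * n), ncol = 2)
  B <- cbind(rnorm(n, 3), rnorm(n, 4))
  res <- separability_index(A, B)
  expect_equal(res$s_prime, 5, tolerance = 0.01)   # bias < 2% at n = 1e5
  expect_equal(abs(res$lambda_mean_A - res$lambda_mean_B) /
                 sqrt(0.5 * (res$lambda_var_A + res$lambda_var_B)),
               res$s_prime)
})

test_that("separability is symmetric, affine invariant, and null-calibrated", {
  set.seed(41)
  A <- matrix(rnorm(2e4), ncol = 2)
  B <- sweep(matrix(rnorm(2e4), ncol = 2), 2, c(1, 0.5), "+")
  expect_identical(separability_index(A, B)$s_prime,
                   separability_index(B, A)$s_prime)
  # population-level invariance on the closed form
  S <- diag(2); dmu <- c(1, 0.5)
  M <- matrix(c(2, 0.3, -0.5, 1.1), 2)
  d_pop <- sqrt(drop(t(dmu) %*% solve(S) %*% dmu))
  d_pop_t <- sqrt(drop(t(M %*% dmu) %*% solve(M %*% S %*% t(M)) %*%
                         (M %*% dmu)))
  expect_equal(d_pop, d_pop_t, tolerance = 1e-9)
  # sample version within sampling error
  s0 <- separability_index(A, B)$s_prime
  s1 <- separability_index(A %*% t(M), B %*% t(M))$s_prime
  expect_equal(s1, s0, tolerance = 0.02)
  # identical distributions: index stays near zero
  set.seed(42)
  nulls <- replicate(20, {
    X <- matrix(rnorm(2e4), ncol = 2)
    Y <- matrix(rnorm(2e4), ncol = 2)
    separability_index(X, Y)$s_prime
  })
  expect_lt(stats::quantile(nulls, 0.95), 0.2)
  expect_error(separability_index(A[1, , drop = FALSE], B), "at least 2")
})

test_that("roi_vectors pairs voxels across matched bin images", {
  set.seed(5)
  lo <- as_test_image(matrix(rnorm(64 * 64), 64, 64))
  hi <- as_test_image(matrix(rnorm(64 * 64), 64, 64))
  v <- roi_vectors(list(low = lo, high = hi), roi_circle(0, 0, 4))
  expect_equal(colnames(v), c("low", "high"))
  expect_equal(v[, "low"], roi_pixels(lo, roi_circle(0, 0, 4)))
  expect_error(
    roi_vectors(list(lo, as_test_image(matrix(0, 64, 64),
                                       pixel_size_mm = 5)),
                roi_circle(0, 0, 4)),
    "common grid")
})
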