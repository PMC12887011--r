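test_that("FBP of a uniform noise-free water disk is flat at the effective mu", {
  pr <- test_protocol(n_views = 180, n_channels = 129, fov_cm = 24,
                      grid_size = 96, pixel_size_mm = 2.5)
  ph <- tiny_phantom(radius = 8, insert_r = 1)
  sino <- simulate_sinogram(ph, pr, "low", noise_free = TRUE)
  img <- fbp(sino)
  # interior (excluding a 2-pixel rim, i.e. 0.5 cm inside the edge)
  interior <- roi_pixels(img, roi_circle(0, 0, 7.0))
  expect_lt(stats::sd(interior) / mean(interior), 0.02)
  expect_gt(mean(interior), 0.15)   # about the effective water mu, 1/cm
  expect_lt(mean(interior), 0.40)
})

test_that("FBP is linear and maps a zero sinogram to a zero image", {
  pr <- test_protocol(n_views = 24, n_channels = 33, grid_size = 32,
                      pixel_size_mm = 8)
  ph <- tiny_phantom("Gd", 4, radius = 8, insert_r = 2)
  sino <- simulate_sinogram(ph, pr, "low", noise_free = TRUE)
  zero <- sino; zero[] <- 0
  expect_equal(max(abs(fbp(zero))), 0)
  expect_equal(unclass(fbp(structure(unclass(sino) * 3.7,
                                     class = class(sino),
                                     bin_keV = attr(sino, "bin_keV"),
                                     protocol = attr(sino, "protocol")))),
               unclass(fbp(sino)) * 3.7, tolerance = 1e-10)
})

test_that("reprojecting a reconstructed disk reproduces the sinogram", {
  pr <- test_protocol(n_views = 90, n_channels = 65, fov_cm = 20,
                      grid_size = 64, pixel_size_mm = 3.125)
  ph <- tiny_phantom(radius = 6, insert_r = 1)
  sino <- simulate_sinogram(ph, pr, "low", noise_free = TRUE)
  img <- fbp(sino)
  look <- image_lookup(img)
  ds <- pr$fov_cm / pr$n_channels
  s_off <- (seq_len(pr$n_channels) - (pr$n_channels + 1) / 2) * ds
  keep <- abs(s_off) < 5.5            # exclude edge channels
  for (j in c(1, 30, 60)) {
    th <- (j - 1) * pi / pr$n_views
    rep_p <- sapply(s_off[keep], function(s)
      sample_line_integral(look, th, s, 10, step = 0.05))
    rms <- sqrt(mean((rep_p - sino[j, keep])^2)) /
      sqrt(mean(sino[j, keep]^2))
    expect_lt(rms, 0.03)
  }
})

test_that("HU calibration maps water to 0 and air to -1000 by definition", {
  cal <- list(mu_water_eff = 0.21, mu_air_eff = 0.0002)
  img <- as_test_image(matrix(c(0.21, 0.0002, 0.25), 1, 3))
  hu <- calibrate_hu(img, cal)
  expect_equal(hu[1, 1], 0)
  expect_equal(hu[1, 2], -1000)
  expect_gt(hu[1, 3], 0)
  expect_error(calibrate_hu(img, list(mu_water_eff = 0.1, mu_air_eff = 0.2)),
               "degenerate")
})

test_that("noise-free calibrated phantom hits water and air anchor values", {
  sw <- nf_sweep()
  # background water ROI within +/- 5 HU of zero at every threshold/bin
  bgs <- unique(sw$metrics[, c("threshold_keV", "bin")])
  expect_equal(nrow(bgs), 18)
  pr <- test_protocol()
  ph <- kedge_phantom()
  sp <- make_spectrum(kV = pr$kV, filtration_mm_al = pr$filtration_mm_al,
                      n0 = pr$n0)
  sino <- simulate_sinogram(ph, pr, "low", noise_free = TRUE, spectrum = sp)
  sino <- correct_water_hardening(sino, sp)
  img <- calibrate_hu(fbp(sino), bin_calibration(pr, "low", spectrum = sp))
  expect_lt(abs(mean(roi_pixels(img, roi_circle(0, 0, 2)))), 5)
  # air outside the cylinder reads about -1000 HU
  expect_equal(mean(roi_pixels(img, roi_circle(0, 16.5, 1))), -1000,
               tolerance = 0.01)
})

test_that("water-control insert reads near zero in every image", {
  sw <- nf_sweep()
  wc <- sw$metrics[sw$metrics$material == "water", ]
  expect_equal(nrow(wc), 18)
  expect_true(all(abs(wc$contrast_HU) < 5))
})

test_that("Gaussian denoising is the identity at sigma 0 and preserves DC", {
  m <- matrix(rnorm(64 * 64, mean = 40, sd = 12), 64, 64)
  img <- as_test_image(m)
  expect_identical(as.vector(unclass(denoise(img, 0))), as.vector(m))
  flat <- as_test_image(matrix(7.5, 40, 40))
  expect_equal(as.vector(unclass(denoise(flat, 2))), rep(7.5, 1600),
               tolerance = 1e-12)
  # noise strictly decreases with increasing sigma
  sds <- sapply(c(0, 1, 2), function(sg)
    stats::sd(unclass(denoise(img, sg))[10:54, 10:54]))
  expect_true(all(diff(sds) < 0))
  expect_error(denoise(img, -1), "sigma")
})

test_that("beam hardening lowers the central-ray effective mu below the
           incident mean-energy value, and the correction flattens water", {
  pr <- test_protocol(n_views = 12, n_channels = 61)
  ph <- tiny_phantom(radius = 15, insert_r = 1)
  sp <- make_spectrum(kV = pr$kV, filtration_mm_al = pr$filtration_mm_al,
                      n0 = pr$n0)
  sino <- simulate_sinogram(ph, pr, "low", noise_free = TRUE, spectrum = sp)
  mu_eff_central <- max(sino) / 30          # central path of 30 cm
  idx <- sp$energy_keV >= 20 & sp$energy_keV < 50
  mean_E <- sum(sp$energy_keV[idx] * sp$fluence[idx]) / sum(sp$fluence[idx])
  expect_lt(mu_eff_central, water_mu_rho(mean_E))
  # after linearization the water sinogram is proportional to thickness
  corr <- correct_water_hardening(sino, sp)
  th <- 0; s_off <- (seq_len(61) - 31) * pr$fov_cm / 61
  chord <- chord_length(0, 0, 15, th, s_off)
  ratio <- corr[1, chord > 5] / chord[chord > 5]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.01)
})
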