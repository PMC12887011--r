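# construct a minimal synthetic kedge_sweep for the argmax helpers
fake_sweep <- function(metrics, separability = NULL) {
  argmax <- NULL
  if (!is.null(separability)) {
    sp <- split(separability,
                paste(separability$material_A, separability$material_B))
    argmax <- dplyr::bind_rows(lapply(sp, function(d) {
      d <- d[order(d$threshold_keV), ]
      tibble::tibble(material_A = d$material_A[1],
                     material_B = d$material_B[1],
                     best_threshold_keV = d$threshold_keV[which.max(d$s_prime)],
                     peak_s_prime = max(d$s_prime))
    }))
  }
  structure(list(metrics = metrics, separability = separability,
                 argmax = argmax, phantom = NULL,
                 config = list(thresholds = unique(metrics$threshold_keV),
                               noise_free = TRUE),
                 images = NULL),
            class = "kedge_sweep")
}

test_that("sweep covers every threshold, bin, material, and pair", {
  sw <- nf_sweep()
  expect_equal(sort(unique(sw$metrics$threshold_keV)), seq(50, 90, 5))
  expect_equal(nrow(sw$metrics), 9 * 2 * 16)
  expect_equal(nrow(sw$separability), 9 * choose(15, 2))
  expect_equal(nrow(sw$argmax), 105)
  expect_equal(sort(unique(sw$metrics$bin)), c("high", "low"))
})

test_that("repeated runs with the same configuration are identical", {
  ph <- kedge_phantom()
  pr <- test_protocol(n_views = 40, n_channels = 61, grid_size = 64,
                      pixel_size_mm = 5.5)
  cals <- sweep_calibrations(pr, thresholds = c(50, 70),
                             background_radius_cm = 15)
  args <- list(phantom = ph, thresholds = c(50, 70), protocol = pr,
               seed = 7L, calibrations = cals, background_roi_cm = 4)
  s1 <- do.call(run_sweep, args)
  s2 <- do.call(run_sweep, args)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$separability, s2$separability)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  utils::write.csv(s1$metrics, f1, row.names = FALSE)
  utils::write.csv(s2$metrics, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("peak_threshold takes the argmax and breaks ties downward", {
  m <- tidyr::expand_grid(threshold_keV = seq(50, 90, 5), bin = "high",
                          material = "X")
  m$contrast_HU <- seq_len(9)            # strictly increasing
  m$noise_HU <- 1
  expect_equal(peak_threshold(fake_sweep(m), "X", "high"), 90)
  m2 <- m; m2$contrast_HU <- c(1, 5, 5, 5, 4, 3, 2, 1, 0)  # tied plateau
  expect_equal(peak_threshold(fake_sweep(m2), "X", "high"), 55)
  expect_error(peak_threshold(fake_sweep(m), "Y", "high"), "unknown")
})

test_that("best_separation_threshold agrees with brute force and is symmetric", {
  set.seed(9)
  th <- seq(50, 90, 5)
  # two synthetic materials whose contrast curves cross once
  cA <- seq(100, 20, length.out = 9)
  cB <- seq(20, 100, length.out = 9)
  sep <- tibble::tibble(threshold_keV = th, material_A = "A",
                        material_B = "B",
                        s_prime = abs(cA - cB) / 10, sign = 1)
  sw <- fake_sweep(
    tidyr::expand_grid(threshold_keV = th, bin = c("low", "high"),
                       material = c("A", "B")) |>
      dplyr::mutate(contrast_HU = 0, noise_HU = 1),
    sep)
  brute <- th[which.max(abs(cA - cB))]
  expect_equal(best_separation_threshold(sw, "A", "B"), brute)
  expect_equal(best_separation_threshold(sw, "B", "A"), brute)
  expect_error(best_separation_threshold(sw, "A", "A"), "undefined")
  expect_error(best_separation_threshold(sw, "A", "C"), "no separability")
})

test_that("the pairwise matrices are symmetric with empty diagonal", {
  sw <- nf_sweep()
  M <- separation_matrix(sw, "threshold")
  expect_identical(M, t(M))
  expect_true(all(is.na(diag(M))))
  expect_equal(dim(M), c(15, 15))
  S <- separation_matrix(sw, "s_prime")
  expect_identical(S, t(S))
  expect_true(all(S[upper.tri(S)] > 0))
})

test_that("reports persist, reject empty input, and re-render from CSV", {
  sw <- nf_sweep()
  dir <- withr::local_tempdir()
  paths <- render_report(sw, dir, figures = FALSE)
  expect_true(all(file.exists(paths)))
  sw2 <- render_report_from_csv(dir)
  expect_equal(sw2$metrics$contrast_HU, sw$metrics$contrast_HU,
               tolerance = 1e-12)
  expect_equal(sw2$argmax$best_threshold_keV, sw$argmax$best_threshold_keV)
  empty <- fake_sweep(sw$metrics[0, ], sw$separability[0, ])
  expect_error(render_report(empty, dir), "empty")
})

test_that("tidy, glance, and autoplot expose the sweep tables", {
  sw <- nf_sweep()
  expect_identical(tidy(sw), sw$metrics)
  expect_identical(tidy(sw, "separability"), sw$separability)
  g <- glance(sw)
  expect_equal(g$n_pairs, 105)
  expect_true(g$noise_free)
  for (ty in c("noise", "contrast", "separability", "matrix")) {
    expect_s3_class(autoplot(sw, type = ty), "ggplot")
  }
})

test_that("sinograms and images survive a TIFF round trip", {
  pr <- test_protocol(n_views = 10, n_channels = 21, seed = 3)
  ph <- tiny_phantom("I", 4, radius = 8, insert_r = 2)
  sino <- simulate_sinogram(ph, pr, "low")
  f <- withr::local_tempfile(fileext = ".tif")
  write_sinogram_tiff(sino, f)
  s2 <- read_sinogram_tiff(f)
  expect_equal(unclass(s2), unclass(sino), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(attr(s2, "bin_keV"), attr(sino, "bin_keV"))
  img <- fbp(sino, grid_size = 24, pixel_size_mm = 8)
  fi <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img, fi)
  i2 <- read_image_tiff(fi)
  expect_equal(unclass(i2), unclass(img), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(attr(i2, "pixel_size_mm"), attr(img, "pixel_size_mm"))
})
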