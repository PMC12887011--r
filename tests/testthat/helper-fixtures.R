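# shared fixtures, computed lazily and memoized across test files
.fixtures <- new.env()

# reduced-resolution protocol used throughout the suite
test_protocol <- function(high = 50, ...) {
  protocol_preset("test", high_threshold_keV = high, ...)
}

# noise-free threshold sweep of the 16-insert study phantom
nf_sweep <- function() {
  if (is.null(.fixtures$nf_sweep)) {
    .fixtures$nf_sweep <- run_sweep(noise_free = TRUE)
  }
  .fixtures$nf_sweep
}

shared_calibrations <- function() {
  if (is.null(.fixtures$cals)) {
    .fixtures$cals <- sweep_calibrations(test_protocol())
  }
  .fixtures$cals
}

# seeded noisy replicate sweeps (Poisson noise + default denoising)
noisy_sweeps <- function(n = 6, base_seed = 20260923) {
  key <- sprintf("noisy_%d_%d", n, base_seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- lapply(seq_len(n), function(k) {
      run_sweep(seed = base_seed + k, calibrations = shared_calibrations())
    })
  }
  .fixtures[[key]]
}

# replicate-averaged water-background noise per threshold and bin
mean_noise_table <- function(sweeps) {
  tab <- do.call(rbind, lapply(sweeps, function(s) {
    unique(s$metrics[, c("threshold_keV", "bin", "noise_HU")])
  }))
  stats::aggregate(noise_HU ~ threshold_keV + bin, tab, mean)
}

# tiny phantom: one centered disk of the given material in a small water
# cylinder, for fast projection/recon oracles
tiny_phantom <- function(solute = NA_character_, conc = 0, radius = 8,
                         insert_r = 2) {
  ins <- tibble::tibble(label = ifelse(is.na(solute), "water", solute),
                        x_cm = 0, y_cm = 0, radius_cm = insert_r,
                        solute = solute, concentration_mg_per_mL = conc)
  ct_phantom(ins, background_radius_cm = radius)
}

# image-domain line integrals by dense point sampling: independent oracle
# for chord lengths and for FBP-forward consistency
sample_line_integral <- function(img_fun, theta, s, half_extent,
                                 step = 0.01) {
  t_seq <- seq(-half_extent, half_extent, by = step)
  x <- s * cos(theta) - t_seq * sin(theta)
  y <- s * sin(theta) + t_seq * cos(theta)
  sum(img_fun(x, y)) * step
}

# bilinear interpolation lookup into a recon_image, zero outside
image_lookup <- function(image) {
  px <- attr(image, "pixel_size_mm") / 10
  g <- nrow(image)
  ctr <- (seq_len(g) - (g + 1) / 2) * px
  m <- unclass(image)
  function(x, y) {
    ix <- (x - ctr[1]) / px + 1
    iy <- (y - ctr[1]) / px + 1
    i0 <- floor(ix); j0 <- floor(iy)
    fx <- ix - i0; fy <- iy - j0
    val <- numeric(length(x))
    ok <- i0 >= 1 & i0 < g & j0 >= 1 & j0 < g
    i <- i0[ok]; j <- j0[ok]
    val[ok] <- m[cbind(i, j)] * (1 - fx[ok]) * (1 - fy[ok]) +
      m[cbind(i + 1, j)] * fx[ok] * (1 - fy[ok]) +
      m[cbind(i, j + 1)] * (1 - fx[ok]) * fy[ok] +
      m[cbind(i + 1, j + 1)] * fx[ok] * fy[ok]
    val
  }
}

# wrap a plain matrix as a recon_image for metrology tests
as_test_image <- function(m, pixel_size_mm = 2.8125) {
  structure(m, class = "recon_image", pixel_size_mm = pixel_size_mm,
            bin_keV = c(20, 50), protocol = NULL, units = "HU")
}
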