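# pixel center coordinates (cm) of a centered square grid
.pixel_centers_cm <- function(grid_size, pixel_size_cm) {
  (seq_len(grid_size) - (grid_size + 1) / 2) * pixel_size_cm
}

.as_recon_image <- function(pixels, template = NULL, units = "HU",
                            pixel_size_mm = NULL, bin_keV = NULL,
                            protocol = NULL) {
  structure(pixels, class = "recon_image",
            pixel_size_mm = pixel_size_mm %||% attr(template, "pixel_size_mm"),
            bin_keV = bin_keV %||% attr(template, "bin_keV"),
            protocol = protocol %||% attr(template, "protocol"),
            units = units)
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %d x %d px at %g mm, units %s\n",
              nrow(x), ncol(x), attr(x, "pixel_size_mm"), attr(x, "units")))
  invisible(x)
}

# Ram-Lak (ramp) filter of one sinogram, rows = views.  FFT-based circular
# convolution with the standard band-limited discrete ramp kernel.
.ramp_filter <- function(sino, ds) {
  nch <- ncol(sino)
  nfft <- 2^ceiling(log2(2 * nch))
  k <- c(0:(nfft / 2), -(nfft / 2 - 1):-1)
  h <- numeric(nfft)
  h[k == 0] <- 1 / (4 * ds^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd] * ds)^2
  H <- Re(stats::fft(h))
  pad <- matrix(0, nrow(sino), nfft)
  pad[, seq_len(nch)] <- sino
  ft <- stats::mvfft(t(pad))
  filt <- Re(stats::mvfft(ft * H, inverse = TRUE)) / nfft
  t(filt)[, seq_len(nch), drop = FALSE] * ds
}

#' Filtered back projection (parallel beam)
#'
#' Reconstructs a linear-attenuation image (1/cm) from a log-normalized
#' parallel-beam sinogram: Ram-Lak ramp filtering of each view followed by
#' linearly interpolated backprojection over 180 degrees.
#'
#' @param sinogram A `binned_sinogram` (views x channels).
#' @param grid_size Output image size in pixels; defaults to the
#'   protocol's reconstruction grid.
#' @param pixel_size_mm Pixel pitch in mm; defaults likewise.
#' @return A `recon_image` in units of 1/cm.
#' @export
fbp <- function(sinogram, grid_size = NULL, pixel_size_mm = NULL) {
  protocol <- attr(sinogram, "protocol")
  grid_size <- grid_size %||% protocol$grid_size
  pixel_size_mm <- pixel_size_mm %||% protocol$pixel_size_mm
  n_views <- nrow(sinogram)
  n_channels <- ncol(sinogram)
  if (!is.null(protocol) &&
      (n_views != protocol$n_views || n_channels != protocol$n_channels)) {
    abort("sinogram dimensions do not match its protocol geometry")
  }
  ds <- if (!is.null(protocol)) protocol$fov_cm / n_channels else
    stop("`sinogram` lacks a protocol; cannot infer channel spacing")
  s <- (seq_len(n_channels) - (n_channels + 1) / 2) * ds
  th <- (seq_len(n_views) - 1) * pi / n_views
  q <- .ramp_filter(unclass(sinogram), ds)
  px_cm <- pixel_size_mm / 10
  ctr <- .pixel_centers_cm(grid_size, px_cm)
  X <- matrix(ctr, grid_size, grid_size)
  Y <- matrix(ctr, grid_size, grid_size, byrow = TRUE)
  img <- matrix(0, grid_size, grid_size)
  for (j in seq_len(n_views)) {
    t_px <- X * cos(th[j]) + Y * sin(th[j])
    v <- stats::approx(s, q[j, ], xout = t_px, rule = 1)$y
    v[is.na(v)] <- 0
    img <- img + v
  }
  img <- img * pi / n_views
  .as_recon_image(img, units = "mu_per_cm", pixel_size_mm = pixel_size_mm,
                  bin_keV = attr(sinogram, "bin_keV"), protocol = protocol)
}

#' Water beam-hardening correction of a binned sinogram
#'
#' Polychromatic log projections of water are a concave function of
#' thickness, which cups the reconstruction.  This correction linearizes
#' them: the exact water curve \eqn{p(t) = -\ln \sum_E w_E e^{-\mu_w(E) t}
#' / \sum_E w_E} is computed for the bin's incident spectrum, inverted to
#' water-equivalent thickness, and rescaled as \eqn{p_{corr} = \mu_{ref}
#' t} with \eqn{\mu_{ref}} the incident-bin fluence-weighted water
#' attenuation, so a pure water object reconstructs uniformly.
#'
#' @param sinogram A `binned_sinogram`.
#' @param spectrum The incident `xray_spectrum` (defaults to the
#'   protocol's model).
#' @param max_thickness_cm Range of the linearization table (default 60).
#' @return The corrected `binned_sinogram` (attribute
#'   `water_corrected = TRUE`).
#' @export
correct_water_hardening <- function(sinogram, spectrum = NULL,
                                    max_thickness_cm = 60) {
  protocol <- attr(sinogram, "protocol")
  sp <- spectrum %||% make_spectrum(kV = protocol$kV,
                                    filtration_mm_al = protocol$filtration_mm_al,
                                    n0 = protocol$n0)
  edges <- attr(sinogram, "bin_keV")
  idx <- .bin_index(sp$energy_keV, edges[1], edges[2])
  w <- sp$fluence[idx]
  muw <- water_mu_rho(sp$energy_keV[idx])  # water density 1 g/cm^3
  t_grid <- seq(0, max_thickness_cm, by = 0.25)
  p_tab <- vapply(t_grid, function(t) -log(sum(w * exp(-muw * t)) / sum(w)),
                  numeric(1))
  mu_ref <- sum(w * muw) / sum(w)
  p <- unclass(sinogram)
  t_eq <- matrix(stats::approx(p_tab, t_grid, xout = pmax(p, 0),
                               rule = 2)$y, nrow(p), ncol(p))
  over <- p > max(p_tab)  # extend linearly beyond the table
  if (any(over)) {
    slope <- (t_grid[length(t_grid)] - t_grid[length(t_grid) - 1]) /
      (p_tab[length(p_tab)] - p_tab[length(p_tab) - 1])
    t_eq[over] <- max(t_grid) + (p[over] - max(p_tab)) * slope
  }
  p_corr <- mu_ref * t_eq
  p_corr[p < 0] <- p[p < 0]  # noise excursions below zero pass through
  out <- sinogram
  out[] <- p_corr
  attr(out, "water_corrected") <- TRUE
  out
}

#' Per-bin water/air Hounsfield calibration
#'
#' Reconstructs a noise-free water cylinder and a noise-free air scan
#' under the given protocol and bin, and measures the effective linear
#' attenuation of each in a central circular region.  These effective
#' values anchor the HU scale of that bin (they change with the
#' threshold, since the bin-weighted spectrum hardens as the bin narrows).
#'
#' @inheritParams expected_counts
#' @param background_radius_cm Radius of the calibration water cylinder;
#'   use the radius of the phantom under study (default 15).
#' @param roi_radius_cm Radius of the central measurement region.
#' @param water_transmission Optional precomputed [ray_transmission()] of
#'   the water cylinder (reusable across thresholds/bins).
#' @param water_bhc Apply [correct_water_hardening()] before
#'   reconstruction (default `TRUE`), matching the pipeline's default.
#' @return List with `mu_water_eff` and `mu_air_eff` (1/cm).
#' @export
bin_calibration <- function(protocol, bin = "low", spectrum = NULL,
                            background_radius_cm = 15, roi_radius_cm = 2,
                            water_transmission = NULL, water_bhc = TRUE) {
  water_ph <- ct_phantom(
    tibble(label = character(), x_cm = numeric(), y_cm = numeric(),
           radius_cm = numeric(), solute = character(),
           concentration_mg_per_mL = numeric()),
    background_radius_cm = background_radius_cm)
  sino_w <- simulate_sinogram(water_ph, protocol, bin, noise_free = TRUE,
                              spectrum = spectrum,
                              transmission = water_transmission)
  if (water_bhc) sino_w <- correct_water_hardening(sino_w, spectrum)
  img_w <- fbp(sino_w)
  sino_a <- structure(matrix(0, protocol$n_views, protocol$n_channels),
                      class = "binned_sinogram",
                      bin_keV = attr(sino_w, "bin_keV"),
                      protocol = protocol, noise_free = TRUE, seed = NULL)
  img_a <- fbp(sino_a)
  roi <- roi_circle(0, 0, roi_radius_cm)
  out <- list(mu_water_eff = mean(roi_pixels(img_w, roi)),
              mu_air_eff = mean(roi_pixels(img_a, roi)))
  if (out$mu_water_eff <= out$mu_air_eff) {
    abort("degenerate calibration: effective water mu <= air mu")
  }
  out
}

#' Convert an attenuation image to Hounsfield units
#'
#' \eqn{HU = 1000 (\mu - \mu_{water}) / (\mu_{water} - \mu_{air})} with
#' the bin-effective water and air attenuation from [bin_calibration()].
#'
#' @param image A `recon_image` in 1/cm.
#' @param calibration List with `mu_water_eff`, `mu_air_eff`.
#' @return A `recon_image` in HU.
#' @export
calibrate_hu <- function(image, calibration) {
  mw <- calibration$mu_water_eff
  ma <- calibration$mu_air_eff
  if (!is.finite(mw) || !is.finite(ma) || mw <= ma) {
    abort("degenerate calibration: effective water mu <= air mu")
  }
  hu <- 1000 * (unclass(image) - mw) / (mw - ma)
  .as_recon_image(hu, template = image, units = "HU")
}

#' Gaussian denoising
#'
#' Single-slice analog of volumetric Gaussian filtering: separable 2-D
#' Gaussian convolution with replicated edges.  `sigma_px = 0` is the
#' identity.
#'
#' @param image A `recon_image`.
#' @param sigma_px Gaussian standard deviation in pixels.
#' @return A `recon_image` with the same units.
#' @export
denoise <- function(image, sigma_px = 1) {
  if (sigma_px < 0) abort("`sigma_px` must be >= 0")
  if (sigma_px == 0) return(image)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  x <- unclass(image)
  n <- nrow(x); m <- ncol(x)
  xp <- x[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
  cv <- apply(xp, 2, function(col) stats::filter(col, k, sides = 2))
  cv <- cv[r + seq_len(n), , drop = FALSE]
  cp <- cv[, c(rep(1L, r), seq_len(m), rep(m, r)), drop = FALSE]
  rv <- t(apply(cp, 1, function(row) stats::filter(row, k, sides = 2)))
  out <- rv[, r + seq_len(m), drop = FALSE]
  .as_recon_image(out, template = image, units = attr(image, "units"))
}
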