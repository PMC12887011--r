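#' @importFrom dplyr filter arrange bind_rows group_by summarise mutate
#'   distinct
NULL

#' Precompute per-threshold HU calibrations
#'
#' [run_sweep()] recalibrates the HU scale for every threshold and bin
#' (the bin-effective water attenuation changes as the bin shifts).  The
#' calibrations depend only on the protocol geometry and spectrum, so
#' they can be computed once and shared across repeated noisy sweeps.
#'
#' @param protocol An `acquisition_protocol` (its high threshold is
#'   overridden per sweep point).
#' @param thresholds Upper thresholds in keV.
#' @param spectrum Optional `xray_spectrum`.
#' @param background_radius_cm Calibration cylinder radius.
#' @return Named list `"T<keV>.<bin>"` of [bin_calibration()] results.
#' @export
sweep_calibrations <- function(protocol, thresholds = seq(50, 90, by = 5),
                               spectrum = NULL, background_radius_cm = 15,
                               water_bhc = TRUE) {
  sp <- spectrum %||% make_spectrum(kV = protocol$kV,
                                    filtration_mm_al = protocol$filtration_mm_al,
                                    n0 = protocol$n0)
  water_ph <- ct_phantom(
    tibble(label = character(), x_cm = numeric(), y_cm = numeric(),
           radius_cm = numeric(), solute = character(),
           concentration_mg_per_mL = numeric()),
    background_radius_cm = background_radius_cm)
  proto0 <- protocol
  trans_w <- ray_transmission(water_ph, proto0, sp$energy_keV)
  out <- list()
  for (T in thresholds) {
    pT <- proto0; pT$high_threshold_keV <- T
    for (bin in c("low", "high")) {
      out[[sprintf("T%d.%s", T, bin)]] <-
        bin_calibration(pT, bin, spectrum = sp,
                        background_radius_cm = background_radius_cm,
                        water_transmission = trans_w, water_bhc = water_bhc)
    }
  }
  out
}

#' Run the two-bin threshold-sweep study
#'
#' For each upper threshold: simulates the low- and high-bin sinograms of
#' the phantom (Poisson-noisy unless `noise_free`), reconstructs by
#' filtered back projection, calibrates each bin to HU against a
#' noise-free water cylinder, optionally denoises, then measures
#' water-background noise, per-insert contrast, and the pairwise
#' Hotelling separability index for every unordered pair of contrast
#' materials.
#'
#' @param phantom A `ct_phantom`; defaults to the 16-insert study phantom.
#' @param thresholds Upper thresholds (keV), default `seq(50, 90, 5)`.
#' @param protocol An `acquisition_protocol` template; defaults to the
#'   reduced `"test"` preset.  Its high threshold is overridden per sweep
#'   point.
#' @param noise_free Simulate without Poisson noise (default `FALSE`).
#' @param denoise_sigma Gaussian denoising width in pixels applied to
#'   noisy reconstructions (default 1; noise-free runs skip denoising).
#' @param seed Base seed; per-threshold/bin seeds are derived from it.
#' @param insert_roi_fraction Insert ROI radius as a fraction of the
#'   insert radius (default 0.6).
#' @param background_roi_cm Radius of the central background ROI (cm).
#' @param calibrations Optional precomputed [sweep_calibrations()];
#'   must have been built with the same `water_bhc` setting.
#' @param water_bhc Apply the projection-domain water beam-hardening
#'   correction (default `TRUE`), the pipeline's analog of scanner
#'   air/water corrections.
#' @param keep_images Retain the calibrated images in the result.
#' @return An object of class `kedge_sweep` with tibbles `metrics`
#'   (threshold_keV, bin, material, contrast_HU, noise_HU), `separability`
#'   (threshold_keV, material_A, material_B, s_prime, sign), `argmax`
#'   (material_A, material_B, best_threshold_keV, peak_s_prime), and a
#'   `config` provenance list.
#' @export
run_sweep <- function(phantom = kedge_phantom(),
                      thresholds = seq(50, 90, by = 5),
                      protocol = protocol_preset("test", high_threshold_keV = 50),
                      noise_free = FALSE,
                      denoise_sigma = 1,
                      seed = NULL,
                      insert_roi_fraction = 0.6,
                      background_roi_cm = 2,
                      calibrations = NULL,
                      water_bhc = TRUE,
                      keep_images = FALSE) {
  t0 <- Sys.time()
  sp <- make_spectrum(kV = protocol$kV,
                      filtration_mm_al = protocol$filtration_mm_al,
                      n0 = protocol$n0)
  trans <- ray_transmission(phantom, protocol, sp$energy_keV)
  if (is.null(calibrations)) {
    calibrations <- sweep_calibrations(
      protocol, thresholds, spectrum = sp,
      background_radius_cm = phantom$background_radius_cm,
      water_bhc = water_bhc)
  }
  ins <- phantom$inserts
  insert_rois <- lapply(seq_len(nrow(ins)), function(i) {
    roi_circle(ins$x_cm[i], ins$y_cm[i], insert_roi_fraction * ins$radius_cm[i])
  })
  names(insert_rois) <- ins$label
  bg_roi <- roi_circle(0, 0, background_roi_cm)
  pair_materials <- ins$label[!is.na(ins$solute)]

  metrics <- list(); separ <- list(); images <- list()
  for (ti in seq_along(thresholds)) {
    T <- thresholds[ti]
    pT <- protocol; pT$high_threshold_keV <- T
    imgs <- list()
    for (bi in seq_along(c("low", "high"))) {
      bin <- c("low", "high")[bi]
      sd_seed <- if (is.null(seed)) NULL else seed + 101L * ti + bi
      sino <- simulate_sinogram(phantom, pT, bin, noise_free = noise_free,
                                spectrum = sp, transmission = trans,
                                seed = sd_seed)
      if (water_bhc) sino <- correct_water_hardening(sino, sp)
      cal <- calibrations[[sprintf("T%d.%s", T, bin)]]
      if (is.null(cal)) abort(sprintf("missing calibration for T=%d %s", T, bin))
      img <- calibrate_hu(fbp(sino), cal)
      if (!noise_free && denoise_sigma > 0) img <- denoise(img, denoise_sigma)
      imgs[[bin]] <- img
      noise <- roi_noise(img, bg_roi)
      contr <- vapply(insert_rois, function(r) roi_contrast(img, r, bg_roi),
                      numeric(1))
      metrics[[length(metrics) + 1L]] <- tibble(
        threshold_keV = T, bin = bin, material = names(insert_rois),
        contrast_HU = unname(contr), noise_HU = noise)
    }
    vecs <- lapply(insert_rois[pair_materials], function(r)
      roi_vectors(imgs, r))
    pairs <- utils::combn(pair_materials, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      res <- separability_index(vecs[[a]], vecs[[b]])
      separ[[length(separ) + 1L]] <- tibble(
        threshold_keV = T, material_A = a, material_B = b,
        s_prime = res$s_prime, sign = res$sign)
    }
    if (keep_images) images[[sprintf("T%d", T)]] <- imgs
  }
  metrics <- bind_rows(metrics)
  separ <- bind_rows(separ)
  argmax <- separ |>
    group_by(.data$material_A, .data$material_B) |>
    arrange(.data$threshold_keV, .by_group = TRUE) |>
    summarise(best_threshold_keV = .data$threshold_keV[which.max(.data$s_prime)],
              peak_s_prime = max(.data$s_prime), .groups = "drop")
  config <- list(
    thresholds = thresholds,
    n_views = protocol$n_views, n_channels = protocol$n_channels,
    fov_cm = protocol$fov_cm, grid_size = protocol$grid_size,
    pixel_size_mm = protocol$pixel_size_mm, n0 = protocol$n0,
    kV = protocol$kV, low_threshold_keV = protocol$low_threshold_keV,
    filtration_mm_al = protocol$filtration_mm_al,
    noise_free = noise_free, denoise_sigma = denoise_sigma, seed = seed,
    water_bhc = water_bhc,
    insert_roi_fraction = insert_roi_fraction,
    background_roi_cm = background_roi_cm,
    n_inserts = nrow(ins),
    package_version = as.character(utils::packageVersion("kedgeCT")))
  config$hash <- rlang::hash(config)
  config$timestamp <- format(t0, "%Y-%m-%dT%H:%M:%S%z")
  config$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(list(metrics = metrics, separability = separ, argmax = argmax,
                 phantom = phantom, config = config,
                 images = if (keep_images) images else NULL),
            class = "kedge_sweep")
}

#' @export
print.kedge_sweep <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<kedge_sweep> %d thresholds (%g-%g keV), %d materials, %s mode\n",
    length(cfg$thresholds), min(cfg$thresholds), max(cfg$thresholds),
    length(unique(x$metrics$material)),
    if (cfg$noise_free) "noise-free" else "noisy"))
  cat(sprintf("  grid %d px @ %g mm, %d views x %d channels, N0 = %g\n",
              cfg$grid_size, cfg$pixel_size_mm, cfg$n_views, cfg$n_channels,
              cfg$n0))
  invisible(x)
}

#' Threshold maximizing a material's contrast
#'
#' @param sweep A `kedge_sweep`.
#' @param material Insert label (element symbol or `"water"`).
#' @param bin `"low"` or `"high"`.
#' @return The threshold (keV) with maximal contrast; ties break toward
#'   the lower threshold.
#' @examples
#' \donttest{
#' sw <- run_sweep(noise_free = TRUE)
#' peak_threshold(sw, "Lu", "high")
#' }
#' @export
peak_threshold <- function(sweep, material, bin = c("high", "low")) {
  stopifnot(inherits(sweep, "kedge_sweep"))
  bin <- match.arg(bin)
  m <- sweep$metrics[sweep$metrics$material == material &
                     sweep$metrics$bin == bin, ]
  if (nrow(m) == 0) abort(sprintf("unknown material '%s'", material))
  m <- m[order(m$threshold_keV), ]
  m$threshold_keV[which.max(m$contrast_HU)]
}

#' Contrast-peak thresholds for every material and bin
#'
#' @param sweep A `kedge_sweep`.
#' @return Tibble with `material`, `bin`, `peak_threshold_keV`.
#' @export
peak_thresholds <- function(sweep) {
  stopifnot(inherits(sweep, "kedge_sweep"))
  sweep$metrics |>
    group_by(.data$material, .data$bin) |>
    arrange(.data$threshold_keV, .by_group = TRUE) |>
    summarise(peak_threshold_keV =
                .data$threshold_keV[which.max(.data$contrast_HU)],
              .groups = "drop")
}

#' Threshold giving the best separability for a material pair
#'
#' @param sweep A `kedge_sweep`.
#' @param material_a,material_b Two distinct insert labels.
#' @return The threshold (keV) maximizing `|s'|`; ties break toward the
#'   lower threshold.
#' @export
best_separation_threshold <- function(sweep, material_a, material_b) {
  stopifnot(inherits(sweep, "kedge_sweep"))
  if (identical(material_a, material_b)) {
    abort("separability of a material with itself is undefined")
  }
  s <- sweep$separability
  m <- s[(s$material_A == material_a & s$material_B == material_b) |
         (s$material_A == material_b & s$material_B == material_a), ]
  if (nrow(m) == 0) {
    abort(sprintf("no separability data for pair %s/%s",
                  material_a, material_b))
  }
  m <- m[order(m$threshold_keV), ]
  m$threshold_keV[which.max(m$s_prime)]
}

#' Pairwise matrix of optimal thresholds or peak separability
#'
#' @param sweep A `kedge_sweep`.
#' @param value `"threshold"` (argmax threshold per pair) or `"s_prime"`
#'   (peak separability per pair).
#' @return A symmetric matrix over the contrast materials, `NA` diagonal.
#' @export
separation_matrix <- function(sweep, value = c("threshold", "s_prime")) {
  value <- match.arg(value)
  am <- sweep$argmax
  mats <- sort(unique(c(am$material_A, am$material_B)))
  M <- matrix(NA_real_, length(mats), length(mats),
              dimnames = list(mats, mats))
  v <- if (value == "threshold") am$best_threshold_keV else am$peak_s_prime
  for (k in seq_len(nrow(am))) {
    M[am$material_A[k], am$material_B[k]] <- v[k]
    M[am$material_B[k], am$material_A[k]] <- v[k]
  }
  M
}
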