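# default per-ray photon budgets; calibrated so that the low-bin water
# background noise at threshold 50 keV is approximately 16 HU for the
# default pipeline of each preset (see the methods vignette)
.N0_DEFAULT <- list(paper = 1.82e7, test = 1.09e6)

#' Two-bin photon-counting acquisition protocol
#'
#' Bundles the acquisition settings of one simulated scan: tube potential,
#' the two counting thresholds, parallel-beam sampling (views over 180
#' degrees, detector channels across the field of view), photon budget per
#' ray, and reconstruction grid.
#'
#' @param high_threshold_keV Upper counting threshold (keV); the sweep of
#'   the study varies it over 50-90 keV in 5 keV steps.
#' @param kV Tube potential (kV), default 120.
#' @param low_threshold_keV Lower counting threshold (keV), default 20.
#' @param n_views Projection angles over 180 degrees.
#' @param n_channels Detector channels.
#' @param fov_cm Detector field of view (cm); must cover the phantom.
#' @param n0 Photons per ray in air over the full spectrum.
#' @param grid_size,pixel_size_mm Reconstruction grid.
#' @param filtration_mm_al Spectrum filtration (mm Al).
#' @param seed Integer seed for Poisson noise, or `NULL`.
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(high_threshold_keV,
                                 kV = 120, low_threshold_keV = 20,
                                 n_views = 360, n_channels = 729,
                                 fov_cm = 36, n0 = .N0_DEFAULT$paper,
                                 grid_size = 512, pixel_size_mm = 0.5,
                                 filtration_mm_al = 2.5, seed = NULL) {
  if (!(low_threshold_keV < high_threshold_keV && high_threshold_keV < kV)) {
    abort("need low_threshold < high_threshold < kV")
  }
  if (n0 <= 0) abort("`n0` must be positive")
  structure(list(kV = kV, low_threshold_keV = low_threshold_keV,
                 high_threshold_keV = high_threshold_keV,
                 n_views = as.integer(n_views),
                 n_channels = as.integer(n_channels),
                 fov_cm = fov_cm, n0 = n0,
                 grid_size = as.integer(grid_size),
                 pixel_size_mm = pixel_size_mm,
                 filtration_mm_al = filtration_mm_al, seed = seed),
            class = "acquisition_protocol")
}

#' @rdname acquisition_protocol
#' @param preset `"paper"` for the full-resolution protocol (512 px at
#'   0.5 mm, 360 views, 729 channels) or `"test"` for the reduced preset
#'   (128 px at 2.8125 mm, 180 views, 183 channels) used in unit tests and
#'   the acceptance run.
#' @param ... Overrides passed to [acquisition_protocol()].
#' @export
protocol_preset <- function(preset = c("test", "paper"), high_threshold_keV,
                            ...) {
  preset <- match.arg(preset)
  args <- if (preset == "paper") {
    list(n_views = 360, n_channels = 729, grid_size = 512,
         pixel_size_mm = 0.5, n0 = .N0_DEFAULT$paper)
  } else {
    list(n_views = 180, n_channels = 183, grid_size = 128,
         pixel_size_mm = 2.8125, n0 = .N0_DEFAULT$test)
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(acquisition_protocol,
          c(list(high_threshold_keV = high_threshold_keV), args))
}

# detector channel offsets (cm) for a protocol
.channel_offsets <- function(protocol) {
  ds <- protocol$fov_cm / protocol$n_channels
  (seq_len(protocol$n_channels) - (protocol$n_channels + 1) / 2) * ds
}

# view angles (radians) over 180 degrees
.view_angles <- function(protocol) {
  (seq_len(protocol$n_views) - 1) * pi / protocol$n_views
}

#' Chord length of a parallel ray through a circle
#'
#' The ray at view angle `theta_rad` with signed perpendicular offset
#' `offset_cm` from the origin intersects the circle centered at
#' `(cx, cy)` with radius `r` in a chord of length
#' \eqn{2\sqrt{r^2 - d^2}} where `d` is the center-to-ray distance; zero
#' when the ray misses the circle.  Vectorized over `offset_cm`.
#'
#' @param cx,cy,r Circle center and radius (cm).
#' @param theta_rad View angle (radians).
#' @param offset_cm Ray offsets (cm).
#' @return Chord lengths in cm.
#' @export
chord_length <- function(cx, cy, r, theta_rad, offset_cm) {
  d <- abs(offset_cm - (cx * cos(theta_rad) + cy * sin(theta_rad)))
  len <- numeric(length(offset_cm))
  hit <- d < r
  len[hit] <- 2 * sqrt(r^2 - d[hit]^2)
  len
}

# path-length matrix: one row per ray (views stacked by channel-major
# order: ray index = (view-1)*n_channels + channel), one column per
# region (background water first, then each insert).  The background path
# is the background chord minus the chords through all inserts.
.path_matrix <- function(phantom, protocol) {
  s <- .channel_offsets(protocol)
  th <- .view_angles(protocol)
  ins <- phantom$inserts
  n_reg <- 1L + nrow(ins)
  L <- matrix(0, protocol$n_views * protocol$n_channels, n_reg)
  for (j in seq_along(th)) {
    rows <- (j - 1L) * protocol$n_channels + seq_len(protocol$n_channels)
    bg <- chord_length(0, 0, phantom$background_radius_cm, th[j], s)
    tot_ins <- 0
    for (i in seq_len(nrow(ins))) {
      ci <- chord_length(ins$x_cm[i], ins$y_cm[i], ins$radius_cm[i], th[j], s)
      L[rows, 1L + i] <- ci
      tot_ins <- tot_ins + ci
    }
    L[rows, 1L] <- bg - tot_ins
  }
  L
}

# linear attenuation (1/cm) of every phantom region at given energies:
# matrix regions x energies
.region_mu <- function(phantom, energies) {
  mats <- c(list(ct_material()),
            lapply(seq_len(nrow(phantom$inserts)),
                   function(i) .insert_material(phantom, i)))
  m <- vapply(mats, linear_attenuation, numeric(length(energies)),
              energy_keV = energies)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)  # single-energy spectrum
  t(m)
}

#' Per-ray spectral transmission of a phantom
#'
#' Computes, for every detector ray and every spectrum energy, the
#' Beer-Lambert transmitted fraction \eqn{\exp(-\sum_r \mu_r(E) \ell_r)}
#' over the phantom's regions.  This matrix is independent of the
#' counting thresholds, so one evaluation serves every bin of a whole
#' threshold sweep.
#'
#' @param phantom A `ct_phantom`.
#' @param protocol An `acquisition_protocol`.
#' @param energies_keV Energy grid (defaults to 1 keV steps from the low
#'   threshold to the tube potential).
#' @return A list of class `ray_transmission` with elements `fraction`
#'   (rays x energies matrix), `energies_keV`, and the sampling geometry.
#' @export
ray_transmission <- function(phantom, protocol,
                             energies_keV = seq(protocol$low_threshold_keV,
                                                protocol$kV, by = 1)) {
  L <- .path_matrix(phantom, protocol)
  Mu <- .region_mu(phantom, energies_keV)
  A <- L %*% Mu
  structure(list(fraction = exp(-A), energies_keV = energies_keV,
                 n_views = protocol$n_views,
                 n_channels = protocol$n_channels),
            class = "ray_transmission")
}

#' Expected photon counts per ray in one energy bin
#'
#' Sums the transmitted spectrum over the bin for every ray:
#' \eqn{N(ray) = \sum_{E \in bin} \Phi(E) \exp(-\sum_r \mu_r(E)\ell_r)}.
#'
#' @param phantom A `ct_phantom`.
#' @param protocol An `acquisition_protocol`.
#' @param spectrum An `xray_spectrum`; defaults to the protocol's filtered
#'   120 kV model.
#' @param bin `"low"`, `"high"`, or numeric `c(lo, hi)` in keV.
#' @param transmission Optional precomputed [ray_transmission()] (its
#'   energy grid must equal the spectrum grid).
#' @return Matrix of expected counts, `n_views` x `n_channels`.
#' @export
expected_counts <- function(phantom, protocol, spectrum = NULL,
                            bin = "low", transmission = NULL) {
  sp <- spectrum %||% make_spectrum(kV = protocol$kV,
                                    filtration_mm_al = protocol$filtration_mm_al,
                                    n0 = protocol$n0)
  edges <- .bin_edges(protocol, bin)
  if (is.null(transmission)) {
    transmission <- ray_transmission(phantom, protocol, sp$energy_keV)
  }
  if (!isTRUE(all.equal(transmission$energies_keV, sp$energy_keV))) {
    abort("transmission energy grid does not match the spectrum grid")
  }
  idx <- .bin_index(sp$energy_keV, edges[1], edges[2])
  w <- sp$fluence * idx
  counts <- transmission$fraction %*% w
  matrix(counts, protocol$n_views, protocol$n_channels, byrow = TRUE)
}

.bin_edges <- function(protocol, bin) {
  if (is.character(bin)) {
    switch(match.arg(bin, c("low", "high")),
           low = c(protocol$low_threshold_keV, protocol$high_threshold_keV),
           high = c(protocol$high_threshold_keV, protocol$kV))
  } else {
    if (length(bin) != 2L || bin[1] >= bin[2]) abort("invalid energy bin")
    as.numeric(bin)
  }
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate a log-normalized binned sinogram
#'
#' Expected counts per ray are Poisson-sampled (unless `noise_free`),
#' flat-field normalized by the matching air-scan expected counts, and
#' log-transformed: \eqn{p = -\ln(N / N_{air})}.  Zero counts are clamped
#' to 0.5 before the logarithm; if more than 1% of rays clamp, a photon
#' starvation warning is raised.
#'
#' @inheritParams expected_counts
#' @param noise_free Skip Poisson sampling (default `FALSE`).
#' @param seed Overrides `protocol$seed` when given.
#' @return An object of class `binned_sinogram`: the line-integral matrix
#'   (`n_views` x `n_channels`) with attributes `bin_keV`, `protocol`,
#'   `noise_free`, `seed`.
#' @export
simulate_sinogram <- function(phantom, protocol, bin = "low",
                              noise_free = FALSE, spectrum = NULL,
                              transmission = NULL, seed = protocol$seed) {
  sp <- spectrum %||% make_spectrum(kV = protocol$kV,
                                    filtration_mm_al = protocol$filtration_mm_al,
                                    n0 = protocol$n0)
  edges <- .bin_edges(protocol, bin)
  lambda <- expected_counts(phantom, protocol, sp, edges, transmission)
  n_air <- bin_fluence(sp, edges[1], edges[2])
  if (noise_free) {
    counts <- lambda
  } else {
    counts <- .with_seed(seed, {
      matrix(stats::rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
    })
    n_clamp <- sum(counts == 0)
    if (n_clamp > 0.01 * length(counts)) {
      warn(sprintf(
        "photon starvation: %d of %d rays (%.1f%%) recorded zero counts",
        n_clamp, length(counts), 100 * n_clamp / length(counts)))
    }
    counts[counts == 0] <- 0.5
  }
  p <- log(n_air) - log(counts)
  if (noise_free) p[p < 0 & p > -1e-12] <- 0  # kill negative rounding dust
  structure(p, class = "binned_sinogram", bin_keV = edges,
            protocol = protocol, noise_free = noise_free, seed = seed)
}

#' @export
print.binned_sinogram <- function(x, ...) {
  b <- attr(x, "bin_keV")
  cat(sprintf("<binned_sinogram> %d views x %d channels, bin [%g, %g] keV, %s\n",
              nrow(x), ncol(x), b[1], b[2],
              if (attr(x, "noise_free")) "noise-free" else "Poisson-noisy"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
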