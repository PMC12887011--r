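#' Generate a filtered polychromatic x-ray spectrum
#'
#' Models the tube output as a Kramers bremsstrahlung continuum,
#' \eqn{\Phi(E) \propto (kV - E)/E} per 1 keV bin, attenuated by an
#' aluminum filter, with optional tungsten-anode characteristic lines at
#' 59.3 and 67.2 keV, renormalized so the total fluence per detector ray
#' equals the photon budget `n0`.
#'
#' @param kV Tube potential in kV (grid and endpoint; default 120).
#' @param filtration_mm_al Aluminum filtration thickness in mm (default 2.5).
#' @param n0 Total photons per ray in air over the 20-120 keV range.
#' @param characteristic Add tungsten K lines (default `TRUE`).
#' @param anode_self_filtration_mm_w Equivalent tungsten thickness (mm)
#'   modeling self-absorption in the anode (default 0.03); hardens the
#'   continuum and imprints the tungsten K edge at 69.5 keV, as real
#'   tube spectra show.
#' @param grid_keV Energy grid; defaults to 1 keV steps over 20-120 keV.
#' @return A tibble of class `xray_spectrum` with columns `energy_keV`,
#'   `fluence`, and attributes `kV` and `n0`.
#' @examples
#' sp <- make_spectrum(n0 = 1e6)
#' sum(sp$fluence)
#' @export
make_spectrum <- function(kV = 120, filtration_mm_al = 2.5, n0 = 1e6,
                          characteristic = TRUE,
                          anode_self_filtration_mm_w = 0.03,
                          grid_keV = seq(20, 120, by = 1)) {
  if (!is.numeric(n0) || length(n0) != 1L || is.na(n0) || n0 <= 0) {
    abort("`n0` must be a single positive photon count.")
  }
  if (filtration_mm_al < 0) abort("`filtration_mm_al` must be >= 0.")
  E <- grid_keV
  fl <- pmax(kV - E, 0) / E
  if (filtration_mm_al > 0) {
    rho_al <- 2.699  # g/cm^3
    t_cm <- filtration_mm_al / 10
    fl <- fl * exp(-mass_attenuation("Al", E) * rho_al * t_cm)
  }
  if (anode_self_filtration_mm_w > 0) {
    rho_w <- 19.3
    fl <- fl * exp(-mass_attenuation("W", E) * rho_w *
                     anode_self_filtration_mm_w / 10)
  }
  if (characteristic && kV > 69.5) {
    # tungsten K alpha / K beta, placed on the nearest grid bins
    cont <- sum(fl)
    for (ln in list(c(59.3, 0.08), c(67.2, 0.04))) {
      i <- which.min(abs(E - ln[1]))
      fl[i] <- fl[i] + ln[2] * cont
    }
  }
  fl[E > kV] <- 0
  fl <- fl / sum(fl) * n0
  sp <- tibble(energy_keV = E, fluence = fl)
  attr(sp, "kV") <- kV
  attr(sp, "n0") <- n0
  class(sp) <- c("xray_spectrum", class(sp))
  sp
}

#' Fluence in one detector energy bin
#'
#' Bins partition the acquisition range: a bin sums fluence over
#' `[lo, hi)` unless `hi` reaches the top of the spectrum grid, in which
#' case the endpoint is included (the terminal high-energy bin spans
#' threshold to tube potential inclusive).
#'
#' @param spectrum An [make_spectrum()] spectrum (or any tibble with
#'   `energy_keV` and `fluence`).
#' @param lo,hi Bin edges in keV, `lo < hi`.
#' @return Total photons per ray in the bin.
#' @export
bin_fluence <- function(spectrum, lo, hi) {
  sum(spectrum$fluence[.bin_index(spectrum$energy_keV, lo, hi)])
}

.bin_index <- function(E, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    abort("invalid energy bin: need lo < hi")
  }
  top <- max(E)
  if (hi >= top) E >= lo & E <= top else E >= lo & E < hi
}

#' Read or write a spectrum as a two-column text file
#'
#' Columns are energy (keV) and photons per ray per bin; lines starting
#' with `#` are comments.  This allows substituting an externally
#' generated spectrum for the built-in model.
#'
#' @param spectrum An `xray_spectrum`.
#' @param path File path.
#' @return `read_spectrum()` returns an `xray_spectrum`;
#'   `write_spectrum()` returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  lines <- c("# energy_keV fluence_photons_per_ray",
             sprintf("%.6f %.8e", spectrum$energy_keV, spectrum$fluence))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  m <- utils::read.table(path, col.names = c("energy_keV", "fluence"))
  sp <- as_tibble(m)
  attr(sp, "kV") <- max(sp$energy_keV)
  attr(sp, "n0") <- sum(sp$fluence)
  class(sp) <- c("xray_spectrum", class(sp))
  sp
}
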