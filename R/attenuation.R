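#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# package-local cache for parsed attenuation tables
.atten_cache <- new.env(parent = emptyenv())

.atten_path <- function(...) {
  system.file("extdata", "attenuation", ..., package = "kedgeCT", mustWork = TRUE)
}

#' Elements with bundled attenuation data
#'
#' Returns the catalogue of chemical elements for which the package bundles
#' a mass attenuation table, together with atomic number, atomic weight and
#' the K-shell absorption-edge energy.  The K-edge column is `NA` for light
#' elements whose edge lies far below the diagnostic energy range.
#'
#' @return A tibble with columns `symbol`, `Z`, `atomic_weight`, `kedge_keV`.
#' @examples
#' atten_elements()
#' @export
atten_elements <- function() {
  if (is.null(.atten_cache$elements)) {
    df <- utils::read.csv(.atten_path("elements.csv"), stringsAsFactors = FALSE)
    df$kedge_keV <- suppressWarnings(as.numeric(df$kedge_keV))
    .atten_cache$elements <- as_tibble(df)
  }
  .atten_cache$elements
}

.check_symbol <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 1L) {
    abort("`symbol` must be a single chemical symbol string.")
  }
  if (!symbol %in% atten_elements()$symbol) {
    abort(sprintf("unsupported element '%s'; see atten_elements()", symbol))
  }
  invisible(symbol)
}

#' Mass attenuation curve for an element
#'
#' Reads the bundled tabulation of the total mass attenuation coefficient
#' \eqn{\mu/\rho} (cm^2/g) against photon energy (keV).  Absorption edges are
#' stored as duplicated energy abscissae: the first row at an edge energy
#' carries the value just below the edge, the second the value just above,
#' so that interpolation never bridges the discontinuity.
#'
#' @param symbol Chemical symbol, e.g. `"I"` or `"Gd"`.
#' @return A tibble with columns `energy_keV` and `mu_over_rho` and
#'   attribute `symbol`.
#' @examples
#' atten_curve("I")
#' @export
atten_curve <- function(symbol) {
  .check_symbol(symbol)
  key <- paste0("curve_", symbol)
  if (is.null(.atten_cache[[key]])) {
    m <- utils::read.table(.atten_path(paste0(symbol, ".txt")),
                           col.names = c("energy_keV", "mu_over_rho"))
    tb <- as_tibble(m)
    attr(tb, "symbol") <- symbol
    .atten_cache[[key]] <- tb
  }
  .atten_cache[[key]]
}

#' K-shell absorption edge energy
#'
#' @param symbol Chemical symbol.
#' @return Edge energy in keV, or `NA` when the element's K edge lies below
#'   the 1 keV tracking cutoff (e.g. hydrogen, oxygen).
#' @examples
#' kedge_energy("I")   # 33.17 keV
#' kedge_energy("Gd")  # 50.24 keV
#' @export
kedge_energy <- function(symbol) {
  .check_symbol(symbol)
  el <- atten_elements()
  el$kedge_keV[match(symbol, el$symbol)]
}

# log-log interpolator over a curve with duplicated edge abscissae.
# The below-edge row is nudged down by a relative 1e-9 so that a query at
# exactly the edge energy lands on the above-edge branch, and no
# interpolation segment spans an edge.
.curve_interp <- function(curve, energy_keV) {
  x <- curve$energy_keV
  y <- curve$mu_over_rho
  dup <- which(duplicated(x))
  if (length(dup)) x[dup - 1L] <- x[dup - 1L] * (1 - 1e-9)
  lx <- log(x)
  ly <- log(y)
  out <- stats::approx(lx, ly, xout = log(energy_keV), rule = 1)$y
  exp(out)
}

#' Mass attenuation coefficient of an element
#'
#' Interpolates the bundled tabulation linearly in log(energy)-log(mu/rho).
#' A query exactly at an edge energy returns the above-edge value.
#'
#' @param symbol Chemical symbol.
#' @param energy_keV Photon energies in keV; must lie inside the tabulated
#'   range (the bundled tables cover 10-150 keV).
#' @return Mass attenuation coefficients in cm^2/g, same length as
#'   `energy_keV`.
#' @examples
#' mass_attenuation("I", c(33.1, 33.3))  # straddles the iodine K edge
#' @export
mass_attenuation <- function(symbol, energy_keV) {
  curve <- atten_curve(symbol)
  if (!is.numeric(energy_keV) || anyNA(energy_keV)) {
    abort("`energy_keV` must be numeric without NA.")
  }
  rng <- range(curve$energy_keV)
  if (any(energy_keV < rng[1] | energy_keV > rng[2])) {
    abort(sprintf("energy outside supported range [%g, %g] keV", rng[1], rng[2]))
  }
  .curve_interp(curve, energy_keV)
}

# mass fractions of standard compositions
.WATER_FRACTIONS <- c(H = 0.111898, O = 0.888102)
.AIR_FRACTIONS   <- c(C = 0.000124, N = 0.755267, O = 0.231781, Ar = 0.012827)
.AIR_DENSITY_G_CM3 <- 0.001205

.mixture_mu_rho <- function(fractions, energy_keV) {
  acc <- 0
  for (sym in names(fractions)) {
    acc <- acc + fractions[[sym]] * mass_attenuation(sym, energy_keV)
  }
  acc
}

#' Mass attenuation of liquid water and dry air
#'
#' Computed from the bundled elemental tables by the mixture rule
#' (mass-fraction weighted sum).
#'
#' @param energy_keV Photon energies in keV.
#' @return Mass attenuation coefficients in cm^2/g.
#' @examples
#' water_mu_rho(60)  # about 0.206 cm^2/g
#' @export
water_mu_rho <- function(energy_keV) .mixture_mu_rho(.WATER_FRACTIONS, energy_keV)

#' @rdname water_mu_rho
#' @export
air_mu_rho <- function(energy_keV) .mixture_mu_rho(.AIR_FRACTIONS, energy_keV)
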