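#' Define an imaging material
#'
#' A material is either dry air or an ideal dilute aqueous solution of a
#' single element: the solute adds its mass attenuation on top of pure
#' water without volume displacement, so attenuation is affine in
#' concentration.  `ct_material()` with no arguments is pure water.
#'
#' @param solute Chemical symbol of the dissolved element, or `NULL` for
#'   the pure solvent.
#' @param concentration_mg_per_mL Solute concentration (mg/mL), `>= 0`.
#' @param base `"water"` (solutions) or `"air"`; air admits no solute.
#' @param label Display label; defaults to the solute symbol, `"water"`,
#'   or `"air"`.
#' @return An object of class `ct_material`.
#' @examples
#' iodine4 <- ct_material("I", 4)
#' linear_attenuation(iodine4, 60)
#' @export
ct_material <- function(solute = NULL, concentration_mg_per_mL = 0,
                        base = c("water", "air"), label = NULL) {
  base <- match.arg(base)
  if (!is.null(solute)) {
    if (base == "air") abort("air materials cannot carry a solute")
    .check_symbol(solute)
  }
  if (!is.numeric(concentration_mg_per_mL) || length(concentration_mg_per_mL) != 1L ||
      is.na(concentration_mg_per_mL) || concentration_mg_per_mL < 0) {
    abort("`concentration_mg_per_mL` must be a single non-negative number.")
  }
  if (is.null(solute) && concentration_mg_per_mL > 0) {
    abort("non-zero concentration requires a solute")
  }
  if (is.null(label)) {
    label <- if (!is.null(solute)) solute else base
  }
  structure(
    list(solute = solute,
         concentration_mg_per_mL = concentration_mg_per_mL,
         base = base, label = label),
    class = "ct_material")
}

#' @export
print.ct_material <- function(x, ...) {
  if (x$base == "air") {
    cat("<ct_material> air\n")
  } else if (is.null(x$solute) || x$concentration_mg_per_mL == 0) {
    cat("<ct_material> water\n")
  } else {
    cat(sprintf("<ct_material> %s %g mg/mL in water\n",
                x$solute, x$concentration_mg_per_mL))
  }
  invisible(x)
}

#' Linear attenuation coefficient of a material
#'
#' Water solutions: \eqn{\mu(E) = \mu_{water}(E) + c \, (\mu/\rho)_{solute}(E)}
#' with the concentration converted from mg/mL to g/cm^3 and water density
#' taken as 1.0 g/cm^3.  Air: standard dry-air composition at 1.205 mg/cm^3.
#'
#' @param material A [ct_material()].
#' @param energy_keV Photon energies in keV.
#' @return Linear attenuation coefficients in 1/cm.
#' @export
linear_attenuation <- function(material, energy_keV) {
  stopifnot(inherits(material, "ct_material"))
  if (material$base == "air") {
    return(.AIR_DENSITY_G_CM3 * air_mu_rho(energy_keV))
  }
  mu <- water_mu_rho(energy_keV)  # water density 1.0 g/cm^3
  if (!is.null(material$solute) && material$concentration_mg_per_mL > 0) {
    c_g_cm3 <- material$concentration_mg_per_mL / 1000
    mu <- mu + c_g_cm3 * mass_attenuation(material$solute, energy_keV)
  }
  mu
}
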