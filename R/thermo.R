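# Physical constants and conversions between the excess chemical potential of
# water (WT, "work to transfer" a water molecule from bulk to a position near
# the solute) and the local-to-bulk density ratio:
#
#   WT(x) = -kT * log( rho(x) / rho_bulk )
#
# Negative WT means the position is favoured over bulk.

# Boltzmann constant in kcal mol^-1 K^-1
.kB <- 0.0019872041

#' Thermodynamic parameters for excess chemical potential calculations
#'
#' Bundles the simulation temperature, the derived thermal energy `kT`
#' (kcal/mol), and the bulk number density of water used as the reference in
#' density-ratio estimates of the excess chemical potential.
#'
#' @param temperature Simulation temperature in Kelvin. Default 300 K.
#' @param rho_bulk Bulk water number density in molecules per cubic Angstrom.
#'   The default 0.033 is the number density of liquid water at ambient
#'   conditions; override it if your water model equilibrates to a slightly
#'   different bulk density.
#'
#' @return An object of class `thermo_params`: a list with elements
#'   `temperature` (K), `kT` (kcal/mol) and `rho_bulk` (A^-3).
#'
#' @examples
#' th <- make_thermo(300)
#' th$kT                      # 0.59616 kcal/mol
#' wt_to_density_ratio(-4.8, th)   # > 1000-fold over bulk
#' @export
make_thermo <- function(temperature = 300, rho_bulk = 0.033) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop_validation("`temperature` must be a single positive number (Kelvin)")
  }
  if (!is.numeric(rho_bulk) || length(rho_bulk) != 1L ||
      !is.finite(rho_bulk) || rho_bulk <= 0) {
    stop_validation("`rho_bulk` must be a single positive number (A^-3)")
  }
  structure(
    list(temperature = temperature, kT = .kB * temperature, rho_bulk = rho_bulk),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "Thermodynamic parameters: T = %g K, kT = %.5f kcal/mol, rho_bulk = %g A^-3\n",
    x$temperature, x$kT, x$rho_bulk
  ))
  invisible(x)
}

#' Convert an excess chemical potential to a local-to-bulk density ratio
#'
#' Inverts `WT = -kT log(rho/rho_bulk)`: a site with `wt = -4.8` kcal/mol at
#' 300 K has a local water density more than 1000-fold above bulk.
#'
#' @param wt Excess chemical potential in kcal/mol (vectorised).
#' @param thermo A [make_thermo()] object.
#' @return `exp(-wt / kT)`, the ratio `rho(x) / rho_bulk`.
#' @seealso [density_ratio_to_wt()]
#' @export
wt_to_density_ratio <- function(wt, thermo = make_thermo()) {
  stopifnot(inherits(thermo, "thermo_params"))
  exp(-wt / thermo$kT)
}

#' Convert a local-to-bulk density ratio to an excess chemical potential
#'
#' @param ratio Density ratio `rho(x)/rho_bulk`; must be positive (vectorised).
#' @param thermo A [make_thermo()] object.
#' @return `-kT log(ratio)` in kcal/mol.
#' @seealso [wt_to_density_ratio()]
#' @export
density_ratio_to_wt <- function(ratio, thermo = make_thermo()) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop_validation("`ratio` must be positive and finite")
  }
  -thermo$kT * log(ratio)
}
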