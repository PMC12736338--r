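# Physical constants pinned in one place. Everything electrostatic is done in
# Hartree atomic units; coordinates at the user surface are in Angstrom.

#' Physical constants used by fqembed
#'
#' A named list of the conversion constants the package relies on:
#' `bohr_per_angstrom` (length conversion), `hc_ev_nm` (photon energy-wavelength
#' product, eV nm), `hartree_ev` (Hartree in eV) and `ev_per_kcalmol`
#' (1 kcal/mol expressed in eV, the usual chemical-accuracy yardstick).
#'
#' @export
fq_constants <- list(
  bohr_per_angstrom = 1 / 0.529177210903,
  angstrom_per_bohr = 0.529177210903,
  hc_ev_nm          = 1239.841984,
  hartree_ev        = 27.211386245988,
  ev_per_kcalmol    = 4.184 / 96.48533212331
)

#' Convert between wavelength (nm) and photon energy (eV)
#'
#' The conversion E\[eV\] = hc / lambda\[nm\] is its own inverse, so the same
#' function maps nm to eV and eV to nm.
#'
#' @param value positive wavelength in nm (returns eV) or energy in eV
#'   (returns nm).
#' @return numeric vector of the converted values.
#' @examples
#' nm_ev_convert(480)            # excitation energy of a 480 nm photon
#' nm_ev_convert(nm_ev_convert(480)) # round trip
#' @export
nm_ev_convert <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    fq_abort("`value` must be positive and finite.", "fqembed_bad_value")
  }
  fq_constants$hc_ev_nm / value
}

#' Convert kcal/mol to eV
#'
#' @param x energies in kcal/mol.
#' @return energies in eV. One kcal/mol is about 0.0434 eV.
#' @export
kcalmol_to_ev <- function(x) x * fq_constants$ev_per_kcalmol

angstrom_to_bohr <- function(x) x * fq_constants$bohr_per_angstrom
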