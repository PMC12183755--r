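## Unit conversion constants. All internal arithmetic is in Hartree atomic
## units (hbar = 1, energies in hartree, mass-weighted lengths in
## sqrt(m_e) * bohr); I/O uses Angstrom / amu / cm^-1.

#' Physical unit conversion constants
#'
#' Named constants used throughout the package: `amu_to_me` (1 amu in electron
#' masses), `ang_to_bohr` (1 Angstrom in bohr), `hartree_to_cm` (1 hartree in
#' cm^-1).
#'
#' @format Named numeric vector of length 3.
#' @export
sbg_units <- c(
  amu_to_me    = 1822.888486,
  ang_to_bohr  = 1.8897261255,
  hartree_to_cm = 219474.6313705
)

#' Convert energies between hartree and wavenumbers
#'
#' @param x numeric energies.
#' @return converted numeric vector.
#' @export
hartree_to_cm <- function(x) x * sbg_units[["hartree_to_cm"]]

#' @rdname hartree_to_cm
#' @export
cm_to_hartree <- function(x) x / sbg_units[["hartree_to_cm"]]
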