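#' Physical constants and unit helpers
#'
#' Internal units are nm, kJ/mol, ps and K throughout. Angstrom values are
#' accepted at analysis interfaces (contact cutoffs, water tiers, reported
#' distances) and converted on entry/exit.
#'
#' @name units
NULL

#' Boltzmann constant in kJ mol^-1 K^-1
#' @export
kB <- 0.0083145

#' Thermal energy kT in kJ/mol
#' @param temperature temperature in K
#' @return kT in kJ/mol
#' @export
kT <- function(temperature) kB * temperature

#' Convert Angstrom to nm
#' @param x length in Angstrom
#' @export
A_to_nm <- function(x) x / 10

#' Convert nm to Angstrom
#' @param x length in nm
#' @export
nm_to_A <- function(x) x * 10
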