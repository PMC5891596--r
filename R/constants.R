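#' Physical constants and unit conventions
#'
#' Internal units are Angstrom, kcal/mol, electron charges and radians.
#' Energies are converted to kJ/mol only at reporting time.
#'
#' @name qmmlink-units
#' @keywords internal
NULL

## Coulomb's constant in kcal*A/(mol*e^2); relative permittivity 1.
COULOMB_KCAL <- 332.0522

## prmtop stores charges multiplied by sqrt(COULOMB) = 18.2223.
PRMTOP_CHARGE_SCALE <- 18.2223

KCAL_TO_KJ <- 4.184

## Default 1-4 scale divisors (AMBER convention): E_14 = E_plain / divisor.
DEFAULT_SCEE <- 1.2
DEFAULT_SCNB <- 2.0

#' Convert kcal/mol to kJ/mol
#'
#' @param x energy in kcal/mol.
#' @return energy in kJ/mol.
#' @export
kcal_to_kj <- function(x) x * KCAL_TO_KJ
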