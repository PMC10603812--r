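# Physical constants (SI) and water reference values shared across modules.
# Molar volumes are carried in cm^3/mol throughout; energies in kJ/mol unless
# a function documents otherwise.

#' Physical constants used throughout crowdfh
#'
#' @format A named list:
#' \describe{
#'   \item{R}{Gas constant, J/mol/K.}
#'   \item{R_kJ}{Gas constant, kJ/mol/K.}
#'   \item{N_A}{Avogadro constant, 1/mol.}
#'   \item{M_water}{Molar mass of water, g/mol.}
#'   \item{Vbar_water}{Partial molar volume of water at 25 C, cm^3/mol.}
#'   \item{T_ref}{Default reference temperature, K.}
#' }
#' @export
fh_constants <- list(
  R          = 8.314462618,
  R_kJ       = 8.314462618e-3,
  N_A        = 6.02214076e23,
  M_water    = 18.015,
  Vbar_water = 18.07,
  T_ref      = 298
)
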