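#' Physical constants table
#'
#' CODATA-2018 values of the physical constants used throughout the package,
#' collected in one place so that every module draws on the same numbers.
#'
#' @format A named list with elements
#' \describe{
#'   \item{R_g}{molar gas constant, J/(mol K)}
#'   \item{k_B}{Boltzmann constant, J/K}
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{F}{Faraday constant, C/mol}
#'   \item{q0}{elementary charge, C}
#'   \item{eps0}{vacuum permittivity, F/m}
#' }
#' @export
#' @examples
#' phys_constants$k_B
phys_constants <- list(
  R_g  = 8.31446261815324,
  k_B  = 1.380649e-23,
  N_A  = 6.02214076e23,
  F    = 96485.33212,
  q0   = 1.602176634e-19,
  eps0 = 8.8541878128e-12
)
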