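# Physical constants used throughout.
# Gas constant in kJ K^-1 mol^-1 (8.314 J, as conventionally used in
# bioenergetics calculations); Faraday constant in kJ/V per mol electrons.
.R_KJ <- 8.314e-3
.FARADAY_KJ_V <- 96.5
.ATM_PA <- 101325
.T_STANDARD <- 298.15
.PH_STANDARD <- 7

# Default Henry's law constants, mol m^-3 Pa^-1
.HENRY_H2 <- 7.8e-6
.HENRY_CH4 <- 1.4e-5

#' Physical constants used by the package
#'
#' Returns the constants the energetics routines rely on: the ideal gas
#' constant (kJ/K/mol), the Faraday constant (kJ/V per mol of electrons),
#' standard temperature (K), the pressure of one atmosphere (Pa), the
#' default Henry's law constants for H2 and CH4 (mol m^-3 Pa^-1), and the
#' minimum free-energy yield commonly assumed necessary for microbial
#' energy conservation (-10 +/- 1 kJ/mol).
#'
#' @return Named list of numeric constants.
#' @export
#' @examples
#' syntherm_constants()$faraday_kj_v
syntherm_constants <- function() {
  list(
    r_kj = .R_KJ,
    faraday_kj_v = .FARADAY_KJ_V,
    atm_pa = .ATM_PA,
    t_standard_k = .T_STANDARD,
    ph_standard = .PH_STANDARD,
    henry_h2 = .HENRY_H2,
    henry_ch4 = .HENRY_CH4,
    dg_min = -10,
    dg_min_tol = 1
  )
}
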