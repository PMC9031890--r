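# Physical constants (SI, CODATA exact values) and unit helpers.
# Frequencies are ordinary frequencies f in GHz throughout the package;
# angular frequency omega = 2*pi*f is formed internally. Times are in ps,
# so omega*tau = 2*pi * f[GHz] * tau[ps] * 1e-3.

.kB <- 1.380649e-23    # J/K
.h  <- 6.62607015e-34  # J s
.GHZ_PER_INVCM <- 29.9792458  # 1 cm^-1 in GHz, exact

#' Dimensionless omega*tau product
#' @param f_GHz frequency in GHz
#' @param tau_ps relaxation time in ps
#' @noRd
omega_tau <- function(f_GHz, tau_ps) 2 * pi * f_GHz * tau_ps * 1e-3

#' Convert wavenumbers to frequency
#'
#' @param wavenumber_invcm wavenumber in cm^-1.
#' @return Frequency in GHz (1 cm^-1 = 29.9792458 GHz, exact).
#' @export
invcm_to_ghz <- function(wavenumber_invcm) wavenumber_invcm * .GHZ_PER_INVCM

#' Viscosity of neat water
#'
#' Shear viscosity of pure water interpolated linearly from tabulated
#' values between 10 and 40 degrees Celsius.
#'
#' @param T_K temperature in kelvin.
#' @return Viscosity in mPa s.
#' @export
water_viscosity <- function(T_K) {
  stopifnot(is.numeric(T_K), all(T_K > 0))
  tab_T <- 273.15 + c(10, 15, 20, 25, 30, 35, 40)
  tab_eta <- c(1.306, 1.138, 1.002, 0.890, 0.797, 0.719, 0.653)
  if (any(T_K < min(tab_T) | T_K > max(tab_T)))
    stop("temperature outside tabulated water-viscosity range (283-313 K)")
  stats::approx(tab_T, tab_eta, xout = T_K)$y
}
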