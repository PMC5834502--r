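# Unit conventions, fixed package-wide: frequency THz, time ps, length um,
# absorption cm^-1. Every conversion lives in this file.

# speed of light in um/ps (numerically equal to m/s * 1e-6 * 1e-12 inverse)
.c_um_ps <- 299.792458

# speed of light in m/s, for the absorption-constant conversion
.c_m_s <- 299792458

# angular frequency in rad/ps from frequency in THz
thz_omega <- function(freq_THz) 2 * pi * freq_THz

# dimensionless single-pass phase omega*d/c for thickness d in um
phase_thickness <- function(freq_THz, d_um) {
  thz_omega(freq_THz) * d_um / .c_um_ps
}

#' Absorption constant from the extinction coefficient
#'
#' Converts the extinction coefficient (imaginary part of the complex
#' refractive index) into the power absorption constant
#' \eqn{\alpha = 2\omega\kappa/c}, reported in cm\eqn{^{-1}} as is
#' conventional for liquid-water THz spectra.
#'
#' @param kappa Extinction coefficient (dimensionless), vectorised.
#' @param freq_THz Frequency in THz, vectorised; must be positive.
#' @return Absorption constant in cm\eqn{^{-1}}.
#' @examples
#' absorption_constant(1, 0.3) # ~125.7 cm^-1
#' @export
absorption_constant <- function(kappa, freq_THz) {
  if (any(!is.finite(freq_THz)) || any(freq_THz <= 0)) {
    abort("`freq_THz` must be positive and finite.", class = "thzcoag_domain_error")
  }
  omega_si <- 2 * pi * freq_THz * 1e12            # rad/s
  (2 * omega_si * kappa / .c_m_s) / 100           # m^-1 -> cm^-1
}
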