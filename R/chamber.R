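#' Fluidic chamber geometry
#'
#' Geometry of the transmission cell: a liquid channel of thickness `d_um`
#' bounded by two polyethylene (PE) windows. PE absorption is neglected and
#' air absorption is neglected, as appropriate below ~3 THz.
#'
#' @param d_um Channel thickness in um (default 100).
#' @param n_window Refractive index of the PE windows (default 1.5).
#' @param n_air Refractive index of air (default 1).
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(d_um = 100, n_window = 1.5, n_air = 1) {
  d_um <- as.numeric(d_um); n_window <- as.numeric(n_window)
  n_air <- as.numeric(n_air)
  if (!is.numeric(d_um) || length(d_um) != 1 || d_um <= 0) {
    abort("`d_um` must be a single positive number.", class = "thzcoag_config_error")
  }
  structure(list(d_um = d_um, n_window = n_window, n_air = n_air),
            class = "chamber_geometry")
}

#' Fresnel field-transmission coefficient at normal incidence
#'
#' \eqn{T_{a\to b} = 2\bar n_a / (\bar n_a + \bar n_b)} for complex indices
#' \eqn{\bar n = n + i\kappa}.
#'
#' @param n_a,n_b Complex (or real) refractive indices of the incident and
#'   transmitting media; vectorised.
#' @return Complex transmission coefficient.
#' @export
fresnel_transmission <- function(n_a, n_b) {
  2 * n_a / (n_a + n_b)
}

# internal: field-reflection coefficient a -> b, used by the optional etalon echo
fresnel_reflection <- function(n_a, n_b) {
  (n_a - n_b) / (n_a + n_b)
}

#' Complex transfer factor of the fluidic chamber
#'
#' Field transfer of the liquid channel relative to the THz source: the empty
#' chamber contributes the two window-to-air interface transmissions and the
#' free propagation phase \eqn{e^{i\omega d/c}}; the filled chamber
#' contributes the window-to-liquid interfaces and
#' \eqn{e^{i\omega d n/c}\,e^{-\omega d \kappa/c}}. Propagation through the PE
#' windows themselves is common to both arms and therefore omitted (it cancels
#' in the sample/reference ratio). The transfer is single-pass; `echo = TRUE`
#' adds the first-order Fabry-Perot round trip
#' \eqn{(1 + r^2 e^{2i\omega d \bar n/c})} to emulate the residual etalon
#' ripple of a thin cell.
#'
#' @param freq_THz Frequency in THz, vectorised.
#' @param geometry A [chamber_geometry()].
#' @param n,kappa Real and imaginary parts of the liquid refractive index,
#'   vectorised over frequency. Ignored when `filled = FALSE`.
#' @param filled Logical: liquid-filled chamber (`TRUE`) or empty reference
#'   chamber (`FALSE`).
#' @param echo Logical: include the first internal Fabry-Perot echo.
#' @return Complex transfer factor, same length as `freq_THz`.
#' @examples
#' g <- chamber_geometry()
#' # a chamber "filled" with air is indistinguishable from the empty chamber
#' all.equal(chamber_transfer(0.5, g, n = 1, kappa = 0),
#'           chamber_transfer(0.5, g, filled = FALSE))
#' @export
chamber_transfer <- function(freq_THz, geometry = chamber_geometry(),
                             n = NULL, kappa = NULL,
                             filled = TRUE, echo = FALSE) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  n_pe <- geometry$n_window
  phi <- phase_thickness(freq_THz, geometry$d_um)
  if (filled) {
    if (is.null(n) || is.null(kappa)) {
      abort("`n` and `kappa` are required for a filled chamber.",
            class = "thzcoag_input_error")
    }
    nbar <- complex(real = n, imaginary = kappa)
  } else {
    nbar <- complex(real = rep(geometry$n_air, length(freq_THz)), imaginary = 0)
  }
  tr <- fresnel_transmission(n_pe, nbar) * fresnel_transmission(nbar, n_pe) *
    exp(1i * phi * nbar)
  if (echo) {
    r_int <- fresnel_reflection(nbar, n_pe) # liquid->window, both faces
    tr <- tr * (1 + r_int^2 * exp(2i * phi * nbar))
  }
  tr
}

# internal: interface correction C(nbar) = [T_pe-liquid * T_liquid-pe] /
# [T_pe-air * T_air-pe], the factor eliminated by the fixed-point iteration.
interface_correction <- function(nbar, geometry) {
  n_pe <- geometry$n_window
  n_air <- geometry$n_air
  (fresnel_transmission(n_pe, nbar) * fresnel_transmission(nbar, n_pe)) /
    (fresnel_transmission(n_pe, n_air) * fresnel_transmission(n_air, n_pe))
}
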