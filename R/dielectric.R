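#' Double-Debye dielectric model for liquid water
#'
#' Two-relaxation (double-Debye) permittivity model used as the water baseline
#' of the blood simulator. Defaults are standard literature values for liquid
#' water at room temperature: a slow collective-reorientation relaxation
#' (~8 ps) and a fast hydrogen-bond relaxation (~0.2 ps).
#'
#' @param eps_static Static permittivity \eqn{\varepsilon_s}.
#' @param eps_intermediate Intermediate permittivity \eqn{\varepsilon_1}
#'   separating the two relaxation branches.
#' @param eps_inf High-frequency permittivity \eqn{\varepsilon_\infty}.
#' @param tau_slow Slow relaxation time, ps.
#' @param tau_fast Fast relaxation time, ps.
#' @return An object of class `debye_model`.
#' @examples
#' water <- debye_water()
#' complex_index(0.35, water)
#' @export
debye_water <- function(eps_static = 78.36,
                        eps_intermediate = 4.93,
                        eps_inf = 3.48,
                        tau_slow = 8.24,
                        tau_fast = 0.18) {
  eps_static <- as.numeric(eps_static)
  eps_intermediate <- as.numeric(eps_intermediate)
  eps_inf <- as.numeric(eps_inf)
  tau_slow <- as.numeric(tau_slow)
  tau_fast <- as.numeric(tau_fast)
  if (!(eps_static > eps_intermediate && eps_intermediate > eps_inf && eps_inf > 1)) {
    abort("Require eps_static > eps_intermediate > eps_inf > 1.",
          class = "thzcoag_config_error")
  }
  if (!(tau_slow > tau_fast && tau_fast > 0)) {
    abort("Require tau_slow > tau_fast > 0.", class = "thzcoag_config_error")
  }
  structure(
    list(eps_static = eps_static, eps_intermediate = eps_intermediate,
         eps_inf = eps_inf, tau_slow = tau_slow, tau_fast = tau_fast),
    class = "debye_model"
  )
}

#' Complex permittivity of a double-Debye model
#'
#' Evaluates \eqn{\varepsilon(\omega) = \varepsilon_\infty +
#' (\varepsilon_s-\varepsilon_1)/(1 - i\omega\tau_{slow}) +
#' (\varepsilon_1-\varepsilon_\infty)/(1 - i\omega\tau_{fast})} under the
#' convention that a lossy medium has \eqn{\mathrm{Im}\,\varepsilon > 0},
#' matching the propagation factor \eqn{e^{i\omega d \bar n/c}} with
#' \eqn{\bar n = n + i\kappa}, \eqn{\kappa \ge 0}.
#'
#' @param freq_THz Frequency in THz, positive, vectorised.
#' @param model A [debye_water()] model.
#' @return Complex permittivity, same length as `freq_THz`.
#' @export
debye_permittivity <- function(freq_THz, model = debye_water()) {
  stopifnot(inherits(model, "debye_model"))
  if (any(!is.finite(freq_THz)) || any(freq_THz <= 0)) {
    abort("`freq_THz` must be positive and finite.", class = "thzcoag_domain_error")
  }
  w <- thz_omega(freq_THz) # rad/ps; tau in ps so w*tau dimensionless
  model$eps_inf +
    (model$eps_static - model$eps_intermediate) / (1 - 1i * w * model$tau_slow) +
    (model$eps_intermediate - model$eps_inf)    / (1 - 1i * w * model$tau_fast)
}

#' Complex refractive index from a dielectric model
#'
#' Principal square root of the permittivity, returned as a tibble of the real
#' index `n` and extinction coefficient `kappa` (both dimensionless) together
#' with the absorption constant in cm\eqn{^{-1}}.
#'
#' @inheritParams debye_permittivity
#' @return A tibble with columns `freq_THz`, `n`, `kappa`, `alpha_cm1`.
#' @export
complex_index <- function(freq_THz, model = debye_water()) {
  eps <- debye_permittivity(freq_THz, model)
  nbar <- sqrt(eps) # principal branch: Im eps > 0 -> arg in (0, pi/2)
  tibble(
    freq_THz = freq_THz,
    n = Re(nbar),
    kappa = Im(nbar),
    alpha_cm1 = absorption_constant(Im(nbar), freq_THz)
  )
}
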