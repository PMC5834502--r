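#' Platelet-dependent coagulation effect model
#'
#' Parameterises how coagulation perturbs the THz absorption of blood. The
#' normalized absorption change relative to uncoagulated blood is modelled as
#' a line in frequency,
#' \eqn{\Delta\alpha/\alpha(f) = s_\Delta (f - f_t(\mathrm{PLT}))},
#' crossing zero at a platelet-dependent transparency frequency
#' \eqn{f_t(\mathrm{PLT}) = f_{t,\mathrm{ref}} +
#' s_{\mathrm{PLT}} (\mathrm{PLT} - \mathrm{PLT}_{\mathrm{ref}})/50}.
#' Below \eqn{f_t} absorption decreases (THz defect), above it increases
#' (THz excess). The late clot (thrombus) state shifts \eqn{f_t} by a small
#' blue shift.
#'
#' Defaults place \eqn{f_t} at 0.9 THz for PLT = 175 K/uL and 0.4 THz for
#' PLT = 224 K/uL (slope \eqn{-0.5\cdot 50/49} THz per 50 K/uL), the reported
#' group-mean calibration points.
#'
#' @param transparency_freq_ref Transparency frequency (THz) at `plt_ref`.
#' @param plt_ref Reference platelet count, K/uL.
#' @param plt_slope Transparency-frequency shift in THz per 50 K/uL of PLT
#'   (negative = red shift with increasing PLT).
#' @param delta_slope Slope of \eqn{\Delta\alpha/\alpha} versus frequency,
#'   per THz.
#' @param thrombus_blue_shift Additional shift (THz, small positive) of the
#'   transparency frequency in the thrombus state.
#' @return An object of class `coagulation_effect`.
#' @export
coagulation_effect <- function(transparency_freq_ref = 0.9,
                               plt_ref = 175,
                               plt_slope = -0.5 * 50 / 49,
                               delta_slope = 0.10,
                               thrombus_blue_shift = 0.05) {
  transparency_freq_ref <- as.numeric(transparency_freq_ref)
  plt_ref <- as.numeric(plt_ref); plt_slope <- as.numeric(plt_slope)
  delta_slope <- as.numeric(delta_slope)
  thrombus_blue_shift <- as.numeric(thrombus_blue_shift)
  structure(
    list(transparency_freq_ref = transparency_freq_ref,
         plt_ref = plt_ref,
         plt_slope = plt_slope,
         delta_slope = delta_slope,
         thrombus_blue_shift = thrombus_blue_shift),
    class = "coagulation_effect"
  )
}

#' Transparency frequency as a function of platelet count
#'
#' @param plt Platelet count in K/uL, vectorised.
#' @param effect A [coagulation_effect()].
#' @return Transparency frequency in THz.
#' @export
transparency_frequency <- function(plt, effect = coagulation_effect()) {
  stopifnot(inherits(effect, "coagulation_effect"))
  effect$transparency_freq_ref +
    effect$plt_slope * (plt - effect$plt_ref) / 50
}

# valid measurement-state labels for a subject record
.thz_groups <- c("uncoagulated", "early_coagulated", "thrombus")

#' Complex refractive index of (coagulating) blood for one subject
#'
#' Ground-truth optical constants used by the simulator. Blood is treated as
#' water-dominated: the real index equals the water-model index, and the
#' extinction coefficient is the water value modulated by the subject state:
#'
#' * `uncoagulated`: \eqn{\kappa = \kappa_w (1 + c_{\mathrm{RBC}}
#'   (\mathrm{RBC} - \mathrm{RBC}_{\mathrm{ref}}))\, s}, an RBC-count effect
#'   with no platelet dependence;
#' * `early_coagulated`: \eqn{\kappa = \kappa_w (1 + \Delta\alpha/\alpha(f))\,
#'   s} with the platelet-dependent zero crossing of
#'   [coagulation_effect()]; the RBC dependence is removed, reflecting the
#'   loss of RBC correlation after the coagulation cascade starts;
#' * `thrombus`: as early-coagulated, with the transparency frequency
#'   blue-shifted by `thrombus_blue_shift`.
#'
#' `s` is an optional per-subject scale (column `kappa_scale`) carrying
#' between-subject absorption variability.
#'
#' @param subject A one-row data frame (or list) with at least `group`,
#'   `rbc`, `plt`; optionally `kappa_scale`.
#' @param freq_THz Frequencies in THz.
#' @param water A [debye_water()] model.
#' @param effect A [coagulation_effect()].
#' @param rbc_coeff Fractional absorption change per (M/uL) of RBC count in
#'   the uncoagulated state.
#' @param rbc_ref Reference RBC count (M/uL) at which the RBC term vanishes.
#' @return A tibble with columns `freq_THz`, `n`, `kappa`, `alpha_cm1`.
#' @export
blood_index <- function(subject, freq_THz,
                        water = debye_water(),
                        effect = coagulation_effect(),
                        rbc_coeff = 0.02, rbc_ref = 4.5) {
  subject <- as.list(subject)
  group <- as.character(subject$group)
  if (!group %in% .thz_groups) {
    abort(paste0("Unknown group '", group, "'."), class = "thzcoag_input_error")
  }
  base <- complex_index(freq_THz, water)
  scale <- subject$kappa_scale %||% 1
  kappa <- switch(
    group,
    uncoagulated = base$kappa * (1 + rbc_coeff * (subject$rbc - rbc_ref)) * scale,
    early_coagulated = {
      f_t <- transparency_frequency(subject$plt, effect)
      base$kappa * (1 + effect$delta_slope * (freq_THz - f_t)) * scale
    },
    thrombus = {
      f_t <- transparency_frequency(subject$plt, effect) + effect$thrombus_blue_shift
      base$kappa * (1 + effect$delta_slope * (freq_THz - f_t)) * scale
    }
  )
  if (any(kappa <= 0)) {
    abort("Effect parameterization drives kappa <= 0 inside the band.",
          class = "thzcoag_parameterization_error")
  }
  tibble(freq_THz = freq_THz, n = base$n, kappa = kappa,
         alpha_cm1 = absorption_constant(kappa, freq_THz))
}
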