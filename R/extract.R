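# Spectral inversion: amplitude/phase ratio of sample and reference spectra,
# closed-form initial estimate of (kappa, n), then per-frequency fixed-point
# elimination of the Fresnel interface transmissions.

# internal: band-limited ratio and unwrapped phase difference of two spectra
ratio_on_band <- function(sample, reference, settings, geometry) {
  if (!isTRUE(all.equal(sample$freq_THz, reference$freq_THz))) {
    abort("Sample and reference spectra must share one frequency grid.",
          class = "thzcoag_input_error")
  }
  keep <- sample$freq_THz >= settings$band[1] & sample$freq_THz <= settings$band[2]
  if (!any(keep)) abort("Analysis band outside the spectrum support.",
                        class = "thzcoag_config_error")
  freq <- sample$freq_THz[keep]
  ref_amp <- reference$amplitude[keep]
  degenerate <- Mod(ref_amp) <= .Machine$double.xmin
  ratio <- sample$amplitude[keep] / ref_amp
  ratio[degenerate] <- NA_complex_

  dphi <- signal::unwrap(Arg(ratio))
  phi_unit <- phase_thickness(freq, geometry$d_um) # omega*d/c
  # anchor the 2*pi branch so that n at the anchor frequency is the plausible
  # liquid value nearest 2.5 (branch spacing is ~23 index units at 0.13 THz,
  # so air n = 1 and water n ~ 2.5 share the k = 0 branch)
  ia <- which.min(abs(freq - settings$phase_anchor))
  n_anchor <- dphi[ia] / phi_unit[ia] + 1
  kbr <- round((2.5 - n_anchor) * phi_unit[ia] / (2 * pi))
  dphi <- dphi + 2 * pi * kbr

  list(freq = freq, ratio = ratio, dphi = dphi, phi_unit = phi_unit,
       degenerate = degenerate, keep = keep)
}

new_optical_constants <- function(freq, n, kappa, converged, iterations,
                                  geometry, settings, ratio = NULL, dphi = NULL) {
  out <- tibble(
    freq_THz = freq, n = n, kappa = kappa,
    alpha_cm1 = absorption_constant(kappa, freq),
    converged = converged, iterations = iterations
  )
  structure(out, class = c("optical_constants", class(out)),
            geometry = geometry, settings = settings,
            measured_ratio = ratio, measured_dphi = dphi)
}

#' Approximate optical constants from the spectral ratio
#'
#' Closed-form first estimate, ignoring the interface transmissions: from the
#' amplitude of the sample/reference ratio \eqn{R},
#' \eqn{\kappa_0 = -\frac{c}{2\omega d}\ln |R|^2} (sign fixed so attenuation
#' gives \eqn{\kappa \ge 0}), and from the unwrapped phase difference
#' \eqn{n_0 = \Delta\varphi\, c/(\omega d) + 1}.
#'
#' @param sample,reference Field spectra from [to_spectrum()], sharing one
#'   frequency grid; the reference amplitude must be nonzero on the band.
#' @param geometry A [chamber_geometry()].
#' @param settings An [extraction_settings()].
#' @return An `optical_constants` tibble (columns `freq_THz`, `n`, `kappa`,
#'   `alpha_cm1`, `converged`, `iterations`); `converged` is `FALSE`
#'   throughout since no interface correction has been applied yet.
#' @export
initial_estimate <- function(sample, reference, geometry = chamber_geometry(),
                             settings = extraction_settings()) {
  rb <- ratio_on_band(sample, reference, settings, geometry)
  kappa0 <- -log(Mod(rb$ratio)^2) / (2 * rb$phi_unit)
  n0 <- rb$dphi / rb$phi_unit + 1
  new_optical_constants(rb$freq, n0, kappa0,
                        converged = rep(FALSE, length(rb$freq)),
                        iterations = rep(0L, length(rb$freq)),
                        geometry, settings, rb$ratio, rb$dphi)
}

#' Iteratively refined optical constants
#'
#' Fixed-point elimination of the Fresnel interface transmissions. Starting
#' from the [initial_estimate()], each pass forms the interface correction
#' \eqn{C_k = T_{PE\to b}T_{b\to PE} / (T_{PE\to air}T_{air\to PE})} from the
#' current complex index \eqn{\bar n_k} and updates
#' \deqn{\kappa_{k+1} = -\frac{c}{\omega d}\,(\ln|R| - \ln|C_k|), \qquad
#'       n_{k+1} = \frac{c}{\omega d}\,(\Delta\varphi - \arg C_k) + 1,}
#' stopping per frequency when both \eqn{|n_{k+1}-n_k|} and
#' \eqn{|\kappa_{k+1}-\kappa_k|} fall below `tolerance` (default 0.001).
#' Frequencies still changing at `max_iterations` are reported as-is with
#' `converged = FALSE`; oscillation (non-decreasing change over the last
#' iterations) is flagged with a warning distinct from slow convergence.
#'
#' @inheritParams initial_estimate
#' @return An `optical_constants` tibble with per-frequency iteration counts
#'   and convergence flags; \eqn{\alpha = 2\omega\kappa/c} in cm\eqn{^{-1}}.
#' @export
refine_index <- function(sample, reference, geometry = chamber_geometry(),
                         settings = extraction_settings()) {
  rb <- ratio_on_band(sample, reference, settings, geometry)
  m <- length(rb$freq)
  ln_R <- log(Mod(rb$ratio))
  n <- rb$dphi / rb$phi_unit + 1
  kappa <- -ln_R / rb$phi_unit
  ok <- !rb$degenerate & is.finite(n) & is.finite(kappa)

  converged <- rep(FALSE, m)
  iterations <- rep(0L, m)
  last_change <- rep(Inf, m)
  oscillating <- rep(FALSE, m)
  active <- ok

  for (it in seq_len(settings$max_iterations)) {
    if (!any(active)) break
    nbar <- complex(real = n[active], imaginary = pmax(kappa[active], 0))
    C <- interface_correction(nbar, geometry)
    kappa_new <- -(ln_R[active] - log(Mod(C))) / rb$phi_unit[active]
    n_new <- (rb$dphi[active] - Arg(C)) / rb$phi_unit[active] + 1
    dn <- abs(n_new - n[active])
    dk <- abs(kappa_new - kappa[active])
    change <- dn + dk
    n[active] <- n_new
    kappa[active] <- kappa_new
    iterations[active] <- it
    done <- dn < settings$tolerance & dk < settings$tolerance
    converged[active][done] <- TRUE
    # track oscillation: change not shrinking while far from tolerance
    osc <- !done & it > 3 & change >= last_change[active]
    oscillating[active][osc] <- TRUE
    oscillating[active][done] <- FALSE
    last_change[active] <- change
    idx <- which(active)
    active[idx[done]] <- FALSE
  }
  if (any(!converged & ok)) {
    n_osc <- sum(oscillating & !converged)
    warn(sprintf(
      "%d frequency bin(s) unconverged after %d iterations (%d oscillating, %d slow).",
      sum(!converged & ok), settings$max_iterations, n_osc,
      sum(!converged & ok) - n_osc))
  }
  converged[!ok] <- FALSE
  new_optical_constants(rb$freq, n, kappa, converged, iterations,
                        geometry, settings, rb$ratio, rb$dphi)
}

#' Model spectral ratio implied by extracted optical constants
#'
#' Re-synthesises the sample/reference ratio from an `optical_constants`
#' result via the forward chamber model,
#' \eqn{R = C(\bar n)\, e^{i\omega d(\bar n - 1)/c}}. Comparing this with the
#' measured ratio (attribute `measured_ratio`) is the self-consistency
#' residual test of the inversion.
#'
#' @param constants An `optical_constants` tibble from [refine_index()].
#' @return A tibble with `freq_THz`, complex `model_ratio`, complex
#'   `measured_ratio` (if available) and `residual_mod` / `residual_phase`.
#' @export
resynthesize_ratio <- function(constants) {
  stopifnot(inherits(constants, "optical_constants"))
  geometry <- attr(constants, "geometry")
  nbar <- complex(real = constants$n, imaginary = constants$kappa)
  phi <- phase_thickness(constants$freq_THz, geometry$d_um)
  model <- interface_correction(nbar, geometry) * exp(1i * phi * (nbar - 1))
  out <- tibble(freq_THz = constants$freq_THz, model_ratio = model)
  meas <- attr(constants, "measured_ratio")
  if (!is.null(meas)) {
    out$measured_ratio <- meas
    out$residual_mod <- Mod(model) - Mod(meas)
    # phase residual on the principal branch of the complex mismatch
    out$residual_phase <- Arg(model / meas)
  }
  out
}

#' Extract optical constants from time traces
#'
#' Convenience wrapper over the full inversion chain: average repeated
#' acquisitions per arm, Fourier-transform, and run the iterative Fresnel
#' correction.
#'
#' @param sample_traces,reference_traces Tibbles with columns `time_ps`,
#'   `field` and, if several acquisitions are present, `acquisition`.
#' @param geometry A [chamber_geometry()].
#' @param settings An [extraction_settings()].
#' @return An `optical_constants` tibble.
#' @export
extract_optical_constants <- function(sample_traces, reference_traces,
                                      geometry = chamber_geometry(),
                                      settings = extraction_settings()) {
  avg <- function(tr) {
    if ("acquisition" %in% names(tr) && length(unique(tr$acquisition)) > 1) {
      average_traces(tr)
    } else tr
  }
  refine_index(to_spectrum(avg(sample_traces), settings),
               to_spectrum(avg(reference_traces), settings),
               geometry, settings)
}

#' Extract optical constants for every subject of a simulated cohort
#'
#' Averages each subject's acquisitions per arm (the one-minute average),
#' transforms to spectra, and inverts. Returns one long tibble across
#' subjects, suitable for the cohort statistics layer.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param settings An [extraction_settings()].
#' @return A tibble with columns `subject_id`, `freq_THz`, `n`, `kappa`,
#'   `alpha_cm1`, `converged`, `iterations`.
#' @export
extract_cohort <- function(cohort, settings = extraction_settings()) {
  stopifnot(inherits(cohort, "thz_cohort"))
  geometry <- cohort$config$geometry
  ids <- unique(cohort$traces$subject_id)
  per <- map(ids, function(id) {
    rows <- cohort$traces[cohort$traces$subject_id == id, ]
    get_avg <- function(arm) {
      m <- rows$field[[which(rows$arm == arm)]]
      tibble(time_ps = cohort$time_ps, field = rowMeans(m))
    }
    oc <- refine_index(to_spectrum(get_avg("sample"), settings),
                       to_spectrum(get_avg("reference"), settings),
                       geometry, settings)
    mutate(as_tibble(oc), subject_id = id, .before = 1)
  })
  list_rbind(per)
}
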