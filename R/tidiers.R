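# broom-style tidiers for the package's result objects

#' Tidy a delta spectrum
#'
#' @param x A [delta_spectrum()] result.
#' @param ... Unused.
#' @return Per-frequency tibble with the observed normalized change, the
#'   fitted line and the excess/defect regime label.
#' @method tidy delta_spectrum
#' @export
tidy.delta_spectrum <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(
    freq_THz = x$freq_THz,
    delta_over_alpha = x$delta_over_alpha,
    fitted = unname(predict(fit)),
    regime = x$regime
  )
}

#' Summarise a delta spectrum fit
#'
#' @inheritParams tidy.delta_spectrum
#' @return One-row tibble: transparency frequency (THz), fitted slope and
#'   intercept, R^2, number of band frequencies, and whether the spectrum was
#'   too flat for a defined crossing.
#' @method glance delta_spectrum
#' @export
glance.delta_spectrum <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(
    transparency_freq = attr(x, "transparency_freq"),
    fit_slope = attr(x, "fit_slope"),
    fit_intercept = attr(x, "fit_intercept"),
    r_squared = summary(fit)$r.squared,
    n_freqs = nrow(x),
    flat = attr(x, "flat")
  )
}

#' Summarise the convergence of a spectral inversion
#'
#' @param x An `optical_constants` result from [refine_index()].
#' @param ... Unused.
#' @return One-row tibble with the band, bin counts, converged fraction and
#'   the iteration-count range.
#' @method glance optical_constants
#' @export
glance.optical_constants <- function(x, ...) {
  tibble(
    band_lo = min(x$freq_THz), band_hi = max(x$freq_THz),
    n_freqs = nrow(x),
    n_converged = sum(x$converged),
    converged_fraction = mean(x$converged),
    max_iterations_used = max(x$iterations),
    median_iterations = median(x$iterations)
  )
}

#' Tidy a platelet-stratified shift
#'
#' @param x A [plt_stratified_shift()] result.
#' @param ... Unused.
#' @return The per-bin tibble (bin bounds, n, mean PLT, transparency
#'   frequency, fitted slope).
#' @method tidy plt_shift
#' @export
tidy.plt_shift <- function(x, ...) x$bins

#' Summarise a platelet-stratified shift
#'
#' @inheritParams tidy.plt_shift
#' @return One-row tibble with the between-bin transparency shift (THz,
#'   negative = red shift) and the bin count.
#' @method glance plt_shift
#' @export
glance.plt_shift <- function(x, ...) {
  tibble(shift_THz = x$shift, n_bins = nrow(x$bins))
}
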