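#' Settings of the spectral inversion
#'
#' @param tolerance Per-frequency convergence tolerance on both `n` and
#'   `kappa` (absolute change between iterations; default 0.001).
#' @param max_iterations Iteration cap per frequency.
#' @param band Analysis band in THz (default 0.13-1.02, the measured range).
#' @param window Apodization: `"rectangular"` (default; traces are pulse-like
#'   and decay within the span) or `"hann"`.
#' @param pad_factor Zero-padding factor of the FFT (default 4).
#' @param phase_anchor Frequency (THz) where the unwrapped phase branch is
#'   anchored to a physically plausible index.
#' @return An object of class `extraction_settings`.
#' @export
extraction_settings <- function(tolerance = 0.001,
                                max_iterations = 100L,
                                band = c(0.13, 1.02),
                                window = c("rectangular", "hann"),
                                pad_factor = 4L,
                                phase_anchor = 0.13) {
  window <- match.arg(window)
  tolerance <- as.numeric(tolerance)
  band <- as.numeric(band)
  phase_anchor <- as.numeric(phase_anchor)
  if (tolerance <= 0) abort("`tolerance` must be positive.",
                            class = "thzcoag_config_error")
  if (band[1] >= band[2] || band[1] <= 0) {
    abort("`band` must be a positive, increasing interval.",
          class = "thzcoag_config_error")
  }
  structure(
    list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
         band = band, window = window, pad_factor = as.integer(pad_factor),
         phase_anchor = phase_anchor),
    class = "extraction_settings"
  )
}

#' Fourier transform of a time trace into a complex field spectrum
#'
#' Discrete Fourier transform after optional apodization and zero-padding,
#' under the convention \eqn{E(\omega) = \sum_j E(t_j) e^{+i\omega t_j}}, so
#' that a pure delay by \eqn{\Delta t} produces phase \eqn{+\omega\Delta t}
#' (matching the propagation factor \eqn{e^{i\omega d n/c}}).
#'
#' @param trace A tibble with columns `time_ps`, `field` on a uniform grid.
#' @param settings An [extraction_settings()].
#' @return A tibble with columns `freq_THz` (positive, strictly increasing,
#'   DC excluded) and complex `amplitude`.
#' @export
to_spectrum <- function(trace, settings = extraction_settings()) {
  stopifnot(is.data.frame(trace))
  if (!all(c("time_ps", "field") %in% names(trace))) {
    abort("`trace` needs columns time_ps and field.", class = "thzcoag_input_error")
  }
  trace <- arrange(trace, time_ps)
  t <- trace$time_ps
  dt <- diff(t)
  if (length(t) < 8 || any(abs(dt - dt[1]) > 1e-9 * dt[1])) {
    abort("Time grid must be uniform.", class = "thzcoag_input_error")
  }
  dt <- dt[1]
  x <- trace$field
  if (any(!is.finite(x))) abort("Non-finite field values.",
                                class = "thzcoag_input_error")
  if (settings$window == "hann") {
    N0 <- length(x)
    x <- x * 0.5 * (1 - cos(2 * pi * (seq_len(N0) - 1) / (N0 - 1)))
  }
  M <- length(x) * settings$pad_factor
  # fft(., inverse = TRUE) computes sum_j x_j e^{+2*pi*i*jk/M}: the +omega*t
  # convention relative to the first sample; the absolute start time enters
  # as a linear phase below.
  X <- stats::fft(c(x, rep(0, M - length(x))), inverse = TRUE)
  k <- 1:(M / 2)
  freq <- k / (M * dt) # THz, since dt is in ps
  amp <- X[k + 1] * exp(1i * thz_omega(freq) * t[1])
  tibble(freq_THz = freq, amplitude = amp)
}
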