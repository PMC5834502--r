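#' THz time-domain spectrometer model
#'
#' Acquisition parameters of the simulated spectrometer. The optical-delay
#' grid has `trace_length` samples at `time_step` ps; the noise floor is set
#' by the single-trace peak dynamic range in dB (peak signal over RMS noise
#' floor); `traces_per_minute` waveforms are averaged into each one-minute
#' spectrum.
#'
#' @param time_step Delay step in ps.
#' @param trace_length Number of samples per trace.
#' @param peak_dynamic_range Single-trace peak dynamic range in dB (peak
#'   signal over RMS noise floor); `Inf` disables noise. The instrument's
#'   quoted floor is "greater than 48 dB"; the default of 54 dB models the
#'   typical performance implied by the sub-percent water repeatability the
#'   same instrument achieves over 0.1-1.2 THz.
#' @param traces_per_minute Number of consecutive traces averaged per minute.
#' @param source_band Frequency interval (THz) the source spectrum covers.
#' @param source_peak Spectral peak of the source pulse, THz.
#' @param source_shoulder Relative amplitude of the weak fast component
#'   (peaking at five times `source_peak`) that extends usable signal to the
#'   upper band edge, as broadband photoconductive-antenna emitters show.
#' @param pulse_delay Arrival time of the pulse centre within the trace, ps.
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(time_step = 0.05,
                             trace_length = 512,
                             peak_dynamic_range = 54,
                             traces_per_minute = 120,
                             source_band = c(0.1, 3),
                             source_peak = 0.3,
                             source_shoulder = 0.4,
                             pulse_delay = 10) {
  time_step <- as.numeric(time_step)
  trace_length <- as.integer(trace_length)
  peak_dynamic_range <- as.numeric(peak_dynamic_range)
  traces_per_minute <- as.integer(traces_per_minute)
  source_band <- as.numeric(source_band)
  source_peak <- as.numeric(source_peak)
  source_shoulder <- as.numeric(source_shoulder)
  pulse_delay <- as.numeric(pulse_delay)
  nyquist <- 1 / (2 * time_step)
  if (nyquist < max(source_band)) {
    abort(sprintf(
      "Nyquist frequency %.2f THz is below the source band upper edge %.2f THz.",
      nyquist, max(source_band)), class = "thzcoag_config_error")
  }
  if (trace_length < 8 || time_step <= 0) {
    abort("Invalid time grid.", class = "thzcoag_config_error")
  }
  structure(
    list(time_step = time_step, trace_length = trace_length,
         peak_dynamic_range = peak_dynamic_range,
         traces_per_minute = traces_per_minute,
         source_band = source_band, source_peak = source_peak,
         source_shoulder = source_shoulder, pulse_delay = pulse_delay),
    class = "instrument_model"
  )
}

# native one-sided frequency grid of the instrument (THz), k = 1..N/2
instrument_freqs <- function(instrument) {
  N <- instrument$trace_length
  (1:(N / 2)) / (N * instrument$time_step)
}

# single-cycle source pulse, specified in the frequency domain as the sum of
# a main lobe peaking at source_peak and a weak fast shoulder (five times
# higher peak, source_shoulder relative amplitude) that carries usable signal
# to the upper edge of the source band. Each component has the smooth shape
# (w*tau/2)^2 exp(2 - w*tau): the omega^2 prefactor keeps the mirrored
# spectrum smooth through DC, so the time-domain pulse decays fast (~t^-3)
# and fits the acquisition window. The linear phase e^{i w t0} centres the
# pulse at pulse_delay.
source_spectrum <- function(freq_THz, instrument) {
  w <- thz_omega(freq_THz)
  lobe <- function(tau) (w * tau / 2)^2 * exp(2 - w * tau)
  tau1 <- 2 / (2 * pi * instrument$source_peak)
  (lobe(tau1) + instrument$source_shoulder * lobe(tau1 / 5)) *
    exp(1i * w * instrument$pulse_delay)
}

# Hermitian inverse DFT: build a real N-point trace whose analysis spectrum
# sum_j x_j e^{+i w_k t_j} equals S_half on the native grid k = 1..N/2.
hermitian_ifft <- function(S_half, N) {
  stopifnot(length(S_half) == N / 2)
  S_full <- complex(length.out = N)
  S_full[1] <- 0 # zero-mean field
  S_half[N / 2] <- complex(real = Re(S_half[N / 2]), imaginary = 0)
  S_full[2:(N / 2 + 1)] <- S_half
  S_full[N:(N / 2 + 2)] <- Conj(S_half[1:(N / 2 - 1)])
  Re(stats::fft(S_full)) / N
}

# synthesis oversampling: clean traces are rendered on a grid 8x longer than
# the acquisition window and truncated, so the emitted trace samples the
# continuous-time pulse (no periodic wrap-around of the pulse tails)
.gen_oversample <- 8L

# clean reference/sample time traces for one subject's optical constants.
# `index_fun` maps a frequency vector to a tibble with columns n, kappa.
clean_trace_pair <- function(index_fun, geometry, instrument, echo = FALSE) {
  N <- instrument$trace_length
  M <- N * .gen_oversample
  fk <- (1:(M / 2)) / (M * instrument$time_step)
  src <- source_spectrum(fk, instrument)
  optics <- index_fun(fk)
  S_ref <- src * chamber_transfer(fk, geometry, filled = FALSE, echo = echo)
  S_sam <- src * chamber_transfer(fk, geometry, n = optics$n,
                                  kappa = optics$kappa, filled = TRUE,
                                  echo = echo)
  ref <- hermitian_ifft(S_ref, M)[1:N]
  sam <- hermitian_ifft(S_sam, M)[1:N]
  scale <- 1 / max(abs(ref)) # arbitrary units: reference peak = 1
  list(time_ps = (0:(N - 1)) * instrument$time_step,
       reference = ref * scale, sample = sam * scale)
}

# matrix of noisy acquisitions (trace_length x n_traces) from a clean trace
noisy_acquisitions <- function(clean, n_traces, noise_sd) {
  m <- matrix(clean, nrow = length(clean), ncol = n_traces)
  if (noise_sd > 0) {
    m <- m + matrix(rnorm(length(clean) * n_traces, sd = noise_sd),
                    nrow = length(clean))
  }
  m
}

#' Average a set of time traces
#'
#' Pointwise arithmetic mean of repeated acquisitions sharing one time grid
#' and one arm, the numerical analogue of the one-minute waveform average.
#'
#' @param traces A tibble with columns `time_ps`, `field`, `acquisition`, and
#'   optionally `arm` (must be constant).
#' @return A tibble with columns `time_ps`, `field` (and `arm` if supplied);
#'   the number of averaged traces is recorded in attribute `n_traces` and the
#'   acquisition index is the sentinel `NA`.
#' @export
average_traces <- function(traces) {
  stopifnot(is.data.frame(traces))
  if (!all(c("time_ps", "field", "acquisition") %in% names(traces))) {
    abort("`traces` needs columns time_ps, field, acquisition.",
          class = "thzcoag_input_error")
  }
  if ("arm" %in% names(traces) && length(unique(traces$arm)) > 1) {
    abort("Cannot average traces from different arms.",
          class = "thzcoag_input_error")
  }
  grids <- split(traces$time_ps, traces$acquisition)
  if (length(unique(map_chr(grids, function(g) paste(signif(g, 12), collapse = ",")))) > 1) {
    abort("All acquisitions must share the same time grid.",
          class = "thzcoag_input_error")
  }
  out <- traces |>
    group_by(time_ps) |>
    summarise(field = mean(field), .groups = "drop") |>
    arrange(time_ps) |>
    mutate(acquisition = NA_integer_)
  if ("arm" %in% names(traces)) out$arm <- traces$arm[[1]]
  attr(out, "n_traces") <- length(grids)
  out
}
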