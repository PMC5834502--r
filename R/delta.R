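# Normalized absorption-change spectra and transparency-frequency estimation.

#' Normalized absorption-change spectrum and transparency frequency
#'
#' Computes \eqn{\Delta\alpha/\alpha_{blood}} per frequency, where
#' \eqn{\Delta\alpha = \alpha_{state} - \alpha_{blood}} is the difference
#' between a coagulation-state mean spectrum and the uncoagulated mean
#' spectrum, fits a line in frequency over the band by unweighted least
#' squares, and locates the transparency frequency as the fitted zero
#' crossing \eqn{f_t = -\mathrm{intercept}/\mathrm{slope}}. The fitted line
#' (not the nearest raw sign change) defines \eqn{f_t}, which is robust to
#' etalon ripple; frequencies above \eqn{f_t} are labelled `excess`
#' (increased absorption), those below `defect`.
#'
#' @param alpha_state Per-frequency mean absorption of the coagulation state:
#'   tibble with `freq_THz`, `alpha_cm1`.
#' @param alpha_blood Per-frequency mean absorption of uncoagulated blood on
#'   the same grid; must be positive on the band.
#' @param band Fit band in THz.
#' @param min_slope Minimum absolute fitted slope (per THz) for the zero
#'   crossing to be considered defined; flatter spectra give `NA` with a flag.
#' @return A `delta_spectrum` tibble with columns `freq_THz`,
#'   `delta_over_alpha`, `regime` (`excess`/`defect`); attributes carry the
#'   `lm` fit, `fit_slope`, `fit_intercept`, `transparency_freq` and `band`.
#'   Use [glance()] for a one-row summary.
#' @export
delta_spectrum <- function(alpha_state, alpha_blood, band = c(0.13, 1.02),
                           min_slope = 0.005) {
  for (nm in list(alpha_state, alpha_blood)) {
    if (!all(c("freq_THz", "alpha_cm1") %in% names(nm))) {
      abort("Inputs need columns freq_THz and alpha_cm1.",
            class = "thzcoag_input_error")
    }
  }
  joined <- inner_join_grid(alpha_state, alpha_blood)
  joined <- joined |>
    filter(.data$freq_THz >= band[1], .data$freq_THz <= band[2])
  if (nrow(joined) < 3) {
    abort("Fewer than 3 shared frequencies on the band.",
          class = "thzcoag_input_error")
  }
  if (any(joined$alpha_blood <= 0)) {
    abort("alpha_blood must be positive on the band.",
          class = "thzcoag_input_error")
  }
  joined <- mutate(joined,
                   delta_over_alpha = (alpha_state - alpha_blood) / alpha_blood)
  fit <- stats::lm(delta_over_alpha ~ freq_THz, data = joined)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  f_t <- if (is.finite(slope) && abs(slope) >= min_slope) {
    -intercept / slope
  } else NA_real_
  out <- joined |>
    select("freq_THz", "delta_over_alpha") |>
    mutate(regime = dplyr::if_else(
      rep(!is.na(f_t), dplyr::n()) & .data$freq_THz > f_t, "excess", "defect"))
  structure(out, class = c("delta_spectrum", class(out)),
            fit = fit, fit_slope = slope, fit_intercept = intercept,
            transparency_freq = f_t, flat = is.na(f_t), band = band)
}

# internal: join two per-frequency spectra on a shared grid
inner_join_grid <- function(alpha_state, alpha_blood) {
  a <- alpha_state |> select("freq_THz", alpha_state = "alpha_cm1")
  b <- alpha_blood |> select("freq_THz", alpha_blood = "alpha_cm1")
  j <- dplyr::inner_join(a, b, by = "freq_THz")
  if (nrow(j) == 0) {
    abort("Spectra share no frequencies; supply matching grids.",
          class = "thzcoag_input_error")
  }
  j
}

#' Transparency frequency of a delta spectrum
#'
#' @param x A [delta_spectrum()] result.
#' @return The fitted zero-crossing frequency in THz (`NA` if the fitted
#'   line is too flat for a defined crossing).
#' @export
transparency_freq <- function(x) {
  stopifnot(inherits(x, "delta_spectrum"))
  attr(x, "transparency_freq")
}

#' Platelet-stratified transparency-frequency shift
#'
#' Splits early-coagulated (or thrombus) subjects into platelet-count bins
#' after the RBC filter, computes the per-bin mean normalized
#' absorption-change spectrum against a common uncoagulated mean spectrum,
#' fits each bin's transparency frequency, and reports the shift between the
#' last and first bins (negative = red shift with increasing PLT).
#'
#' Bins are left-closed, right-open, except the last bin which is closed, so
#' a boundary count belongs to the higher bin.
#'
#' @param records Subject records of the coagulation-state group (columns
#'   `subject_id`, `rbc`, `plt`).
#' @param alphas Long tibble `subject_id`, `freq_THz`, `alpha_cm1` for those
#'   subjects.
#' @param alpha_blood Per-frequency uncoagulated mean spectrum
#'   (`freq_THz`, `alpha_cm1`).
#' @param bins List of PLT intervals in K/uL, ordered low to high.
#' @param rbc_range RBC filter passed to [filter_subjects()]; `NULL` skips it.
#' @param band,min_slope Passed to [delta_spectrum()].
#' @return An object of class `plt_shift`: list with `bins` (tibble of bin
#'   label, n, mean PLT, transparency frequency, fitted slope), `shift`
#'   (THz, \eqn{f_t(\mathrm{last}) - f_t(\mathrm{first})}), and the per-bin
#'   `delta_spectra`. [tidy()] returns the bin table, [glance()] the shift.
#' @export
plt_stratified_shift <- function(records, alphas, alpha_blood,
                                 bins = list(low = c(100, 200),
                                             high = c(200, 300)),
                                 rbc_range = c(4, 5),
                                 band = c(0.13, 1.02), min_slope = 0.005) {
  stopifnot(is.data.frame(records), is.data.frame(alphas))
  if (!is.null(rbc_range)) {
    records <- records |>
      filter(.data$rbc > rbc_range[1], .data$rbc <= rbc_range[2])
  }
  labels <- names(bins) %||% paste0("bin", seq_along(bins))
  last <- length(bins)
  rows <- list(); spectra <- list()
  for (i in seq_along(bins)) {
    b <- bins[[i]]
    in_bin <- records$plt >= b[1] &
      (if (i == last) records$plt <= b[2] else records$plt < b[2])
    sub <- records[in_bin, ]
    if (nrow(sub) == 0) {
      warn(sprintf("PLT bin [%g, %g%s skipped: no subjects after filters.",
                   b[1], b[2], if (i == last) "]" else ")"))
      next
    }
    mean_state <- alphas |>
      filter(.data$subject_id %in% sub$subject_id) |>
      minute_average_alpha()
    ds <- delta_spectrum(mean_state, alpha_blood, band = band,
                         min_slope = min_slope)
    spectra[[labels[i]]] <- ds
    rows[[labels[i]]] <- tibble(
      bin = labels[i], plt_low = b[1], plt_high = b[2],
      n = nrow(sub), plt_mean = mean(sub$plt),
      transparency_freq = transparency_freq(ds),
      fit_slope = attr(ds, "fit_slope")
    )
  }
  if (length(rows) == 0) {
    abort("All PLT bins are empty after filters.", class = "thzcoag_input_error")
  }
  bins_tbl <- list_rbind(rows)
  shift <- if (nrow(bins_tbl) >= 2) {
    bins_tbl$transparency_freq[nrow(bins_tbl)] - bins_tbl$transparency_freq[1]
  } else NA_real_
  structure(list(bins = bins_tbl, shift = shift, delta_spectra = spectra,
                 band = band),
            class = "plt_shift")
}

#' @export
print.plt_shift <- function(x, ...) {
  cat("<plt_shift> transparency-frequency shift:",
      formatC(x$shift, digits = 3, format = "f"), "THz\n")
  print(x$bins)
  invisible(x)
}
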