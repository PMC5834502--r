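# ggplot2 autoplot methods

#' Plot extracted optical constants
#'
#' Faceted view of n, kappa and the absorption constant versus frequency;
#' unconverged bins are drawn as open points.
#'
#' @param object An `optical_constants` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot optical_constants
#' @export
autoplot.optical_constants <- function(object, ...) {
  long <- as_tibble(object) |>
    pivot_longer(c("n", "kappa", "alpha_cm1"),
                 names_to = "quantity", values_to = "value") |>
    mutate(quantity = factor(.data$quantity,
                             levels = c("n", "kappa", "alpha_cm1"),
                             labels = c("n", "kappa", "alpha (1/cm)")))
  ggplot(long, aes(x = .data$freq_THz, y = .data$value)) +
    geom_line() +
    geom_point(data = ~ filter(.x, !.data$converged), shape = 1) +
    facet_wrap(vars(.data$quantity), scales = "free_y", ncol = 1) +
    labs(x = "frequency (THz)", y = NULL) +
    theme_minimal()
}

#' Plot a normalized absorption-change spectrum
#'
#' The per-frequency \eqn{\Delta\alpha/\alpha_{blood}} curve with its linear
#' fit; the zero line and the fitted transparency frequency are marked.
#'
#' @param object A [delta_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delta_spectrum
#' @export
autoplot.delta_spectrum <- function(object, ...) {
  td <- tidy(object)
  f_t <- attr(object, "transparency_freq")
  p <- ggplot(td, aes(x = .data$freq_THz, y = .data$delta_over_alpha)) +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_point(aes(shape = .data$regime)) +
    geom_line(aes(y = .data$fitted), linetype = 2) +
    labs(x = "frequency (THz)",
         y = expression(Delta * alpha / alpha["blood"]),
         shape = NULL) +
    theme_minimal()
  if (is.finite(f_t %||% NA_real_)) {
    p <- p + geom_vline(xintercept = f_t, linetype = 3)
  }
  p
}

#' Plot platelet-stratified delta spectra
#'
#' One curve per PLT bin with each bin's fitted transparency frequency.
#'
#' @param object A [plt_stratified_shift()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plt_shift
#' @export
autoplot.plt_shift <- function(object, ...) {
  td <- list_rbind(imap(object$delta_spectra, function(d, b) {
    mutate(tidy(d), bin = b, .before = 1)
  }))
  ggplot(td, aes(x = .data$freq_THz, y = .data$delta_over_alpha,
                 colour = .data$bin)) +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_point() +
    geom_line(aes(y = .data$fitted), linetype = 2) +
    geom_vline(data = object$bins,
               aes(xintercept = .data$transparency_freq,
                   colour = .data$bin),
               linetype = 3) +
    labs(x = "frequency (THz)",
         y = expression(Delta * alpha / alpha["blood"]),
         colour = "PLT bin") +
    theme_minimal()
}
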