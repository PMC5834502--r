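# Cohort statistics: minute averages, hematology filters, pooled two-sample
# t-tests with significance stars, and Pearson correlation against covariates.

#' Per-frequency mean absorption over a set of spectra
#'
#' Arithmetic mean of the absorption constant per frequency across the input
#' rows (e.g. across the spectra belonging to one acquisition minute, or
#' across the subjects of a group).
#'
#' @param constants A data frame with columns `freq_THz` and `alpha_cm1`
#'   (extra columns such as `subject_id` are allowed and ignored).
#' @return A tibble with `freq_THz`, mean `alpha_cm1` and the count `n_spectra`.
#' @export
minute_average_alpha <- function(constants) {
  stopifnot(is.data.frame(constants))
  if (nrow(constants) == 0) {
    abort("Empty set of spectra.", class = "thzcoag_input_error")
  }
  if (!all(c("freq_THz", "alpha_cm1") %in% names(constants))) {
    abort("Need columns freq_THz and alpha_cm1.", class = "thzcoag_input_error")
  }
  constants |>
    group_by(freq_THz) |>
    summarise(alpha_cm1 = mean(alpha_cm1), n_spectra = dplyr::n(),
              .groups = "drop") |>
    arrange(freq_THz)
}

#' Filter subject records on hematology ranges
#'
#' Retains subjects with RBC count strictly above the lower bound and at or
#' below the upper bound (the half-open "4 < RBC <= 5 M/uL" convention) and
#' platelet count inside the closed PLT range. Row order is preserved.
#'
#' @param records Subject records with columns `rbc` and `plt`.
#' @param rbc_range Half-open RBC interval `(lo, hi]` in M/uL.
#' @param plt_range Closed PLT interval in K/uL.
#' @return The filtered records (possibly empty).
#' @export
filter_subjects <- function(records, rbc_range = c(4, 5),
                            plt_range = c(100, 300)) {
  stopifnot(is.data.frame(records))
  if (rbc_range[1] >= rbc_range[2] || plt_range[1] >= plt_range[2]) {
    abort("Filter ranges must be increasing.", class = "thzcoag_input_error")
  }
  records |>
    filter(.data$rbc > rbc_range[1], .data$rbc <= rbc_range[2],
           .data$plt >= plt_range[1], .data$plt <= plt_range[2])
}

#' Significance stars for a p-value
#'
#' Bins as conventionally printed: `***` for p < 0.001, `**` for
#' 0.001 < p < 0.01, `*` for 0.01 < p < 0.05, `ns` otherwise. The bins are
#' open intervals; a p-value landing exactly on a boundary is labelled at the
#' less significant side.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01  ~ "**",   # includes the boundary p == 0.001 (conservative)
    p < 0.05  ~ "*",    # includes the boundary p == 0.01
    TRUE      ~ "ns"    # includes the boundary p == 0.05
  )
}

#' Pooled-variance two-sample t-test
#'
#' Two-tailed unpaired t-test with the classic equal-variance (pooled)
#' statistic and the 95 percent confidence interval of the mean difference
#' \eqn{\bar a - \bar b}. Matches the default semantics of the usual
#' two-sample t-test of numerical packages. With zero pooled variance the
#' degenerate conventions apply: equal means give p = 1, unequal means give
#' p = 0 and are flagged.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled (equal-variance) statistic (default); set
#'   `FALSE` for the Welch unequal-variance form.
#' @param conf_level Confidence level of the difference CI.
#' @return A one-row tibble: `n_a`, `n_b`, `mean_a`, `mean_b`, `t_statistic`,
#'   `p_value`, `ci_low`, `ci_high`, `stars`, `degenerate`.
#' @export
unpaired_ttest <- function(a, b, var_equal = TRUE, conf_level = 0.95) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least two finite observations.",
          class = "thzcoag_input_error")
  }
  degenerate <- FALSE
  if (var(a) == 0 && var(b) == 0) {
    degenerate <- TRUE
    d <- mean(a) - mean(b)
    res <- tibble(
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b),
      t_statistic = if (d == 0) 0 else sign(d) * Inf,
      p_value = if (d == 0) 1 else 0,
      ci_low = d, ci_high = d
    )
  } else {
    ht <- stats::t.test(a, b, var.equal = var_equal,
                        conf.level = conf_level)
    res <- tibble(
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b),
      t_statistic = unname(ht$statistic),
      p_value = ht$p.value,
      ci_low = ht$conf.int[1], ci_high = ht$conf.int[2]
    )
  }
  res |> mutate(stars = p_stars(p_value), degenerate = degenerate)
}

#' Per-frequency group comparison of absorption constants
#'
#' Runs [unpaired_ttest()] at each frequency between two subject groups.
#' No multiple-testing correction is applied across frequencies: the
#' comparison mirrors per-frequency reporting, and the per-frequency p-values
#' should be read accordingly.
#'
#' @param alphas Long tibble with columns `subject_id`, `freq_THz`,
#'   `alpha_cm1` (one spectrum per subject).
#' @param records Subject records with `subject_id` and `group`.
#' @param group_a,group_b Group labels to compare (difference is a - b).
#' @param freqs Optional frequencies (THz) to restrict to; each is matched to
#'   the nearest available grid frequency. Default: all frequencies.
#' @inheritParams unpaired_ttest
#' @return A tibble with one row per frequency and the [unpaired_ttest()]
#'   columns.
#' @export
compare_groups <- function(alphas, records, group_a, group_b,
                           freqs = NULL, var_equal = TRUE) {
  joined <- alphas |>
    left_join(select(records, "subject_id", "group"), by = "subject_id") |>
    filter(.data$group %in% c(group_a, group_b))
  if (nrow(joined) == 0) {
    abort("No spectra for the requested groups.", class = "thzcoag_input_error")
  }
  grid <- sort(unique(joined$freq_THz))
  sel <- if (is.null(freqs)) grid else
    grid[vapply(freqs, function(f) which.min(abs(grid - f)), integer(1))]
  list_rbind(map(sel, function(f) {
    at_f <- joined[joined$freq_THz == f, ]
    unpaired_ttest(at_f$alpha_cm1[at_f$group == group_a],
                   at_f$alpha_cm1[at_f$group == group_b],
                   var_equal = var_equal) |>
      mutate(freq_THz = f, .before = 1)
  }))
}

#' Pearson correlation between absorption and a covariate
#'
#' Bivariate Pearson correlation with the two-sided p-value from the
#' t-distributed transform of r. A correlation is declared (`significant`)
#' only when p < 0.05. Zero variance in either input yields an undefined r
#' and is flagged.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); non-finite pairs are
#'   dropped.
#' @param covariate Optional name recorded in the output.
#' @return A one-row tibble: `covariate`, `r`, `p_value`, `n`, `stars`,
#'   `significant`, `undefined`.
#' @export
pearson_correlation <- function(x, y, covariate = NA_character_) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    abort("Need at least three complete pairs.", class = "thzcoag_input_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    return(tibble(covariate = covariate, r = NA_real_, p_value = NA_real_,
                  n = length(x), stars = NA_character_, significant = FALSE,
                  undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(covariate = covariate, r = unname(ct$estimate),
         p_value = ct$p.value, n = length(x),
         stars = p_stars(ct$p.value),
         significant = ct$p.value < 0.05, undefined = FALSE)
}

#' Correlate per-subject absorption at one frequency with a covariate
#'
#' @param alphas Long tibble `subject_id`, `freq_THz`, `alpha_cm1`.
#' @param records Subject records containing the covariate column.
#' @param covariate Covariate column name (e.g. `"rbc"`, `"plt"`).
#' @param freq Frequency in THz (nearest grid frequency is used).
#' @return A one-row tibble from [pearson_correlation()] plus `freq_THz`.
#' @export
correlate_covariate <- function(alphas, records, covariate, freq) {
  grid <- sort(unique(alphas$freq_THz))
  f <- grid[which.min(abs(grid - freq))]
  at_f <- alphas[alphas$freq_THz == f, ] |>
    left_join(records, by = "subject_id")
  pearson_correlation(at_f$alpha_cm1, at_f[[covariate]],
                      covariate = covariate) |>
    mutate(freq_THz = f, .before = 1)
}
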