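# shared fixtures: analytic spectra, noiseless configs, closed-form oracles

# analytic reference/sample field spectra for a homogeneous liquid (n, kappa)
# in the default chamber, on a given frequency grid; source spectrum is S0.
analytic_spectra <- function(freq, n, kappa, geometry = chamber_geometry(),
                             S0 = 1 + 0i) {
  ref <- S0 * chamber_transfer(freq, geometry, filled = FALSE)
  sam <- S0 * chamber_transfer(freq, geometry, n = rep(n, length(freq)),
                               kappa = rep(kappa, length(freq)))
  list(sample = tibble::tibble(freq_THz = freq, amplitude = sam),
       reference = tibble::tibble(freq_THz = freq, amplitude = ref))
}

# noiseless pure-water cohort config (no RBC effect, no subject scatter)
water_config <- function(groups = c(uncoagulated = 1L), noiseless = TRUE, ...) {
  cohort_config(
    groups = groups,
    instrument = instrument_model(
      peak_dynamic_range = if (noiseless) Inf else 54),
    rbc_coeff = 0, subject_sdlog = 0, ...)
}

# minute-averaged trace tibbles for one subject of a simulated cohort
subject_avg_traces <- function(cohort, subject_id) {
  rows <- cohort$traces[cohort$traces$subject_id == subject_id, ]
  get <- function(arm) {
    m <- rows$field[[which(rows$arm == arm)]]
    tibble::tibble(time_ps = cohort$time_ps, field = rowMeans(m))
  }
  list(sample = get("sample"), reference = get("reference"))
}

# closed-form pooled two-sample t-test, written independently of the package
oracle_pooled_t <- function(a, b, conf_level = 0.95) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (mean(a) - mean(b)) / se
  df <- na + nb - 2
  p <- 2 * pt(-abs(t), df)
  half <- qt(1 - (1 - conf_level) / 2, df) * se
  list(t = t, p = p, ci = c(mean(a) - mean(b) - half, mean(a) - mean(b) + half))
}

# closed-form Pearson r and two-sided p via the t transform, independent
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# platelet-stratification protocol: an early-coagulated cohort large enough
# that both PLT bins keep >= 9 subjects after the RBC filter, trimmed to 9
# per bin, against the 28-subject uncoagulated mean spectrum
strat_protocol <- function(seed, n_per_bin = 9) {
  for (size in c(44L, 64L, 88L)) {
    cfg <- cohort_config(groups = c(uncoagulated = 28L,
                                    early_coagulated = size))
    co <- suppressMessages(simulate_cohort(cfg, seed = seed))
    subj <- co$subjects
    early <- subj[subj$group == "early_coagulated" &
                    subj$rbc > 4 & subj$rbc <= 5, ]
    lo <- early[early$plt >= 100 & early$plt < 200, ]
    hi <- early[early$plt >= 200 & early$plt <= 300, ]
    if (nrow(lo) >= n_per_bin && nrow(hi) >= n_per_bin) {
      sel <- rbind(utils::head(lo, n_per_bin), utils::head(hi, n_per_bin))
      al <- extract_cohort(co)
      blood_ids <- subj$subject_id[subj$group == "uncoagulated"]
      blood <- minute_average_alpha(al[al$subject_id %in% blood_ids, ])
      return(plt_stratified_shift(
        sel, al[al$subject_id %in% sel$subject_id, ], blood,
        rbc_range = NULL))
    }
    seed <- seed + 10000L # redraw a larger cohort deterministically
  }
  stop("could not fill PLT bins")
}

# per-frequency grid step of the default zero-padded analysis grid, THz
default_grid_step <- function() {
  ins <- instrument_model()
  1 / (ins$trace_length * 4L * ins$time_step)
}
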