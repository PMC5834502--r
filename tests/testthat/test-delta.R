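# normalized absorption-change spectra and transparency frequency

test_that("identical spectra give a flat delta with no defined crossing", {
  f <- seq(0.13, 1.02, by = 0.01)
  a <- tibble::tibble(freq_THz = f, alpha_cm1 = 100 + 50 * f)
  ds <- delta_spectrum(a, a)
  expect_equal(ds$delta_over_alpha, rep(0, length(f)))
  expect_true(is.na(transparency_freq(ds)))
  expect_true(glance(ds)$flat)
})

test_that("a constructed linear change crosses zero where built", {
  f <- seq(0.13, 1.02, by = 0.01)
  blood <- tibble::tibble(freq_THz = f, alpha_cm1 = rep(120, length(f)))
  state <- tibble::tibble(freq_THz = f,
                          alpha_cm1 = 120 * (1 + 0.1 * (f - 0.68)))
  ds <- delta_spectrum(state, blood)
  expect_equal(transparency_freq(ds), 0.68, tolerance = 1e-10)
  expect_equal(glance(ds)$fit_slope, 0.1, tolerance = 1e-10)
  expect_identical(unique(ds$regime[ds$freq_THz > 0.69]), "excess")
  expect_identical(unique(ds$regime[ds$freq_THz < 0.67]), "defect")
})

test_that("delta spectrum rejects broken inputs", {
  f <- seq(0.2, 1, by = 0.1)
  a <- tibble::tibble(freq_THz = f, alpha_cm1 = rep(1, length(f)))
  bad <- tibble::tibble(freq_THz = f, alpha_cm1 = rep(0, length(f)))
  expect_error(delta_spectrum(a, bad), class = "thzcoag_input_error")
  other_grid <- tibble::tibble(freq_THz = f + 0.001, alpha_cm1 = rep(1, length(f)))
  expect_error(delta_spectrum(a, other_grid), class = "thzcoag_input_error")
})

test_that("platelet stratification recovers constructed crossings and shift", {
  f <- seq(0.13, 1.02, by = 0.01)
  blood <- tibble::tibble(freq_THz = f, alpha_cm1 = rep(100, length(f)))
  line <- function(f0) tibble::tibble(
    freq_THz = f, alpha_cm1 = 100 * (1 + 0.1 * (f - f0)))
  records <- tibble::tibble(
    subject_id = c("L1", "L2", "H1", "H2"),
    rbc = rep(4.5, 4), plt = c(150, 160, 240, 250))
  alphas <- dplyr::bind_rows(
    dplyr::mutate(line(0.9), subject_id = "L1"),
    dplyr::mutate(line(0.9), subject_id = "L2"),
    dplyr::mutate(line(0.4), subject_id = "H1"),
    dplyr::mutate(line(0.4), subject_id = "H2"))
  ps <- plt_stratified_shift(records, alphas, blood)
  expect_equal(ps$bins$transparency_freq, c(0.9, 0.4), tolerance = 1e-9)
  expect_equal(ps$shift, -0.5, tolerance = 1e-9)
  expect_equal(glance(ps)$shift_THz, ps$shift)
  # identical spectra in both bins: zero shift
  alphas0 <- dplyr::bind_rows(lapply(records$subject_id, function(id)
    dplyr::mutate(line(0.65), subject_id = id)))
  ps0 <- plt_stratified_shift(records, alphas0, blood)
  expect_equal(ps0$shift, 0, tolerance = 1e-9)
})

test_that("empty platelet bins are skipped with a warning", {
  f <- seq(0.13, 1.02, by = 0.01)
  blood <- tibble::tibble(freq_THz = f, alpha_cm1 = rep(100, length(f)))
  records <- tibble::tibble(subject_id = "X1", rbc = 4.5, plt = 150)
  alphas <- tibble::tibble(freq_THz = f,
                           alpha_cm1 = 100 * (1 + 0.1 * (f - 0.9)),
                           subject_id = "X1")
  expect_warning(ps <- plt_stratified_shift(records, alphas, blood),
                 regexp = "skipped")
  expect_identical(nrow(ps$bins), 1L)
  expect_true(is.na(ps$shift))
})

test_that("a noiseless generator cohort returns the generator's crossing", {
  # early-coagulated subjects without scatter: the mean normalized change is
  # an exact line crossing zero at f_t evaluated at the cohort-mean PLT
  cfg <- water_config(groups = c(uncoagulated = 3L, early_coagulated = 6L))
  co <- suppressMessages(simulate_cohort(cfg, seed = 17))
  al <- extract_cohort(co)
  subj <- co$subjects
  ms <- function(g) minute_average_alpha(
    al[al$subject_id %in% subj$subject_id[subj$group == g], ])
  ds <- delta_spectrum(ms("early_coagulated"), ms("uncoagulated"))
  f_t_true <- mean(transparency_frequency(
    subj$plt[subj$group == "early_coagulated"], cfg$effect))
  expect_equal(transparency_freq(ds), f_t_true, tolerance = 0.02)
})
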