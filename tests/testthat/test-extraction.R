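# spectral inversion: initial estimate and Fresnel-corrected iteration

test_that("an identity ratio gives the free-space constants", {
  f <- seq(0.15, 1.0, by = 0.05)
  spec <- tibble::tibble(freq_THz = f, amplitude = complex(real = rep(1, length(f))))
  oc <- initial_estimate(spec, spec)
  expect_equal(oc$kappa, rep(0, length(f)), tolerance = 1e-12)
  expect_equal(oc$n, rep(1, length(f)), tolerance = 1e-12)
})

test_that("the initial estimate reduces to unit kappa when omega*d/c = 1", {
  # at f = c/(2*pi*d) = 0.4771345 THz (d = 100 um), |R| = e^-1 maps to
  # kappa0 = 1 and a phase of +1 rad maps to n0 = 2
  f <- c(0.3, 0.47713451592369, 0.7)
  phi <- 2 * pi * f * 100 / 299.792458
  ref <- tibble::tibble(freq_THz = f, amplitude = complex(real = rep(1, 3)))
  sam <- tibble::tibble(freq_THz = f,
                        amplitude = exp(-phi) * exp(1i * phi))
  oc <- initial_estimate(sam, ref)
  expect_equal(oc$kappa[2], 1, tolerance = 1e-9)
  expect_equal(oc$n[2], 2, tolerance = 1e-9)
})

test_that("a known homogeneous liquid is recovered through the iteration", {
  f <- seq(0.14, 1.0, by = 0.01)
  sp <- analytic_spectra(f, n = 2.3, kappa = 0.5)
  approx <- initial_estimate(sp$sample, sp$reference)
  expect_lt(max(abs(approx$n / 2.3 - 1)), 0.10)   # interfaces not yet removed
  expect_lt(max(abs(approx$kappa / 0.5 - 1)), 0.10)
  oc <- refine_index(sp$sample, sp$reference)
  expect_true(all(oc$converged))
  expect_true(all(oc$iterations <= 100))
  expect_lt(max(abs(oc$n - 2.3)), 0.001)
  expect_lt(max(abs(oc$kappa - 0.5)), 0.001)
})

test_that("an air-filled chamber converges to unity almost immediately", {
  f <- seq(0.14, 1.0, by = 0.02)
  sp <- analytic_spectra(f, n = 1, kappa = 0)
  oc <- refine_index(sp$sample, sp$reference)
  expect_true(all(oc$converged))
  expect_true(all(oc$iterations <= 2))
  expect_equal(oc$n, rep(1, length(f)), tolerance = 1e-9)
  expect_equal(oc$kappa, rep(0, length(f)), tolerance = 1e-9)
  expect_equal(oc$alpha_cm1, rep(0, length(f)), tolerance = 1e-6)
})

test_that("noiseless synthesis round-trips frequency-dependent water", {
  co <- simulate_cohort(water_config(), seed = 7)
  tr <- subject_avg_traces(co, "S001")
  oc <- refine_index(to_spectrum(tr$sample), to_spectrum(tr$reference),
                     co$config$geometry)
  truth <- complex_index(oc$freq_THz)
  band <- oc$freq_THz >= 0.2 & oc$freq_THz <= 1.0
  expect_lt(max(abs(oc$n - truth$n)[band]), 0.005)
  expect_lt(max(abs(oc$kappa - truth$kappa)[band]), 0.005)
  expect_lt(max(abs(oc$alpha_cm1 / truth$alpha_cm1 - 1)[band]), 0.01)
  expect_true(all(oc$converged))
  # the contraction also reaches a much tighter tolerance within the cap
  tight <- refine_index(to_spectrum(tr$sample), to_spectrum(tr$reference),
                        co$config$geometry,
                        extraction_settings(tolerance = 1e-6))
  expect_true(all(tight$converged))
})

test_that("re-synthesized ratios reproduce the measurement (residual test)", {
  co <- simulate_cohort(water_config(), seed = 9)
  tr <- subject_avg_traces(co, "S001")
  oc <- refine_index(to_spectrum(tr$sample), to_spectrum(tr$reference),
                     co$config$geometry)
  res <- resynthesize_ratio(oc)
  conv <- oc$converged
  expect_lt(max(abs(res$residual_mod[conv] / Mod(res$measured_ratio[conv]))),
            5e-3)
  expect_lt(max(abs(res$residual_phase[conv])), 5e-3)
})

test_that("extraction flags bins that cannot converge within the cap", {
  f <- seq(0.14, 1.0, by = 0.02)
  sp <- analytic_spectra(f, n = 2.3, kappa = 0.5)
  expect_warning(
    oc <- refine_index(sp$sample, sp$reference,
                       settings = extraction_settings(max_iterations = 1L)),
    regexp = "unconverged")
  expect_true(any(!oc$converged))
  expect_true(all(is.finite(oc$n)))
})

test_that("absorption constant conversion is exact and linear", {
  expect_equal(absorption_constant(0, 0.5), 0)
  # frozen: 2 * 2*pi*0.3e12 / c, in cm^-1
  expect_equal(absorption_constant(1, 0.3), 125.7507013171009,
               tolerance = 1e-12)
  k <- runif(20, 0, 2); f <- runif(20, 0.1, 3)
  expect_equal(absorption_constant(2 * k, f), 2 * absorption_constant(k, f),
               tolerance = 1e-12)
})

test_that("cohort-level extraction matches the single-subject path", {
  cfg <- water_config(groups = c(uncoagulated = 2L))
  co <- simulate_cohort(cfg, seed = 12)
  al <- extract_cohort(co)
  tr <- subject_avg_traces(co, "S002")
  oc <- refine_index(to_spectrum(tr$sample), to_spectrum(tr$reference),
                     co$config$geometry)
  expect_equal(al$alpha_cm1[al$subject_id == "S002"], oc$alpha_cm1)
})
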