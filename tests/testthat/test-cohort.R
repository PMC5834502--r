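# synthetic cohort generator

test_that("the same seed reproduces traces and metadata bit for bit", {
  cfg <- cohort_config(groups = c(uncoagulated = 2L, early_coagulated = 2L),
                       instrument = instrument_model(traces_per_minute = 5L))
  a <- suppressMessages(simulate_cohort(cfg, seed = 3))
  b <- suppressMessages(simulate_cohort(cfg, seed = 3))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$traces$field, b$traces$field)
  c <- suppressMessages(simulate_cohort(cfg, seed = 4))
  expect_false(identical(a$subjects$rbc, c$subjects$rbc))
})

test_that("study-sized configuration yields 57 subject records", {
  cfg <- cohort_config(groups = c(early_coagulated = 29L, uncoagulated = 28L),
                       instrument = instrument_model(traces_per_minute = 1L))
  co <- suppressMessages(simulate_cohort(cfg, seed = 1))
  expect_identical(nrow(co$subjects), 57L)
  expect_identical(sum(co$subjects$group == "early_coagulated"), 29L)
})

test_that("covariates and clotting times respect their stated ranges", {
  cfg <- cohort_config(groups = c(uncoagulated = 10L, thrombus = 10L),
                       instrument = instrument_model(traces_per_minute = 2L))
  co <- suppressMessages(simulate_cohort(cfg, seed = 5))
  s <- co$subjects
  expect_true(all(s$rbc > 0 & s$wbc > 0 & s$plt > 0))
  expect_true(all(s$plt >= 100 & s$plt <= 400))
  expect_true(all(is.na(s$clotting_time[s$group == "uncoagulated"])))
  ct <- s$clotting_time[s$group == "thrombus"]
  expect_true(all(ct >= 8 & ct <= 21))
})

test_that("misconfigured generators fail loudly", {
  expect_error(cohort_config(groups = c(uncoagulated = 2L, thrombus = 0L)),
               regexp = "thrombus", class = "thzcoag_config_error")
  expect_error(instrument_model(time_step = 0.5, source_band = c(0.1, 3)),
               class = "thzcoag_config_error") # Nyquist 1 THz < 3 THz
  expect_error(cohort_config(groups = c(2L, 2L)),
               class = "thzcoag_config_error")
})

test_that("trace averaging is exact on constants and antisymmetric pairs", {
  t <- seq(0, 5, by = 0.05)
  x <- exp(-(t - 2)^2)
  many <- tibble::tibble(
    time_ps = rep(t, 120), field = rep(x, 120),
    acquisition = rep(1:120, each = length(t)), arm = "sample")
  avg <- average_traces(many)
  expect_equal(avg$field, x)
  expect_identical(attr(avg, "n_traces"), 120L)
  expect_true(all(is.na(avg$acquisition)))
  pair <- tibble::tibble(time_ps = rep(t, 2), field = c(x, -x),
                         acquisition = rep(1:2, each = length(t)))
  expect_equal(average_traces(pair)$field, rep(0, length(t)))
})

test_that("averaging 120 noisy traces shrinks the noise about root-120-fold", {
  set.seed(99)
  t <- seq(0, 5, by = 0.05)
  clean <- exp(-(t - 2)^2)
  sd1 <- 0.05
  noisy <- tibble::tibble(
    time_ps = rep(t, 120),
    field = rep(clean, 120) + rnorm(120 * length(t), sd = sd1),
    acquisition = rep(1:120, each = length(t)))
  avg <- average_traces(noisy)
  rms <- sqrt(mean((avg$field - clean)^2))
  expect_lt(abs(rms / (sd1 / sqrt(120)) - 1), 0.15)
})

test_that("mixed arms or mismatched grids cannot be averaged", {
  t <- seq(0, 1, by = 0.1)
  bad_arm <- tibble::tibble(time_ps = rep(t, 2), field = rnorm(2 * length(t)),
                            acquisition = rep(1:2, each = length(t)),
                            arm = rep(c("sample", "reference"), each = length(t)))
  expect_error(average_traces(bad_arm), class = "thzcoag_input_error")
  bad_grid <- tibble::tibble(time_ps = c(t, t + 0.01),
                             field = rnorm(2 * length(t)),
                             acquisition = rep(1:2, each = length(t)))
  expect_error(average_traces(bad_grid), class = "thzcoag_input_error")
})

test_that("cohort files round-trip through the disk dialect", {
  cfg <- cohort_config(groups = c(uncoagulated = 2L),
                       instrument = instrument_model(traces_per_minute = 2L))
  co <- simulate_cohort(cfg, seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, traces = TRUE)
  meta <- read_cohort_metadata(file.path(dir, "metadata.csv"))
  expect_equal(meta$subject_id, co$subjects$subject_id)
  expect_equal(meta$rbc, co$subjects$rbc)
  tr <- read_trace(file.path(dir, "traces", "S001_sample_001.csv"))
  expect_equal(tr$field, co$traces$field[[
    which(co$traces$subject_id == "S001" & co$traces$arm == "sample")]][, 1])
  side <- jsonlite::read_json(file.path(dir, "instrument.json"))
  expect_equal(side$seed, 8)
  expect_equal(side$instrument$traces_per_minute, 2L)
})
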