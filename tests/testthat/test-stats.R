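# cohort statistics: pooled t-test, Pearson correlation, filters, stars

test_that("pooled t-test matches the closed form on random fixtures", {
  set.seed(21)
  for (i in 1:50) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    got <- unpaired_ttest(a, b)
    want <- oracle_pooled_t(a, b)
    expect_equal(got$t_statistic, want$t, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    expect_equal(c(got$ci_low, got$ci_high), want$ci, tolerance = 1e-10)
  }
})

test_that("the textbook shifted-groups example reproduces hand values", {
  got <- unpaired_ttest(c(1, 2, 3), c(11, 12, 13))
  expect_equal(got$t_statistic, -12.24744871391589, tolerance = 1e-10)
  expect_equal(got$p_value, 2.552167494419268e-04, tolerance = 1e-10)
  expect_equal(got$ci_low, -12.266957935527518, tolerance = 1e-9)
  expect_equal(got$ci_high, -7.733042064472481, tolerance = 1e-9)
  expect_identical(got$stars, "***")
  # antisymmetry
  rev <- unpaired_ttest(c(11, 12, 13), c(1, 2, 3))
  expect_equal(rev$t_statistic, -got$t_statistic)
  expect_equal(rev$p_value, got$p_value)
})

test_that("degenerate zero-variance groups follow the stated conventions", {
  same <- unpaired_ttest(rep(2, 5), rep(2, 4))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$ci_low <= 0 && same$ci_high >= 0)
  diff <- unpaired_ttest(rep(2, 5), rep(3, 4))
  expect_equal(diff$p_value, 0)
  expect_true(diff$degenerate)
})

test_that("significance stars partition the printed open bins", {
  expect_identical(
    p_stars(c(5e-4, 0.001, 0.005, 0.01, 0.03, 0.05, 0.2)),
    c("***", "**", "**", "*", "*", "ns", "ns"))
})

test_that("Pearson correlation is exact on constructed cases", {
  x <- c(1.5, 2, 4, 4.5, 7, 9)
  perfect <- pearson_correlation(x, 2 * x + 1)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  # orthogonalized covariate gives r = 0
  y <- rnorm(20)
  x2 <- rnorm(20)
  y_orth <- y - mean(y) - (x2 - mean(x2)) *
    sum((y - mean(y)) * (x2 - mean(x2))) / sum((x2 - mean(x2))^2)
  expect_equal(pearson_correlation(x2, y_orth)$r, 0, tolerance = 1e-12)
})

test_that("Pearson r and p match the closed form, symmetrically", {
  set.seed(31)
  for (i in 1:30) {
    x <- rnorm(sample(4:25, 1)); y <- rnorm(length(x)) + 0.5 * x
    got <- pearson_correlation(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    sym <- pearson_correlation(y, x)
    expect_equal(sym$p_value, got$p_value, tolerance = 1e-12)
    neg <- pearson_correlation(x, -y)
    expect_equal(neg$r, -got$r, tolerance = 1e-12)
  }
})

test_that("zero-variance inputs are flagged undefined", {
  out <- pearson_correlation(rep(1, 5), rnorm(5))
  expect_true(out$undefined)
  expect_true(is.na(out$r))
  expect_error(pearson_correlation(1:2, 2:3), class = "thzcoag_input_error")
})

test_that("hematology filter applies half-open RBC and closed PLT bounds", {
  recs <- tibble::tibble(
    subject_id = sprintf("r%02d", 1:10),
    rbc = c(4.0, 4.01, 4.5, 5.0, 5.01, 3.9, 4.2, 4.8, 4.6, 4.4),
    plt = c(200, 99, 100, 300, 200, 150, 301, 250, 300.5, 120))
  kept <- filter_subjects(recs)
  # hand enumeration: rbc must be in (4, 5], plt in [100, 300]
  expect_identical(kept$subject_id, c("r03", "r04", "r08", "r10"))
  expect_false("r01" %in% kept$subject_id) # rbc exactly 4 excluded
  expect_true(all(c("r03", "r04") %in% kept$subject_id)) # boundaries kept
  expect_identical(nrow(filter_subjects(recs, rbc_range = c(9, 10))), 0L)
  expect_error(filter_subjects(recs, rbc_range = c(5, 4)),
               class = "thzcoag_input_error")
})

test_that("minute averaging of spectra is the plain per-frequency mean", {
  f <- seq(0.2, 1, by = 0.1)
  one <- tibble::tibble(freq_THz = f, alpha_cm1 = f * 100)
  expect_equal(minute_average_alpha(one)$alpha_cm1, one$alpha_cm1)
  two <- dplyr::bind_rows(one, dplyr::mutate(one, alpha_cm1 = 3 * alpha_cm1))
  expect_equal(minute_average_alpha(two)$alpha_cm1, 2 * one$alpha_cm1)
  # brute-force oracle across 120 random spectra
  set.seed(41)
  m <- matrix(rnorm(120 * length(f), 100, 5), nrow = length(f))
  long <- tibble::tibble(freq_THz = rep(f, 120), alpha_cm1 = as.vector(m))
  expect_equal(minute_average_alpha(long)$alpha_cm1, rowMeans(m),
               tolerance = 1e-12)
  expect_error(minute_average_alpha(one[0, ]), class = "thzcoag_input_error")
})
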