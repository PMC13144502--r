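test_that("percentage difference is the mean of individual ratios", {
  expect_equal(percentage_difference(c(750, 1500), c(1000, 2000))$mean_pct, -25)
  expect_equal(percentage_difference(c(1000, 2000), c(1000, 2000))$mean_pct, 0)
  two <- percentage_difference(c(500, 3000), c(1000, 2000)) # -50% and +50%
  expect_equal(two$mean_pct, 0)
  expect_equal(two$sd_pct, 70.711, tolerance = 1e-3)
  expect_error(percentage_difference(c(1, 2), c(1, 0)), "> 0")
  # mean-of-ratios differs from ratio-of-means when errors track size
  tdee <- c(2000, 4000); tdei <- c(1000, 3900)
  expect_false(isTRUE(all.equal(
    percentage_difference(tdei, tdee)$mean_pct,
    100 * (mean(tdei) - mean(tdee)) / mean(tdee))))
})

test_that("misreporting magnitudes split the diffs into disjoint exhaustive sides", {
  mm <- misreport_magnitudes(c(100, -200, -400), 3000)
  expect_equal(mm$over_mean, 100)
  expect_equal(mm$under_mean, -300)
  expect_equal(mm$n_over + mm$n_under + mm$n_zero, 3)
  allneg <- misreport_magnitudes(c(-100, -50), 2000)
  expect_true(is.na(allneg$over_mean)) # "no overestimation" sentinel
  expect_equal(allneg$under_mean, -75)
  zero <- misreport_magnitudes(c(0, 0), 2000)
  expect_equal(zero$n_zero, 2)
  expect_true(is.na(zero$over_mean) && is.na(zero$under_mean))
})

test_that("the scorecard's facet 1 reuses the agreement result bit-for-bit", {
  sim <- noise_free_sim(5, 3)
  dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
  bundle <- assemble_validation(sim$participants, sim$intake, dlw)
  rep <- build_scorecard(bundle, "app")
  direct <- bland_altman(bundle$analysis$tdei_app,
                         bundle$analysis$tdee_kcal_day)
  expect_identical(rep$agreement$bias, direct$bias)
  expect_identical(rep$agreement$loa, direct$loa)
  expect_identical(rep$agreement$se_loa, direct$se_loa)
  expect_identical(rep$accuracy$mean_diff, direct$bias)
})

test_that("an identity cohort scores perfectly across facets", {
  p <- cohort_params(n = 8, seed = 14, isotope_noise_sd = 0)
  p$tools <- list(app = list(bias_frac = 0, cv_within = 0,
                             cv_between = 0, occasions_mean = 5))
  sim <- simulate_cohort(p)
  dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
  bundle <- assemble_validation(sim$participants, sim$intake, dlw)
  rep <- suppressWarnings(build_scorecard(bundle, "app"))
  expect_equal(rep$agreement$bias, 0, tolerance = 1e-9)
  expect_equal(unname(rep$agreement$loa), c(0, 0), tolerance = 1e-9)
  expect_equal(rep$accuracy$mean_pct, 0, tolerance = 1e-9)
  # every day identical to the participant mean: perfect stability
  expect_equal(rep$stability$icc, 1, tolerance = 1e-9)
  # with tiny S everyone would be plausible; the best Goldberg cell already is
  expect_equal(rep$goldberg$n_plausible + rep$goldberg$n_over +
                 rep$goldberg$n_under, 8)
})

test_that("i.i.d. day-to-day reporting noise drives the stability facet to ~0", {
  p <- cohort_params(n = 60, seed = 25, isotope_noise_sd = 0)
  p$tools <- list(app = list(bias_frac = -0.25, cv_within = 40,
                             cv_between = 0, occasions_mean = 5),
                  recall = list(bias_frac = -0.5, cv_within = 26,
                                cv_between = 25, occasions_mean = 3))
  p$tdee_sd <- 0 # no between-person signal at all for the app tool
  sim <- simulate_cohort(p)
  dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
  bundle <- assemble_validation(sim$participants, sim$intake, dlw)
  rep <- build_scorecard(bundle, "app")
  expect_lt(abs(rep$stability$icc), 0.15)
})

test_that("the long-format rendering round-trips through CSV unchanged", {
  sim <- noise_free_sim(5, 3)
  dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
  bundle <- assemble_validation(sim$participants, sim$intake, dlw)
  rep <- build_scorecard(bundle, "app")
  long <- tibble::as_tibble(rep)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scorecard_csv(rep, path)
  back <- read_scorecard_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(long), tolerance = 1e-12)
})

test_that("missing facet inputs mark facets not-computable without failing", {
  sim <- noise_free_sim(5, 3)
  dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
  parts <- sim$participants
  parts$ffm_kg <- NA_real_
  parts$ree_kcal_day <- NA_real_
  bundle <- assemble_validation(parts, sim$intake, dlw)
  rep <- suppressMessages(build_scorecard(bundle, "app"))
  expect_true(is.na(rep$homoeostasis$signed_r2))
  expect_false(is.na(rep$agreement$bias))
})
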