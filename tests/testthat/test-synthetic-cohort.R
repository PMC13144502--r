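test_that("cohort generation is deterministic and respects degenerate variance", {
  p <- cohort_params(n = 6, seed = 99)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$participants, b$participants)
  expect_identical(a$isotope$samples, b$isotope$samples)
  expect_identical(a$intake, b$intake)

  p0 <- cohort_params(n = 2, seed = 5,
                      weight_sd = 0, height_sd = 0, age_sd = 0, tdee_sd = 0,
                      body_fat_frac_sd = 0, pal_lifestyle_sd = 0, ree_cv = 0)
  g <- generate_participants(p0)
  expect_equal(g$participants$weight_day1_kg, rep(108.4, 2))
  expect_equal(g$participants$height_m, rep(1.66, 2))
  expect_equal(g$participants$age_years, rep(37.9, 2))
  expect_equal(g$truth$tdee_kcal_day, rep(3004.2, 2))
})

test_that("anthropometric and TDEE moments are recovered at large n", {
  p <- cohort_params(n = 400, seed = 21)
  g <- generate_participants(p)
  w <- g$participants$weight_day1_kg
  # truncation at 2 SD below the mean shifts moments by < 1 SE at this n
  expect_lt(abs(mean(w) - 108.4), 3 * 16.3 / sqrt(400) + 0.5)
  expect_lt(abs(sd(w) - 16.3), 3)
  expect_lt(abs(mean(g$truth$tdee_kcal_day) - 3004.2),
            3 * 480.5 / sqrt(400) + 15)
  # body-composition bookkeeping
  expect_equal(g$truth$fm_kg + g$truth$ffm_kg, w, tolerance = 1e-12)
  expect_true(all(g$truth$tbw_kg < w))
  expect_equal(g$truth$tbw_kg, 0.732 * g$truth$ffm_kg, tolerance = 1e-12)
})

test_that("reported intake reproduces the configured bias and collapses at zero noise", {
  p0 <- cohort_params(n = 3, seed = 8)
  p0$tools <- list(app = list(bias_frac = -0.25, cv_within = 0,
                              cv_between = 0, occasions_mean = 5))
  g <- generate_participants(p0)
  intake <- simulate_reported_intake(g$truth, p0)
  joined <- merge(intake, g$truth, by.x = "participant_id", by.y = "id")
  expect_equal(joined$kcal, 0.75 * joined$tdee_kcal_day, tolerance = 1e-12)

  # law of large numbers: cohort-mean relative bias within Monte-Carlo error
  p <- cohort_params(n = 200, seed = 13)
  p$tools$app$cv_within <- 30; p$tools$app$cv_between <- 0
  g <- generate_participants(p)
  intake <- simulate_reported_intake(g$truth, p)
  app <- intake[intake$tool == "app", ]
  per <- tapply(app$kcal, app$participant_id, mean)
  rel <- per[g$truth$id] / g$truth$tdee_kcal_day - 1
  se <- sd(rel) / sqrt(length(rel))
  expect_lt(abs(mean(rel) - (-0.25)), 3 * se)
})

test_that("intake noise is right-skewed and macronutrients follow the energy split", {
  p <- cohort_params(n = 150, seed = 4)
  g <- generate_participants(p)
  intake <- simulate_reported_intake(g$truth, p)
  app <- intake[intake$tool == "app", ]
  expect_true(all(app$kcal >= 0))
  expect_gt(mean(((app$kcal - mean(app$kcal)) / sd(app$kcal))^3), 0.5)
  expect_equal(app$carb_g, app$kcal * 0.45 / 4, tolerance = 1e-12)
  expect_equal(app$fat_g, app$kcal * 0.35 / 9, tolerance = 1e-12)
})

test_that("parameter validation rejects bad cohort settings", {
  expect_error(cohort_params(n = 1), "n")
  expect_error(cohort_params(weight_sd = -1), "standard deviations")
  expect_error(cohort_params(rq = 1.2), "rq")
  expect_error(cohort_params(n_days = 0), "n_days")
  p <- cohort_params(n = 3)
  g <- generate_participants(p)
  expect_error(
    simulate_isotope_series(g$truth, p, sample_times_h = c(0, 4, 5, 4.5)),
    "final sample")
})

test_that("simulated dilution-space ratios sit in the physiologic band", {
  sim <- simulate_cohort(cohort_params(n = 50, seed = 17, isotope_noise_sd = 0))
  dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
  expect_lt(abs(mean(dlw$ratio_nd_no) - 1.0398), 3 * 0.0067 / sqrt(50) + 0.003)
  expect_true(all(dlw$ratio_nd_no > 1.00 & dlw$ratio_nd_no < 1.07))
})
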