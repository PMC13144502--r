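test_that("elimination rate matches the closed form and its sign contract", {
  expect_equal(elimination_rate(100, 50, 7), log(2) / 7, tolerance = 1e-12)
  expect_equal(elimination_rate(80, 80, 5), 0)
  expect_lt(elimination_rate(50, 100, 7), 0)
  expect_error(elimination_rate(-1, 50, 7), "initial excess")
  expect_error(elimination_rate(100, 0, 7), "final excess")
  expect_error(elimination_rate(100, 50, 0), "delta_t_days")
})

test_that("dilution space is linear in dose and inverse in plateau excess", {
  n1 <- dilution_space(81, 0.10, 176, "18O")
  expect_equal(dilution_space(162, 0.10, 176, "18O"), 2 * n1, tolerance = 1e-12)
  expect_equal(dilution_space(81, 0.10, 352, "18O"), n1 / 2, tolerance = 1e-12)
  expect_error(dilution_space(81, 0.10, 0, "18O"), "plateau")
  expect_error(dilution_space(81, 1.2, 176, "18O"), "atom_fraction")
})

test_that("rCO2 and the Weir conversion reproduce hand arithmetic", {
  expect_equal(rco2(2500, 0.12, 0.09),
               0.4664 * 2500 * (1.007 * 0.12 - 1.043 * 0.09) * 22.26,
               tolerance = 1e-12)
  expect_equal(rco2(2500, 0.12, 0.09), 700.0107, tolerance = 1e-4)
  expect_equal(rco2(0, 0.12, 0.09), 0)
  expect_equal(rco2(2500, (1.043 / 1.007) * 0.09, 0.09), 0, tolerance = 1e-10)
  expect_equal(tdee_weir(500, 0.85), 500 * (1.106 + 3.94 / 0.85),
               tolerance = 1e-12)
  expect_equal(tdee_weir(500, 0.85), 2870.647, tolerance = 1e-3)
  expect_equal(tdee_weir(100, 1.0), 504.6, tolerance = 1e-10)
  expect_equal(tdee_weir(0), 0)
  expect_error(tdee_weir(100, 0), "rq")
})

test_that("noise-free simulation round-trips through the engine exactly", {
  sim <- noise_free_sim(5, 3)
  dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
  expect_equal(dlw$tdee_kcal_day, sim$truth$tdee_kcal_day, tolerance = 1e-9)
  expect_equal(dlw$tdee_kj_day, dlw$tdee_kcal_day * 4.184, tolerance = 0)
  # known-TBW recovery: engine pool equals the simulated body-water pool
  expect_equal(dlw$n_pool, sim$truth$tbw_kg * 1000 / 18.015, tolerance = 1e-9)
  expect_true(all(dlw$qc_flags == ""))
})

test_that("TDEE is monotone increasing in k_O and decreasing in k_d", {
  base <- tdee_weir(rco2(2500, 0.12, 0.09))
  ks <- seq(0.10, 0.16, by = 0.01)
  expect_true(all(diff(tdee_weir(rco2(2500, ks, 0.09))) > 0))
  expect_true(all(diff(tdee_weir(rco2(2500, 0.12, seq(0.07, 0.11, 0.01)))) < 0))
  expect_gt(tdee_weir(rco2(2500, 0.13, 0.09)), base)
})

test_that("run_dlw raises QC flags and data errors appropriately", {
  sim <- noise_free_sim(2, 12)
  s1 <- sim$isotope$samples[sim$isotope$samples$participant_id == "P01", ]
  d1 <- sim$isotope$doses[sim$isotope$doses$participant_id == "P01", ]

  # inflate the 2H plateau so Nd/No falls below the engine's dose bookkeeping band
  s_bad <- s1
  plat <- s_bad$tracer == "2H" & s_bad$time_h %in% c(4, 5)
  s_bad$excess_ppm[plat] <- s_bad$excess_ppm[plat] * 1.2
  res <- run_dlw(s_bad, d1)
  expect_match(res$qc_flags, "nd_no_outside_band")

  # k_d pushed above the cancellation point turns rCO2 negative, flagged not errored
  s_neg <- s1
  fin <- s_neg$tracer == "2H" & s_neg$time_h == max(s_neg$time_h)
  s_neg$excess_ppm[fin] <- s_neg$excess_ppm[fin] * 0.05
  res2 <- run_dlw(s_neg, d1)
  expect_lt(res2$rco2_l_day, 0)
  expect_match(res2$qc_flags, "negative_rco2")

  expect_error(run_dlw(s1[s1$tracer == "18O", ], d1), "2H")
  expect_error(run_dlw(s1[!(s1$time_h %in% c(4, 5)), ], d1), "plateau")
  expect_error(run_dlw(s1, d1[d1$tracer == "18O", ]), "dose")
})

test_that("a cohort at the default conditions recovers the configured mean TDEE", {
  sim <- simulate_cohort(cohort_params(n = 20, seed = 31, isotope_noise_sd = 0))
  dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
  se <- 480.5 / sqrt(20)
  expect_lt(abs(mean(dlw$tdee_kcal_day) - 3004.2), 3 * se + 30)
})
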