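test_that("the variability factor S composes its components as stated", {
  expect_equal(s_factor(0, 0, 0, 7), 0)
  bd <- black_defaults()
  expect_equal(s_factor(bd[["cv_w_tdei"]], bd[["cv_w_b"]], bd[["cv_t_p"]], 7),
               sqrt(26^2 / 7 + 8.5^2 + 14.9^2), tolerance = 1e-12)
  expect_equal(s_factor(26, 8.5, 14.9, 7), 19.769, tolerance = 1e-3)
  expect_error(s_factor(26, 8.5, 14.9, 0), "d")
  expect_error(s_factor(-1, 8.5, 14.9, 7), "CV")
})

test_that("Goldberg bounds are log-symmetric, collapse at s = 0 and tighten with n", {
  b <- goldberg_bounds(2.081, 40.01, 19)
  expect_equal(unname(b[1] * b[2]), 2.081^2, tolerance = 1e-10) # log symmetry
  expect_equal(unname(b), c(1.738, 2.491), tolerance = 1e-3)
  expect_equal(unname(goldberg_bounds(1.55, 0, 20)), c(1.55, 1.55))
  wide <- goldberg_bounds(1.55, 30, 10)
  tight <- goldberg_bounds(1.55, 30, 1e8)
  expect_lt(tight[["upper"]] - tight[["lower"]], 1e-3)
  expect_gt(wide[["upper"]] - wide[["lower"]], tight[["upper"]] - tight[["lower"]])
})

test_that("classification respects bounds, tie rule and missing data", {
  b <- c(lower = 1.74, upper = 2.49)
  expect_equal(classify_goldberg(1.0, b), "under")
  expect_equal(classify_goldberg(3.0, b), "over")
  expect_equal(classify_goldberg(2.0, b), "plausible")
  expect_equal(classify_goldberg(1.74, b), "plausible") # tie at a bound
  expect_equal(classify_goldberg(2.49, b), "plausible")
  expect_equal(classify_goldberg(NA_real_, b), "unclassifiable")
})

test_that("enlarging S never moves a participant out of plausible", {
  set.seed(41)
  ratios <- runif(50, 0.8, 3.2)
  pal_ref <- 2.0
  labels_at <- function(s) classify_goldberg(ratios, goldberg_bounds(pal_ref, s, 20))
  for (pair in list(c(5, 15), c(15, 30), c(30, 60))) {
    small <- labels_at(pair[1]); big <- labels_at(pair[2])
    expect_true(all(big[small == "plausible"] == "plausible"))
  }
})

test_that("labels are scale-equivariant in intake and denominator", {
  sim <- noise_free_sim(5, 3)
  dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
  b <- assemble_validation(sim$participants, sim$intake, dlw)
  g1 <- classification_grid(b$analysis, b$intake_daily)

  scaled <- b
  for (col in grep("^tdei_", names(scaled$analysis), value = TRUE)) {
    scaled$analysis[[col]] <- scaled$analysis[[col]] * 3
  }
  scaled$analysis$abmr <- scaled$analysis$abmr * 3
  scaled$analysis$ree_kcal_day <- scaled$analysis$ree_kcal_day * 3
  scaled$intake_daily$kcal <- scaled$intake_daily$kcal * 3
  g2 <- classification_grid(scaled$analysis, scaled$intake_daily)
  counts <- c("n_under", "n_plausible", "n_over")
  expect_equal(g1[counts], g2[counts])
})

test_that("grid counts partition the cohort and extreme constructions classify as built", {
  # strong underreporting with tight CVs: everyone under in every cell
  p <- cohort_params(n = 12, seed = 19, isotope_noise_sd = 0)
  p$tools <- list(recall = list(bias_frac = -0.5, cv_within = 3,
                                cv_between = 3, occasions_mean = 3))
  sim <- simulate_cohort(p)
  dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
  b <- assemble_validation(sim$participants, sim$intake, dlw)
  grid <- classification_grid(b$analysis, b$intake_daily, n_days = p$n_days)
  expect_true(all(grid$n_under + grid$n_plausible + grid$n_over +
                    grid$n_unclassifiable == 12))
  under_cells <- grid[grid$denominator == "abmr" & grid$pal_variant == "pal_abmr", ]
  expect_true(all(under_cells$n_under == 12))

  # zero bias, tiny noise, homogeneous cohort (narrow PAL spread): majority
  # plausible against the matched denominator
  p2 <- cohort_params(n = 12, seed = 23, isotope_noise_sd = 0,
                      weight_sd = 2, height_sd = 0.01, age_sd = 2,
                      tdee_sd = 60, body_fat_frac_sd = 0.01, ree_cv = 2)
  p2$tools <- list(app = list(bias_frac = 0, cv_within = 3,
                              cv_between = 3, occasions_mean = 5))
  sim2 <- simulate_cohort(p2)
  dlw2 <- run_dlw_cohort(sim2$isotope$samples, sim2$isotope$doses)
  b2 <- assemble_validation(sim2$participants, sim2$intake, dlw2)
  g2 <- classification_grid(b2$analysis, b2$intake_daily, n_days = p2$n_days)
  cell <- g2[g2$denominator == "abmr" & g2$pal_variant == "pal_abmr" &
               g2$s_mode == "black", ]
  expect_gt(cell$n_plausible, 6)

  # single participant: no crash, single-count cells
  b1 <- assemble_validation(sim$participants[1, ],
                            sim$intake[sim$intake$participant_id == "P01", ],
                            dlw[1, ])
  g1 <- classification_grid(b1$analysis, b1$intake_daily)
  expect_true(all(g1$n_under + g1$n_plausible + g1$n_over +
                    g1$n_unclassifiable == 1))
})
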