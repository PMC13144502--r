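#' Generate the participant table and ground truth of a synthetic cohort
#'
#' Draws anthropometrics from truncated normals at the configured moments
#' (truncated at 2 SD below the mean and at physiologic bounds, never above),
#' splits weight into fat and fat-free mass, derives total body water from
#' fat-free mass via the hydration constant, and draws each participant's true
#' TDEE and true tool-specific mean reported intake
#' (`TDEE * (1 + bias_frac)`).
#'
#' @param params A [cohort_params()] object.
#' @return A list with two tibbles: `participants` (one row per participant:
#'   id, sex, age, height, day-1/day-8 weights, FM, FFM, device REE,
#'   lifestyle PAL) and `truth` (the generating ground truth: true TDEE, TBW,
#'   and per-tool true mean intake — used only by recovery tests and
#'   downstream simulators, never by the analysis).
#' @examples
#' cohort <- generate_participants(cohort_params(n = 4, seed = 7))
#' cohort$participants
#' @export
generate_participants <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n

  weight <- rtrunc_norm(n, params$weight_mean, params$weight_sd,
                        lower = max(params$weight_mean - 2 * params$weight_sd, 35))
  height <- rtrunc_norm(n, params$height_mean, params$height_sd,
                        lower = max(params$height_mean - 2 * params$height_sd, 1.3))
  age <- rtrunc_norm(n, params$age_mean, params$age_sd,
                     lower = max(params$age_mean - 2 * params$age_sd, 18))
  fat_frac <- rtrunc_norm(n, params$body_fat_frac_mean, params$body_fat_frac_sd,
                          lower = 0.15, upper = 0.60)
  fm <- fat_frac * weight
  ffm <- weight - fm
  tbw <- params$hydration * ffm
  tdee <- rtrunc_norm(n, params$tdee_mean, params$tdee_sd,
                      lower = max(params$tdee_mean - 2 * params$tdee_sd, 800))

  # weight-stable protocol: day-8 weight wobbles around day 1
  weight_day8 <- weight + if (params$weight_sd == 0) 0 else rnorm(n, 0, 0.8)

  # device REE: anthropometric prediction on actual weight plus device noise
  ree <- bmr_mifflin_female(weight, 100 * height, age) * rlnorm_cv(n, params$ree_cv)
  pal_life <- rtrunc_norm(n, params$pal_lifestyle_mean, params$pal_lifestyle_sd,
                          lower = 1.1, upper = 2.5)

  ids <- sprintf("P%02d", seq_len(n))
  participants <- tibble(
    id = ids, sex = "female",
    age_years = age, height_m = height,
    weight_day1_kg = weight, weight_day8_kg = weight_day8,
    fm_kg = fm, ffm_kg = ffm,
    ree_kcal_day = ree, pal_lifestyle = pal_life
  )
  true_intake <- lapply(params$tools, function(t) tdee * (1 + t$bias_frac))
  truth <- tibble(
    id = ids, tdee_kcal_day = tdee, tbw_kg = tbw,
    fm_kg = fm, ffm_kg = ffm
  )
  for (nm in names(true_intake)) {
    truth[[paste0("true_intake_", nm)]] <- true_intake[[nm]]
  }
  list(participants = participants, truth = truth)
}

#' Default DLW dosing scheme
#'
#' Per-participant dose masses scale with total body water: 1.8 g/kg TBW of
#' 10 atom% \eqn{^{18}}O water and 0.12 g/kg TBW of 99.9 atom% \eqn{^{2}}H
#' water.
#'
#' @param o18_g_per_kg_tbw,h2_g_per_kg_tbw Dose masses, g per kg TBW.
#' @param o18_atom_fraction,h2_atom_fraction Heavy-isotope atom fractions of
#'   the dose waters, in `(0, 1]`.
#' @return A list of class `dose_scheme`.
#' @export
dose_scheme <- function(o18_g_per_kg_tbw = 1.8, h2_g_per_kg_tbw = 0.12,
                        o18_atom_fraction = 0.10, h2_atom_fraction = 0.999) {
  stopifnot(o18_g_per_kg_tbw > 0, h2_g_per_kg_tbw > 0,
            o18_atom_fraction > 0, o18_atom_fraction <= 1,
            h2_atom_fraction > 0, h2_atom_fraction <= 1)
  structure(list(o18_g_per_kg_tbw = o18_g_per_kg_tbw,
                 h2_g_per_kg_tbw = h2_g_per_kg_tbw,
                 o18_atom_fraction = o18_atom_fraction,
                 h2_atom_fraction = h2_atom_fraction),
            class = "dose_scheme")
}

#' Simulate a two-point DLW urine sampling series
#'
#' For each participant, elimination rates for the two tracers are chosen by
#' inverting the CO2-production equation so that the DLW engine recovers the
#' participant's true TDEE exactly in the noise-free case: the dilution-space
#' ratio N_d/N_o and the rate ratio k_O/k_d are drawn from their configured
#' physiologic distributions, the body-water pool in moles is fixed by the
#' true TBW, and k_d then follows from the target CO2 production. Post-dose
#' plateau samples (default 4 h and 5 h) are laid on the elimination curve so
#' that their arithmetic mean equals the exact plateau enrichment, and the
#' final sample decays from the plateau midpoint. Gaussian measurement noise
#' (`params$isotope_noise_sd`, ppm) is added to every post-dose excess.
#'
#' @param truth Ground-truth tibble from [generate_participants()].
#' @param params A [cohort_params()] object.
#' @param dose A [dose_scheme()].
#' @param sample_times_h Sampling times in hours since dose. Must contain a
#'   pre-dose time (0), at least one plateau time, and a final time well after
#'   the plateau.
#' @param plateau_times_h The post-dose plateau times.
#' @return A list with `samples` (tibble: participant_id, time_h, tracer,
#'   excess_ppm) and `doses` (tibble: participant_id, tracer, dose_g,
#'   atom_fraction).
#' @export
simulate_isotope_series <- function(truth, params,
                                    dose = dose_scheme(),
                                    sample_times_h = c(0, 4, 5, 168),
                                    plateau_times_h = c(4, 5)) {
  stopifnot(inherits(params, "cohort_params"), inherits(dose, "dose_scheme"))
  final_h <- max(sample_times_h)
  if (final_h <= max(plateau_times_h)) {
    abort("final sample time must exceed the plateau times")
  }
  set.seed(params$seed + 1L)
  n <- nrow(truth)

  nd_no <- rtrunc_norm(n, params$nd_no_mean, params$nd_no_sd, lower = 1.0)
  ko_kd <- rtrunc_norm(n, params$ko_kd_mean, params$ko_kd_sd, lower = 1.1)

  rco2_l <- truth$tdee_kcal_day / weir_factor(params$rq)
  n_pool <- truth$tbw_kg * 1000 / MW_WATER          # mol body water
  # invert the engine's pool convention: N = (N_o + N_d / ref) / 2
  n_o <- 2 * n_pool / (1 + nd_no / ND_NO_REF_DEFAULT)
  n_d <- nd_no * n_o
  # rCO2 = 0.4664 * N * (1.007 k_O - 1.043 k_d) * 22.26, with k_O = r * k_d
  k_d <- rco2_l / (RCO2_COEF * n_pool * MOLAR_VOLUME_CO2 *
                     (1.007 * ko_kd - 1.043))
  k_o <- ko_kd * k_d

  dose_o_g <- dose$o18_g_per_kg_tbw * truth$tbw_kg
  dose_h_g <- dose$h2_g_per_kg_tbw * truth$tbw_kg
  plateau_o <- dose_excess_mol(dose_o_g, dose$o18_atom_fraction, "18O") / n_o * 1e6
  plateau_d <- dose_excess_mol(dose_h_g, dose$h2_atom_fraction, "2H") / n_d * 1e6

  mid_h <- mean(plateau_times_h)
  one_tracer <- function(id, plateau, k, tracer) {
    # plateau samples on the decay curve, rescaled so their mean is exact
    rel <- exp(-k * (plateau_times_h - mid_h) / 24)
    plat <- plateau * rel / mean(rel)
    fin <- plateau * exp(-k * (final_h - mid_h) / 24)
    other <- setdiff(sample_times_h, c(plateau_times_h, final_h))
    tibble(
      participant_id = id,
      time_h = c(other, plateau_times_h, final_h),
      tracer = tracer,
      excess_ppm = c(ifelse(other == 0, 0,
                            plateau * exp(-k * (other - mid_h) / 24)),
                     plat, fin)
    )
  }
  samples <- purrr::map_dfr(seq_len(n), function(i) {
    dplyr::bind_rows(
      one_tracer(truth$id[i], plateau_o[i], k_o[i], "18O"),
      one_tracer(truth$id[i], plateau_d[i], k_d[i], "2H")
    )
  })
  if (params$isotope_noise_sd > 0) {
    post <- samples$time_h > 0
    samples$excess_ppm[post] <- samples$excess_ppm[post] +
      rnorm(sum(post), 0, params$isotope_noise_sd)
  }
  doses <- tibble(
    participant_id = rep(truth$id, each = 2L),
    tracer = rep(c("18O", "2H"), n),
    dose_g = as.vector(rbind(dose_o_g, dose_h_g)),
    atom_fraction = rep(c(dose$o18_atom_fraction, dose$h2_atom_fraction), n)
  )
  list(samples = samples, doses = doses)
}

#' Simulate daily reported intake for each tool
#'
#' Day-level reported energy is
#' `TDEE * (1 + bias_frac) * B_i * W_id`, with `B_i` a between-person and
#' `W_id` a within-person lognormal factor of mean 1 at the configured
#' coefficients of variation — multiplicative noise keeps intake positive and
#' produces the right-skew typical of app-reported intake. Eating occasions
#' are Poisson with a tool-specific mean; macronutrient grams follow a fixed
#' energy split (4/9/4 kcal per g of carbohydrate/fat/protein).
#'
#' @param truth Ground-truth tibble from [generate_participants()].
#' @param params A [cohort_params()] object.
#' @return Tibble: participant_id, tool, day, kcal, carb_g, sugar_g, fat_g,
#'   satfat_g, protein_g, fibre_g, occasions.
#' @export
simulate_reported_intake <- function(truth, params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed + 2L)
  n <- nrow(truth)
  d <- params$n_days
  fr <- params$macro_fracs
  out <- purrr::map_dfr(names(params$tools), function(nm) {
    t <- params$tools[[nm]]
    between <- rlnorm_cv(n, t$cv_between)
    base <- truth$tdee_kcal_day * (1 + t$bias_frac) * between
    purrr::map_dfr(seq_len(n), function(i) {
      kcal <- pmax(base[i] * rlnorm_cv(d, t$cv_within), 0)
      tibble(
        participant_id = truth$id[i], tool = nm, day = seq_len(d),
        kcal = kcal,
        carb_g = kcal * fr[["carb"]] / 4,
        sugar_g = kcal * fr[["carb"]] / 4 * 0.40,
        fat_g = kcal * fr[["fat"]] / 9,
        satfat_g = kcal * fr[["fat"]] / 9 * 0.40,
        protein_g = kcal * fr[["protein"]] / 4,
        fibre_g = kcal / 1000 * 10,
        occasions = rpois(d, t$occasions_mean)
      )
    })
  })
  out
}

#' Simulate a complete synthetic validation cohort
#'
#' Runs [generate_participants()], [simulate_isotope_series()] and
#' [simulate_reported_intake()] under the parameter set's seed. The result is
#' bit-identical across calls with the same parameters.
#'
#' @inheritParams generate_participants
#' @param dose A [dose_scheme()].
#' @return A list of class `cohort_sim`: `params`, `participants`, `truth`,
#'   `isotope` (samples + doses) and `intake`.
#' @examples
#' sim <- simulate_cohort(cohort_params(n = 3, seed = 11))
#' names(sim)
#' @export
simulate_cohort <- function(params = cohort_params(), dose = dose_scheme()) {
  cohort <- generate_participants(params)
  isotope <- simulate_isotope_series(cohort$truth, params, dose = dose)
  intake <- simulate_reported_intake(cohort$truth, params)
  structure(list(params = params,
                 participants = cohort$participants,
                 truth = cohort$truth,
                 isotope = isotope,
                 intake = intake),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim> n =", x$params$n, " seed =", x$params$seed,
      " days =", x$params$n_days, "\n")
  cat("  tools:", paste(names(x$params$tools), collapse = ", "), "\n")
  cat("  isotope samples:", nrow(x$isotope$samples),
      " intake rows:", nrow(x$intake), "\n")
  invisible(x)
}
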