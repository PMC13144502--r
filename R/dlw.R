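# Two-point doubly-labelled-water engine.
#
# Conventions: isotope excesses are carried in ppm excess atom fraction above
# the pre-dose baseline; elimination rates are per day; dilution spaces and
# the body-water pool are in moles of water; rCO2 in L/day; TDEE in kcal/day.

RCO2_COEF <- 0.4664          # pool-size coefficient of the rCO2 equation
MOLAR_VOLUME_CO2 <- 22.26    # L per mol CO2 at STP
ND_NO_REF_DEFAULT <- 1.041   # reference dilution-space ratio for pooling N_o, N_d

weir_factor <- function(rq) {
  if (any(rq <= 0)) abort("`rq` must be > 0")
  1.106 + 3.94 / rq
}

# moles of excess heavy-isotope tracer delivered by a dose, above natural
# abundance; the per-molecule site multiplicity of hydrogen cancels against
# the per-site definition of enrichment, so both tracers share one formula
dose_excess_mol <- function(dose_g, atom_fraction, tracer = c("18O", "2H")) {
  tracer <- match.arg(tracer)
  assert_positive(dose_g, "dose_g")
  if (any(atom_fraction <= 0) || any(atom_fraction > 1)) {
    abort("`atom_fraction` must lie in (0, 1]")
  }
  dose_g / MW_DOSE[[tracer]] * (atom_fraction - NAT_ABUNDANCE[[tracer]])
}

#' Isotope elimination rate from two time points
#'
#' `k = (ln(excess_initial) - ln(excess_final)) / delta_t`: the per-day
#' exponential decay constant of excess enrichment between the post-dose
#' plateau and the final sample.
#'
#' @param excess_initial,excess_final Excess enrichments at the two time
#'   points (any self-consistent unit, e.g. ppm excess); must be > 0.
#' @param delta_t_days Time between the points, days; must be > 0.
#' @return Elimination rate, per day. Negative when enrichment rises
#'   (non-physiologic; flagged downstream by [run_dlw()]).
#' @examples
#' elimination_rate(100, 50, 7) # log(2)/7
#' @export
elimination_rate <- function(excess_initial, excess_final, delta_t_days) {
  if (any(!is.finite(excess_initial)) || any(excess_initial <= 0)) {
    abort(paste0("initial excess must be > 0 (got ",
                 paste(signif(excess_initial, 4), collapse = ", "), ")"))
  }
  if (any(!is.finite(excess_final)) || any(excess_final <= 0)) {
    abort(paste0("final excess must be > 0 (got ",
                 paste(signif(excess_final, 4), collapse = ", "), ")"))
  }
  assert_positive(delta_t_days, "delta_t_days")
  (log(excess_initial) - log(excess_final)) / delta_t_days
}

#' Tracer dilution space from dose and plateau enrichment
#'
#' `N = (dose excess moles) / (plateau excess)`: the apparent body-water pool
#' that dilutes the administered tracer to its post-dose plateau enrichment.
#'
#' @param dose_g Dose mass, g of labelled water.
#' @param atom_fraction Heavy-isotope atom fraction of the dose, in (0, 1].
#' @param excess_plateau_ppm Plateau excess enrichment, ppm above baseline.
#' @param tracer `"18O"` or `"2H"` (selects dose molar mass and natural
#'   abundance).
#' @return Dilution space in moles of body water.
#' @examples
#' dilution_space(81, 0.10, 176.4, "18O")
#' @export
dilution_space <- function(dose_g, atom_fraction, excess_plateau_ppm,
                           tracer = c("18O", "2H")) {
  tracer <- match.arg(tracer)
  if (any(!is.finite(excess_plateau_ppm)) || any(excess_plateau_ppm <= 0)) {
    abort("plateau excess must be > 0")
  }
  dose_excess_mol(dose_g, atom_fraction, tracer) / (excess_plateau_ppm * 1e-6)
}

#' CO2 production rate from the body-water pool and elimination rates
#'
#' `rCO2 = 0.4664 * N * (1.007 k_O - 1.043 k_d) * 22.26` litres/day, where
#' the bracket is the isotopically derived CO2 turnover in mol/day per mol of
#' pool and 22.26 L/mol converts moles of CO2 to litres. The 1.007 and 1.043
#' factors correct the apparent elimination rates for isotope exchange and
#' fractionation.
#'
#' @param n_pool Body-water pool, mol.
#' @param k_o,k_d Elimination rates of \eqn{^{18}}O and \eqn{^{2}}H, per day.
#' @return CO2 production, L/day. May be negative for non-physiologic inputs
#'   (flagged, not errored, by [run_dlw()]).
#' @examples
#' rco2(2500, 0.12, 0.09) # ~700 L/day
#' @export
rco2 <- function(n_pool, k_o, k_d) {
  if (any(n_pool < 0)) abort("`n_pool` must be >= 0")
  RCO2_COEF * n_pool * (1.007 * k_o - 1.043 * k_d) * MOLAR_VOLUME_CO2
}

#' Energy expenditure from CO2 production (Weir equation)
#'
#' `TDEE = rCO2 * (1.106 + 3.94 / RQ)` kcal/day. The respiratory quotient RQ
#' (CO2 produced / O2 consumed) encodes the fuel mix; 0.85 is the standard
#' assumption for mixed diets when food-quotient data are unavailable.
#'
#' @param rco2_l_day CO2 production, L/day.
#' @param rq Respiratory quotient, > 0; default 0.85.
#' @return Energy expenditure, kcal/day.
#' @examples
#' tdee_weir(500)        # ~2870.6 kcal/day
#' tdee_weir(100, rq = 1)
#' @export
tdee_weir <- function(rco2_l_day, rq = 0.85) {
  rco2_l_day * weir_factor(rq)
}

#' Run the two-point DLW computation for one participant
#'
#' Assembles, per tracer, the plateau enrichment (arithmetic mean of the
#' plateau samples), the elimination rate from the plateau midpoint to the
#' final sample, and the dilution space from the dose; then pools the
#' dilution spaces into the body-water pool
#' `N = (N_o + N_d / nd_no_ref) / 2`, computes CO2 production and converts it
#' to energy expenditure with the Weir equation. Quality-control flags are
#' attached rather than errored: a dilution-space ratio outside `qc_band`,
#' negative elimination rates, or negative CO2 production.
#'
#' @param samples Tibble for one participant with columns `time_h`, `tracer`
#'   (`"18O"`/`"2H"`) and `excess_ppm`. A pre-dose row (time 0) is allowed and
#'   ignored; plateau rows at `plateau_times_h` and one final row at the
#'   latest time are required for each tracer.
#' @param doses Tibble with one row per tracer: `tracer`, `dose_g`,
#'   `atom_fraction`.
#' @param rq Respiratory quotient passed to [tdee_weir()].
#' @param plateau_times_h Post-dose plateau sampling times, hours.
#' @param nd_no_ref Reference dilution-space ratio used to pool N_o and N_d.
#' @param qc_band Acceptable range of the observed N_d/N_o ratio.
#' @return A one-row tibble of class `dlw_result`: elimination rates,
#'   dilution spaces, pooled N, QC ratios, `rco2_l_day`, `tdee_kcal_day`,
#'   `tdee_kj_day` (exactly 4.184 x kcal) and a `qc_flags` string
#'   (`;`-separated, empty when clean).
#' @seealso [run_dlw_cohort()] for a whole sample sheet.
#' @export
run_dlw <- function(samples, doses, rq = 0.85,
                    plateau_times_h = c(4, 5),
                    nd_no_ref = ND_NO_REF_DEFAULT,
                    qc_band = c(1.00, 1.07)) {
  need <- c("time_h", "tracer", "excess_ppm")
  miss <- setdiff(need, names(samples))
  if (length(miss)) abort(paste("sample sheet is missing columns:",
                                paste(miss, collapse = ", ")))
  flags <- character()

  per_tracer <- function(tr) {
    s <- samples[samples$tracer == tr & samples$time_h > 0, , drop = FALSE]
    if (nrow(s) == 0) abort(paste0("no post-dose samples for tracer ", tr))
    plat <- s$excess_ppm[s$time_h %in% plateau_times_h]
    if (length(plat) == 0) {
      abort(paste0("missing plateau sample(s) at ",
                   paste(plateau_times_h, collapse = "/"),
                   " h for tracer ", tr))
    }
    t_final <- max(s$time_h)
    if (t_final <= max(plateau_times_h)) {
      abort(paste0("no final sample after the plateau for tracer ", tr))
    }
    e_final <- s$excess_ppm[s$time_h == t_final][1]
    e_plat <- mean(plat)
    dt_days <- (t_final - mean(plateau_times_h)) / 24
    d <- doses[doses$tracer == tr, , drop = FALSE]
    if (nrow(d) == 0) abort(paste0("missing dose specification for tracer ", tr))
    list(k = elimination_rate(e_plat, e_final, dt_days),
         n = dilution_space(d$dose_g[1], d$atom_fraction[1], e_plat, tr))
  }

  o <- per_tracer("18O")
  h <- per_tracer("2H")
  if (o$k <= 0 || h$k <= 0) flags <- c(flags, "nonpositive_elimination_rate")
  ratio_nd_no <- h$n / o$n
  if (ratio_nd_no < qc_band[1] || ratio_nd_no > qc_band[2]) {
    flags <- c(flags, "nd_no_outside_band")
  }
  n_pool <- (o$n + h$n / nd_no_ref) / 2
  r <- rco2(n_pool, o$k, h$k)
  if (r < 0) flags <- c(flags, "negative_rco2")
  tdee <- tdee_weir(r, rq)
  res <- tibble(
    k_o = o$k, k_d = h$k,
    n_o = o$n, n_d = h$n, n_pool = n_pool,
    ratio_nd_no = ratio_nd_no, ratio_ko_kd = o$k / h$k,
    rco2_l_day = r,
    tdee_kcal_day = tdee, tdee_kj_day = tdee * KCAL_TO_KJ,
    qc_flags = paste(flags, collapse = ";")
  )
  class(res) <- c("dlw_result", class(res))
  res
}

#' Run the DLW computation over a multi-participant sample sheet
#'
#' @param samples Tibble with a `participant_id` column plus the columns
#'   required by [run_dlw()].
#' @param doses Tibble with `participant_id`, `tracer`, `dose_g`,
#'   `atom_fraction`.
#' @inheritParams run_dlw
#' @return Tibble with one [run_dlw()] row per participant, keyed by
#'   `participant_id`.
#' @examples
#' sim <- simulate_cohort(cohort_params(n = 3, seed = 2, isotope_noise_sd = 0))
#' run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
#' @export
run_dlw_cohort <- function(samples, doses, rq = 0.85,
                           plateau_times_h = c(4, 5),
                           nd_no_ref = ND_NO_REF_DEFAULT,
                           qc_band = c(1.00, 1.07)) {
  if (!"participant_id" %in% names(samples)) {
    abort("sample sheet needs a `participant_id` column")
  }
  ids <- unique(samples$participant_id)
  purrr::map_dfr(ids, function(id) {
    res <- run_dlw(samples[samples$participant_id == id, , drop = FALSE],
                   doses[doses$participant_id == id, , drop = FALSE],
                   rq = rq, plateau_times_h = plateau_times_h,
                   nd_no_ref = nd_no_ref, qc_band = qc_band)
    dplyr::bind_cols(tibble(participant_id = id), res)
  })
}
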