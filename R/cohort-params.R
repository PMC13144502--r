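#' Parameters for the synthetic validation cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults emulate
#' a free-living DLW validation study in adult females with obesity: n = 20,
#' weight 108.4 +/- 16.3 kg, height 1.66 +/- 0.06 m, age 37.9 +/- 13.4 y,
#' DLW-measured TDEE 3004.2 +/- 480.5 kcal/day, a 7-day reporting window, and
#' two reporting tools — an image-based app that underestimates intake by 25%
#' on average with large within-person variability, and a recall-style
#' instrument that underestimates by 50% with tighter variability.
#'
#' @param n Number of participants (>= 2).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   parameter set and this seed.
#' @param weight_mean,weight_sd Body weight moments, kg.
#' @param height_mean,height_sd Height moments, m.
#' @param age_mean,age_sd Age moments, years.
#' @param tdee_mean,tdee_sd True total daily energy expenditure moments,
#'   kcal/day.
#' @param tools Named list of per-tool reporting models. Each element is a
#'   list with `bias_frac` (fractional reporting bias, negative =
#'   underreporting), `cv_within` and `cv_between` (within- and between-person
#'   coefficients of variation of reported intake, percent), and
#'   `occasions_mean` (Poisson mean of daily eating occasions).
#' @param n_days Days of intake reporting (>= 1).
#' @param rq Assumed respiratory quotient, in `[0.7, 1.0]`.
#' @param isotope_noise_sd Additive measurement noise on post-dose isotope
#'   excesses, ppm excess abundance. 0 gives noise-free kinetics. The default
#'   0.25 ppm reflects optical-spectroscopy analytic precision and, after
#'   two-point propagation through the elimination-rate difference, yields
#'   the ~4-6% TDEE repeatability typical of DLW.
#' @param body_fat_frac_mean,body_fat_frac_sd Fat mass as a fraction of body
#'   weight (drawn per participant, truncated to `[0.15, 0.60]`).
#' @param hydration Hydration fraction of fat-free mass used to derive total
#'   body water (TBW = hydration * FFM).
#' @param nd_no_mean,nd_no_sd Moments of the simulated dilution-space ratio
#'   N_d/N_o (a DLW quality-control metric, physiologically near 1.04).
#' @param ko_kd_mean,ko_kd_sd Moments of the simulated elimination-rate ratio
#'   k_O/k_d (> 1 in physiologic data).
#' @param ree_cv Coefficient of variation (%) of the simulated device-measured
#'   resting energy expenditure around its anthropometric prediction.
#' @param pal_lifestyle_mean,pal_lifestyle_sd Moments of the self-reported
#'   lifestyle physical activity level.
#' @param macro_fracs Named energy fractions (`carb`, `fat`, `protein`) of
#'   reported intake; must sum to 1.
#'
#' @return An object of class `cohort_params` (a validated list).
#' @seealso [simulate_cohort()]
#' @examples
#' p <- cohort_params(n = 5, seed = 42)
#' p$tools$app$bias_frac
#' @export
cohort_params <- function(n = 20,
                          seed = 1L,
                          weight_mean = 108.4, weight_sd = 16.3,
                          height_mean = 1.66, height_sd = 0.06,
                          age_mean = 37.9, age_sd = 13.4,
                          tdee_mean = 3004.2, tdee_sd = 480.5,
                          tools = list(
                            app = list(bias_frac = -0.25, cv_within = 88.36,
                                       cv_between = 35, occasions_mean = 5.5),
                            recall = list(bias_frac = -0.50, cv_within = 26,
                                          cv_between = 25, occasions_mean = 3.4)
                          ),
                          n_days = 7L,
                          rq = 0.85,
                          isotope_noise_sd = 0.25,
                          body_fat_frac_mean = 0.48, body_fat_frac_sd = 0.04,
                          hydration = 0.732,
                          nd_no_mean = 1.0398, nd_no_sd = 0.0067,
                          ko_kd_mean = 1.3207, ko_kd_sd = 0.0598,
                          ree_cv = 5,
                          pal_lifestyle_mean = 1.5, pal_lifestyle_sd = 0.15,
                          macro_fracs = c(carb = 0.45, fat = 0.35, protein = 0.20)) {
  if (!is.numeric(n) || n < 2) abort("`n` must be >= 2")
  if (n_days < 1) abort("`n_days` must be >= 1")
  if (rq < 0.7 || rq > 1.0) abort("`rq` must lie in [0.7, 1.0]")
  sds <- c(weight_sd, height_sd, age_sd, tdee_sd, body_fat_frac_sd,
           nd_no_sd, ko_kd_sd, pal_lifestyle_sd)
  if (any(sds < 0)) abort("all standard deviations must be >= 0")
  if (isotope_noise_sd < 0) abort("`isotope_noise_sd` must be >= 0")
  if (!is.list(tools) || is.null(names(tools)) || any(names(tools) == "")) {
    abort("`tools` must be a named list")
  }
  for (nm in names(tools)) {
    t <- tools[[nm]]
    need <- c("bias_frac", "cv_within", "cv_between", "occasions_mean")
    miss <- setdiff(need, names(t))
    if (length(miss)) abort(paste0("tool `", nm, "` is missing: ",
                                   paste(miss, collapse = ", ")))
    if (t$cv_within < 0 || t$cv_between < 0) {
      abort(paste0("tool `", nm, "`: CVs must be >= 0"))
    }
  }
  if (abs(sum(macro_fracs[c("carb", "fat", "protein")]) - 1) > 1e-8) {
    abort("`macro_fracs` carb + fat + protein must sum to 1")
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         weight_mean = weight_mean, weight_sd = weight_sd,
         height_mean = height_mean, height_sd = height_sd,
         age_mean = age_mean, age_sd = age_sd,
         tdee_mean = tdee_mean, tdee_sd = tdee_sd,
         tools = tools, n_days = as.integer(n_days), rq = rq,
         isotope_noise_sd = isotope_noise_sd,
         body_fat_frac_mean = body_fat_frac_mean,
         body_fat_frac_sd = body_fat_frac_sd,
         hydration = hydration,
         nd_no_mean = nd_no_mean, nd_no_sd = nd_no_sd,
         ko_kd_mean = ko_kd_mean, ko_kd_sd = ko_kd_sd,
         ree_cv = ree_cv,
         pal_lifestyle_mean = pal_lifestyle_mean,
         pal_lifestyle_sd = pal_lifestyle_sd,
         macro_fracs = macro_fracs),
    class = "cohort_params"
  )
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params>\n")
  cat("  n =", x$n, " seed =", x$seed, " days =", x$n_days, "\n")
  cat(sprintf("  weight %.1f (%.1f) kg, height %.2f (%.2f) m, age %.1f (%.1f) y\n",
              x$weight_mean, x$weight_sd, x$height_mean, x$height_sd,
              x$age_mean, x$age_sd))
  cat(sprintf("  TDEE %.1f (%.1f) kcal/day, RQ %.2f\n",
              x$tdee_mean, x$tdee_sd, x$rq))
  for (nm in names(x$tools)) {
    t <- x$tools[[nm]]
    cat(sprintf("  tool %-8s bias %+.0f%%, CVw %.1f%%, CVb %.1f%%\n",
                nm, 100 * t$bias_frac, t$cv_within, t$cv_between))
  }
  invisible(x)
}
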