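# Energy-requirement prediction and physical-activity-level variants.
#
# In cohorts with obesity, predicting basal metabolic rate from actual body
# weight overestimates it (adipose tissue is metabolically less active than
# lean tissue), so the prediction equations are evaluated on adjusted body
# weight by default: ABW = IBW + 0.3 * (weight - IBW), with IBW from the
# Devine formula.

HB_FEMALE_COEF <- c(intercept = 655.0955, weight = 9.5634,
                    height = 1.8496, age = -4.6756)

#' Ideal body weight (Devine, adult females)
#'
#' `IBW = 50 + 2.3 * ((height_cm - 152.4) / 2.54)` kg — 50 kg at 5 ft plus
#' 2.3 kg per inch above.
#'
#' @param height_m Height in metres.
#' @return Ideal body weight, kg.
#' @examples
#' ibw_devine(1.524) # exactly 50
#' @export
ibw_devine <- function(height_m) {
  assert_positive(height_m, "height_m")
  50 + 2.3 * (height_m * 100 - 152.4) / 2.54
}

#' Adjusted body weight
#'
#' `ABW = IBW + 0.3 * (weight - IBW)`, i.e. 70% ideal and 30% actual weight.
#' The formula is applied unchanged when `weight < IBW` (a warning is
#' emitted; such participants are outside the intended population).
#'
#' @param weight_kg Actual body weight, kg.
#' @param ibw_kg Ideal body weight, kg (see [ibw_devine()]).
#' @param fraction Weight placed on the excess over IBW; default 0.3.
#' @return Adjusted body weight, kg.
#' @export
adjusted_body_weight <- function(weight_kg, ibw_kg, fraction = 0.3) {
  assert_positive(weight_kg, "weight_kg")
  assert_positive(ibw_kg, "ibw_kg")
  if (any(weight_kg < ibw_kg)) {
    warn("weight below ideal body weight for some participants; ABW < IBW there")
  }
  ibw_kg + fraction * (weight_kg - ibw_kg)
}

#' Basal metabolic rate, Mifflin-St Jeor (female form)
#'
#' `BMR = 10 W + 6.25 H - 5 A - 161` kcal/day with weight in kg, height in
#' cm, age in years. Pass adjusted body weight as `weight_kg` to obtain the
#' obesity-adjusted aBMR.
#'
#' @param weight_kg Body weight (actual or adjusted), kg.
#' @param height_cm Height, cm.
#' @param age_years Age, years.
#' @return BMR, kcal/day.
#' @examples
#' bmr_mifflin_female(76.14, 166, 37.9)
#' @export
bmr_mifflin_female <- function(weight_kg, height_cm, age_years) {
  if (any(weight_kg <= 0) || any(height_cm <= 0) || any(age_years < 0)) {
    warn("out-of-domain anthropometrics passed to the Mifflin-St Jeor equation")
  }
  10 * weight_kg + 6.25 * height_cm - 5 * age_years - 161
}

#' Basal metabolic rate, Harris-Benedict (revised classic female form)
#'
#' `BMR = 655.0955 + 9.5634 W + 1.8496 H - 4.6756 A` kcal/day. The
#' coefficient set is configurable since several revisions circulate.
#'
#' @inheritParams bmr_mifflin_female
#' @param coef Named coefficient vector (`intercept`, `weight`, `height`,
#'   `age`).
#' @return BMR, kcal/day.
#' @export
bmr_harris_benedict_female <- function(weight_kg, height_cm, age_years,
                                       coef = HB_FEMALE_COEF) {
  stopifnot(all(c("intercept", "weight", "height", "age") %in% names(coef)))
  coef[["intercept"]] + coef[["weight"]] * weight_kg +
    coef[["height"]] * height_cm + coef[["age"]] * age_years
}

#' Energy-requirement norms for a participant table
#'
#' Computes, per participant, Devine IBW, adjusted body weight, both BMR
#' predictions on the chosen weight basis, and the selected aBMR variant.
#'
#' @param participants Tibble with `id`, `height_m`, `weight_day1_kg`,
#'   `age_years` (as produced by [generate_participants()] or
#'   [read_cohort()]).
#' @param bmr_variant Which equation supplies the working `abmr` column:
#'   `"mifflin"` (default) or `"harris_benedict"`.
#' @param use_abw Evaluate the BMR equations on adjusted (default) rather
#'   than actual body weight.
#' @return Tibble: `id`, `ibw_kg`, `abw_kg`, `bmr_mifflin`,
#'   `bmr_harris_benedict`, `abmr` (all kcal/day except weights).
#' @export
energy_norms <- function(participants,
                         bmr_variant = c("mifflin", "harris_benedict"),
                         use_abw = TRUE) {
  bmr_variant <- match.arg(bmr_variant)
  need <- c("id", "height_m", "weight_day1_kg", "age_years")
  miss <- setdiff(need, names(participants))
  if (length(miss)) abort(paste("participants table is missing:",
                                paste(miss, collapse = ", ")))
  ibw <- ibw_devine(participants$height_m)
  abw <- adjusted_body_weight(participants$weight_day1_kg, ibw)
  w <- if (use_abw) abw else participants$weight_day1_kg
  h_cm <- participants$height_m * 100
  msj <- bmr_mifflin_female(w, h_cm, participants$age_years)
  hb <- bmr_harris_benedict_female(w, h_cm, participants$age_years)
  tibble(
    id = participants$id,
    ibw_kg = ibw, abw_kg = abw,
    bmr_mifflin = msj, bmr_harris_benedict = hb,
    abmr = if (bmr_variant == "mifflin") msj else hb
  )
}

#' The three physical-activity-level variants
#'
#' PAL is the ratio of total to resting energy expenditure, computed three
#' ways: against the adjusted-weight BMR prediction (`pal_abmr`), against the
#' device-measured REE (`pal_ree`), and as the self-reported lifestyle value
#' passed through unchanged (`pal_lifestyle`). A missing REE or lifestyle
#' column yields `NA` for the corresponding variant — never a default.
#'
#' @param tdee_kcal_day DLW-derived TDEE, kcal/day.
#' @param abmr Adjusted-weight BMR, kcal/day (from [energy_norms()]).
#' @param ree_kcal_day Device-measured resting energy expenditure, kcal/day,
#'   or `NULL`/`NA` when unavailable.
#' @param pal_lifestyle Self-reported lifestyle PAL, or `NULL`/`NA`.
#' @return Tibble: `pal_abmr`, `pal_ree`, `pal_lifestyle`.
#' @export
pal_set <- function(tdee_kcal_day, abmr, ree_kcal_day = NULL,
                    pal_lifestyle = NULL) {
  assert_positive(abmr, "abmr")
  n <- length(tdee_kcal_day)
  ree <- ree_kcal_day %||% rep(NA_real_, n)
  if (any(!is.na(ree) & ree <= 0)) abort("`ree_kcal_day` must be > 0 where present")
  tibble(
    pal_abmr = tdee_kcal_day / abmr,
    pal_ree = tdee_kcal_day / ree,
    pal_lifestyle = as.numeric(pal_lifestyle %||% rep(NA_real_, n))
  )
}
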