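# Nine-facet validity scorecard for one dietary assessment tool against a
# reference measure of energy expenditure.
#
# Facets: (1) agreement (Bland-Altman), (2) strength of relationship
# (Pearson), (3) accuracy (absolute and percentage difference with paired
# test), (4) misreporting magnitudes, (5) Goldberg plausibility counts,
# (6) homoeostatic control (intake vs fat-free mass), (7) energy balance
# (intake vs energy-storage change), (8) compliance (measurement difference
# vs weight change), (9) diet stability (day-to-day ICC).

#' Assemble the per-participant validation table
#'
#' Joins participants, energy norms, DLW results and per-tool mean reported
#' intake into one wide analysis table, the common input of
#' [classification_grid()] and [build_scorecard()].
#'
#' @param participants Participant tibble (see [generate_participants()] or
#'   [read_cohort()]).
#' @param intake_daily Daily intake tibble (`participant_id`, `tool`, `day`,
#'   `kcal`, ...).
#' @param dlw DLW result tibble from [run_dlw_cohort()].
#' @param norms Energy-norms tibble from [energy_norms()]; computed from
#'   `participants` when omitted.
#' @return A list of class `validation_bundle`: `analysis` (wide
#'   per-participant table with `tdee_kcal_day`, `abmr`, PAL variants and one
#'   `tdei_<tool>` column per tool) and `intake_daily`.
#' @export
assemble_validation <- function(participants, intake_daily, dlw,
                                norms = NULL) {
  norms <- norms %||% energy_norms(participants)
  tdei <- dplyr::summarise(
    dplyr::group_by(intake_daily, .data$participant_id, .data$tool),
    tdei = mean(.data$kcal), .groups = "drop")
  tdei_wide <- tidyr::pivot_wider(tdei, names_from = "tool",
                                  values_from = "tdei",
                                  names_prefix = "tdei_")
  analysis <- participants |>
    dplyr::left_join(norms, by = "id") |>
    dplyr::left_join(
      dplyr::select(dlw, "participant_id", "tdee_kcal_day", "ratio_nd_no",
                    "qc_flags"),
      by = c(id = "participant_id")) |>
    dplyr::left_join(tdei_wide, by = c(id = "participant_id"))
  pal <- pal_set(analysis$tdee_kcal_day, analysis$abmr,
                 analysis$ree_kcal_day,
                 analysis$pal_lifestyle)
  analysis$pal_abmr <- pal$pal_abmr
  analysis$pal_ree <- pal$pal_ree
  structure(list(analysis = analysis, intake_daily = intake_daily),
            class = "validation_bundle")
}

#' Mean percentage difference between reported intake and expenditure
#'
#' Mean over participants of `100 * (tdei_i - tdee_i) / tdee_i` — the mean of
#' individual percentage errors, not the percentage error of the means (the
#' two differ whenever error and expenditure are correlated).
#'
#' @param tdei,tdee Per-participant reported intake and reference
#'   expenditure, kcal/day; `tdee` must be positive throughout.
#' @return A list: `mean_pct`, `sd_pct`, `n`.
#' @examples
#' percentage_difference(c(750, 1500), c(1000, 2000)) # -25% each
#' @export
percentage_difference <- function(tdei, tdee) {
  if (length(tdei) != length(tdee)) abort("inputs must have equal length")
  if (any(!is.finite(tdee)) || any(tdee <= 0)) {
    abort("all reference expenditures must be finite and > 0")
  }
  pct <- 100 * (tdei - tdee) / tdee
  list(mean_pct = mean(pct),
       sd_pct = if (length(pct) > 1) stats::sd(pct) else NA_real_,
       n = length(pct))
}

#' Mean over- and under-estimation magnitudes
#'
#' Means of the positive and of the negative per-participant differences,
#' reported separately in kcal/day and as a percentage of the reference mean.
#' An empty side is `NA` (e.g. "no overestimation" when every participant
#' underreports).
#'
#' @param diffs Per-participant differences (tool minus reference), kcal/day.
#' @param reference_mean Mean of the reference method, used to express the
#'   magnitudes in percent.
#' @return A list: `over_mean`, `under_mean` (kcal/day), `over_pct`,
#'   `under_pct`, `n_over`, `n_under`, `n_zero`.
#' @examples
#' misreport_magnitudes(c(100, -200, -400), 3000)
#' @export
misreport_magnitudes <- function(diffs, reference_mean) {
  if (length(diffs) < 1) abort("need at least one participant")
  over <- diffs[diffs > 0]
  under <- diffs[diffs < 0]
  om <- if (length(over)) mean(over) else NA_real_
  um <- if (length(under)) mean(under) else NA_real_
  list(over_mean = om, under_mean = um,
       over_pct = 100 * om / reference_mean,
       under_pct = 100 * um / reference_mean,
       n_over = length(over), n_under = length(under),
       n_zero = sum(diffs == 0))
}

# signed-r2 regression facet helper; returns NA-filled entry when the
# covariate is absent
facet_assoc <- function(x, y, k) {
  if (all(is.na(x)) || all(is.na(y))) {
    return(list(signed_r2 = NA_real_, p_adjusted = NA_real_, n = 0L))
  }
  pa <- pearson_assoc(x, y)
  list(signed_r2 = pa$signed_r2,
       p_adjusted = if (is.na(pa$p)) NA_real_ else min(1, k * pa$p),
       n = pa$n)
}

#' Build the nine-facet validity scorecard for one tool
#'
#' Runs every facet of the comprehensive validity assessment of a dietary
#' assessment tool against the DLW reference: group-level agreement and its
#' limits, strength and direction of association with expenditure, absolute
#' and relative accuracy with a normality-gated paired test, the magnitudes
#' of over- and under-estimation, Goldberg plausibility counts (the
#' best-performing grid cell), the physiological-plausibility regressions
#' (fat-free mass, energy-storage change, weight-change compliance), and the
#' day-to-day stability ICC. Facet 1 reuses the [bland_altman()] result
#' object unchanged.
#'
#' @param bundle A `validation_bundle` from [assemble_validation()].
#' @param tool Name of the tool column (`tdei_<tool>` must exist).
#' @param convention Divisor convention for facet 1, see [bland_altman()].
#' @param energy_density Energy content of body-weight change, kcal/kg;
#'   default 7700 (mixed-tissue convention) for facet 7's energy-storage
#'   regressor `delta_weight * energy_density`.
#' @param bonferroni_k Multiplicity family size applied to the facet p-values
#'   (facets 2, 3, 6, 7, 8); default 3.
#' @param goldberg_args Extra arguments passed to [classification_grid()]
#'   for facet 5.
#' @return A `validity_report` (list of facets with a print method);
#'   [as_tibble()] renders it long (`facet`, `metric`, `value`).
#' @export
build_scorecard <- function(bundle, tool, convention = c("n", "n-1"),
                            energy_density = 7700, bonferroni_k = 3,
                            goldberg_args = list()) {
  stopifnot(inherits(bundle, "validation_bundle"))
  convention <- match.arg(convention)
  an <- bundle$analysis
  col <- paste0("tdei_", tool)
  if (!col %in% names(an)) abort(paste0("no column `", col, "` in the bundle"))
  tdei <- an[[col]]
  tdee <- an$tdee_kcal_day
  ok <- complete.cases(tdei, tdee)
  diffs <- tdei[ok] - tdee[ok]

  ba <- bland_altman(tdei[ok], tdee[ok], convention = convention)
  assoc <- facet_assoc(tdee, tdei, bonferroni_k)
  pc <- paired_compare(tdei[ok], tdee[ok], bonferroni_k = bonferroni_k)
  pd <- percentage_difference(tdei[ok], tdee[ok])
  mm <- misreport_magnitudes(diffs, mean(tdee[ok]))

  grid <- tryCatch(
    do.call(classification_grid,
            c(list(analysis = an, intake_daily = bundle$intake_daily), goldberg_args)),
    error = function(e) NULL)
  goldberg <- if (!is.null(grid) && nrow(grid) > 0) {
    g <- grid[grid$tool == tool & grid$best, , drop = FALSE][1, ]
    list(n_plausible = g$n_plausible, n_over = g$n_over, n_under = g$n_under,
         denominator = g$denominator, pal_variant = g$pal_variant,
         s_mode = g$s_mode, s = g$s)
  } else {
    list(n_plausible = NA_integer_, n_over = NA_integer_,
         n_under = NA_integer_, denominator = NA_character_,
         pal_variant = NA_character_, s_mode = NA_character_, s = NA_real_)
  }

  dw <- an$weight_day8_kg - an$weight_day1_kg
  ffm <- facet_assoc(an$ffm_kg, tdei, bonferroni_k)
  storage <- facet_assoc(dw * energy_density, tdei, bonferroni_k)
  compliance <- facet_assoc(dw, tdei - tdee, bonferroni_k)

  daily <- bundle$intake_daily[bundle$intake_daily$tool == tool, , drop = FALSE]
  stability <- tryCatch({
    wide <- tidyr::pivot_wider(
      dplyr::select(daily, "participant_id", "day", "kcal"),
      names_from = "day", values_from = "kcal")
    icc <- icc_two_way_random(as.matrix(wide[, -1]))
    list(icc = icc$icc, ci = icc$ci, p = icc$p)
  }, error = function(e) list(icc = NA_real_,
                              ci = c(lower = NA_real_, upper = NA_real_),
                              p = NA_real_))

  structure(
    list(tool = tool, reference = "DLW", n = sum(ok),
         agreement = ba,
         strength = assoc,
         accuracy = list(mean_diff = ba$bias, sd_diff = ba$sd_bias,
                         mean_pct = pd$mean_pct, sd_pct = pd$sd_pct,
                         test = pc$test, p_adjusted = pc$p_adjusted),
         misreporting = mm,
         goldberg = goldberg,
         homoeostasis = ffm,
         energy_balance = storage,
         compliance = compliance,
         stability = stability),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  fmt_or <- function(v, fmt, alt) if (is.na(v)) alt else sprintf(fmt, v)
  cat("Validity scorecard:", x$tool, "vs", x$reference,
      sprintf("(n = %d)\n", x$n))
  cat(sprintf("  1 Agreement      bias %.1f kcal/day, LoA (%.1f, %.1f)\n",
              x$agreement$bias, x$agreement$loa[["lower"]],
              x$agreement$loa[["upper"]]))
  cat(sprintf("  2 Strength       signed R2 = %.0f%%, p = %.2g\n",
              100 * x$strength$signed_r2, x$strength$p_adjusted))
  cat(sprintf("  3 Accuracy       %.1f +/- %.1f kcal/day (%.1f%%), %s, p = %.2g\n",
              x$accuracy$mean_diff, x$accuracy$sd_diff, x$accuracy$mean_pct,
              x$accuracy$test, x$accuracy$p_adjusted))
  side <- function(mean, pct, absent) {
    if (is.na(mean)) absent
    else sprintf("%+.1f kcal/day (%+.1f%%)", mean, pct)
  }
  cat("  4 Misreporting   over:", side(x$misreporting$over_mean,
                                       x$misreporting$over_pct,
                                       "no overestimation"),
      " under:", side(x$misreporting$under_mean, x$misreporting$under_pct,
                      "no underestimation"), "\n")
  cat(sprintf("  5 Goldberg       %s plausible, %s over, %s under  [%s/%s, S %s]\n",
              x$goldberg$n_plausible, x$goldberg$n_over, x$goldberg$n_under,
              x$goldberg$denominator, x$goldberg$pal_variant,
              x$goldberg$s_mode))
  cat(sprintf("  6 Homoeostasis   signed R2 = %.0f%%, p = %.2g (vs FFM)\n",
              100 * x$homoeostasis$signed_r2, x$homoeostasis$p_adjusted))
  cat(sprintf("  7 Energy balance signed R2 = %.0f%%, p = %.2g (vs storage change)\n",
              100 * x$energy_balance$signed_r2, x$energy_balance$p_adjusted))
  cat(sprintf("  8 Compliance     signed R2 = %.0f%%, p = %.2g (diff vs weight change)\n",
              100 * x$compliance$signed_r2, x$compliance$p_adjusted))
  cat(sprintf("  9 Stability      ICC = %.2f [%.2f, %.2f]\n",
              x$stability$icc, x$stability$ci[["lower"]],
              x$stability$ci[["upper"]]))
  invisible(x)
}

#' @export
as_tibble.validity_report <- function(x, ...) {
  num <- function(facet, metric, value) {
    tibble(facet = facet, metric = metric, value = as.numeric(value))
  }
  dplyr::bind_rows(
    num("agreement", "bias", x$agreement$bias),
    num("agreement", "loa_lower", x$agreement$loa[["lower"]]),
    num("agreement", "loa_upper", x$agreement$loa[["upper"]]),
    num("strength", "signed_r2", x$strength$signed_r2),
    num("strength", "p_adjusted", x$strength$p_adjusted),
    num("accuracy", "mean_diff", x$accuracy$mean_diff),
    num("accuracy", "sd_diff", x$accuracy$sd_diff),
    num("accuracy", "mean_pct", x$accuracy$mean_pct),
    num("accuracy", "p_adjusted", x$accuracy$p_adjusted),
    num("misreporting", "over_mean", x$misreporting$over_mean),
    num("misreporting", "over_pct", x$misreporting$over_pct),
    num("misreporting", "under_mean", x$misreporting$under_mean),
    num("misreporting", "under_pct", x$misreporting$under_pct),
    num("goldberg", "n_plausible", x$goldberg$n_plausible),
    num("goldberg", "n_over", x$goldberg$n_over),
    num("goldberg", "n_under", x$goldberg$n_under),
    num("homoeostasis", "signed_r2", x$homoeostasis$signed_r2),
    num("homoeostasis", "p_adjusted", x$homoeostasis$p_adjusted),
    num("energy_balance", "signed_r2", x$energy_balance$signed_r2),
    num("energy_balance", "p_adjusted", x$energy_balance$p_adjusted),
    num("compliance", "signed_r2", x$compliance$signed_r2),
    num("compliance", "p_adjusted", x$compliance$p_adjusted),
    num("stability", "icc", x$stability$icc),
    num("stability", "icc_ci_lower", x$stability$ci[["lower"]]),
    num("stability", "icc_ci_upper", x$stability$ci[["upper"]])
  )
}
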