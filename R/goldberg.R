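# Goldberg cut-off classification of reporting plausibility.
#
# A participant's reported-intake:BMR ratio is compared against log-scale
# bounds around a reference PAL; the width of the bounds is driven by the
# composite variability factor S, which pools within-person intake
# variability (shrunk by the number of reporting days), the uncertainty of
# the BMR/REE denominator, and between-person PAL variability.

#' Black's default variability components for adult females
#'
#' Within-subject CV of reported intake 26%, between-subject CV of PAL
#' 14.9%, CV of the BMR prediction 8.5%.
#'
#' @return Named numeric vector (`cv_w_tdei`, `cv_t_p`, `cv_w_b`), percent.
#' @export
black_defaults <- function() {
  c(cv_w_tdei = 26, cv_t_p = 14.9, cv_w_b = 8.5)
}

#' Composite variability factor S
#'
#' `S = sqrt(cv_w_tdei^2 / d + cv_w_b^2 + cv_t_p^2)` percent, where `d` is
#' the number of diet-assessment days (repeated days shrink the within-person
#' intake component).
#'
#' @param cv_w_tdei Within-subject CV of reported intake, %.
#' @param cv_w_b CV of the BMR/REE denominator, %.
#' @param cv_t_p Between-subject CV of PAL, %.
#' @param d Days of diet assessment, >= 1.
#' @return S, percent.
#' @examples
#' do.call(s_factor, c(as.list(black_defaults()), d = 7))
#' @export
s_factor <- function(cv_w_tdei, cv_w_b, cv_t_p, d) {
  if (any(c(cv_w_tdei, cv_w_b, cv_t_p) < 0)) abort("CV components must be >= 0")
  if (d < 1) abort("`d` must be >= 1")
  sqrt(cv_w_tdei^2 / d + cv_w_b^2 + cv_t_p^2)
}

#' Goldberg plausibility bounds
#'
#' Log-scale symmetric bounds around the reference PAL:
#' `pal_ref * exp(-z * (s/100) / sqrt(n))` to
#' `pal_ref * exp(+z * (s/100) / sqrt(n))`.
#'
#' @param pal_ref Reference physical activity level, > 0.
#' @param s Composite variability factor, percent (see [s_factor()]).
#' @param n Number of participants entering the bound, >= 1. Both the `n` and
#'   `n - 1` conventions circulate; pass whichever is wanted.
#' @param z Normal quantile; default 1.96 for 95% bounds.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' goldberg_bounds(2.081, 40.01, 19) # ~ (1.74, 2.49)
#' @export
goldberg_bounds <- function(pal_ref, s, n, z = 1.96) {
  assert_positive(pal_ref, "pal_ref")
  if (s < 0) abort("`s` must be >= 0")
  if (n < 1) abort("`n` must be >= 1")
  assert_positive(z, "z")
  half <- z * (s / 100) / sqrt(n)
  c(lower = pal_ref * exp(-half), upper = pal_ref * exp(half))
}

#' Classify an intake:denominator ratio against Goldberg bounds
#'
#' `"under"` strictly below the lower bound, `"over"` strictly above the
#' upper, `"plausible"` otherwise (ties at a bound count as plausible —
#' conservative toward accurate reporting); `NA` ratios give
#' `"unclassifiable"`.
#'
#' @param ei_ratio Reported intake divided by the BMR/REE denominator.
#' @param bounds Numeric `c(lower, upper)` from [goldberg_bounds()].
#' @return Character vector of labels.
#' @export
classify_goldberg <- function(ei_ratio, bounds) {
  stopifnot(length(bounds) == 2, bounds[1] <= bounds[2])
  dplyr::case_when(
    is.na(ei_ratio) ~ "unclassifiable",
    ei_ratio < bounds[1] ~ "under",
    ei_ratio > bounds[2] ~ "over",
    TRUE ~ "plausible"
  )
}

# pooled within-subject CV (%) of daily intake: root-mean of per-participant
# variances over the grand mean of participant means
cv_within_intake <- function(intake_daily) {
  per <- dplyr::summarise(dplyr::group_by(intake_daily, .data$participant_id),
                          m = mean(.data$kcal), v = stats::var(.data$kcal),
                          .groups = "drop")
  100 * sqrt(mean(per$v)) / mean(per$m)
}

#' Goldberg classification across the full method grid
#'
#' Classifies each participant-tool mean reported intake for every
#' combination of denominator (adjusted-weight BMR or device REE), PAL
#' variant (TDEE/aBMR, TDEE/REE, lifestyle) and variability-factor mode
#' (study-specific, computed from the cohort's own daily intake and PAL
#' spread, or Black's defaults), and tabulates under/plausible/over counts
#' per cell. The cell maximising plausible reporters per tool is flagged in
#' the `best` column.
#'
#' @param analysis Per-participant analysis table from
#'   [assemble_validation()] (needs `abmr`, `ree_kcal_day`, `pal_abmr`,
#'   `pal_ree`, `pal_lifestyle` and one `tdei_<tool>` column per tool).
#' @param intake_daily Daily intake tibble (for the study-specific
#'   within-person CV), or `NULL` to skip study-specific S cells.
#' @param n_days Diet-assessment days `d` entering [s_factor()].
#' @param cv_w_b Denominator CV (%) used in both S modes; Black's literature
#'   value 8.5 by default.
#' @param s_modes,denominators,pal_variants Grid axes; defaults cover the
#'   full grid.
#' @param n_mode Participants entering [goldberg_bounds()]: `"n"` or
#'   `"n-1"`.
#' @param z Normal quantile for the bounds.
#' @return Tidy tibble with one row per grid cell: the axes, `s`, `pal_ref`,
#'   `lower`, `upper`, counts (`n_under`, `n_plausible`, `n_over`,
#'   `n_unclassifiable`) and a logical `best` marking, per tool, the cell
#'   with the most plausible reporters.
#' @export
classification_grid <- function(analysis, intake_daily = NULL, n_days = 7,
                                cv_w_b = 8.5,
                                s_modes = c("study", "black"),
                                denominators = c("abmr", "ree"),
                                pal_variants = c("pal_abmr", "pal_ree",
                                                 "pal_lifestyle"),
                                n_mode = c("n", "n-1"), z = 1.96) {
  n_mode <- match.arg(n_mode)
  tools <- sub("^tdei_", "", grep("^tdei_", names(analysis), value = TRUE))
  if (length(tools) == 0) abort("no `tdei_<tool>` columns in `analysis`")
  if (nrow(analysis) == 0) {
    return(tibble(tool = character(), denominator = character(),
                  pal_variant = character(), s_mode = character()))
  }
  grid <- tidyr::expand_grid(tool = tools, denominator = denominators,
                             pal_variant = pal_variants, s_mode = s_modes)
  rows <- purrr::pmap_dfr(grid, function(tool, denominator, pal_variant, s_mode) {
    denom <- switch(denominator, abmr = analysis$abmr,
                    ree = analysis$ree_kcal_day)
    pal <- analysis[[pal_variant]]
    if (all(is.na(pal)) || all(is.na(denom))) {
      inform(paste0("grid cell ", tool, "/", denominator, "/", pal_variant,
                    ": required column absent, cell skipped"))
      return(NULL)
    }
    if (s_mode == "study") {
      if (is.null(intake_daily)) return(NULL)
      cv_w <- cv_within_intake(
        intake_daily[intake_daily$tool == tool, , drop = FALSE])
      cv_p <- cv_percent(pal[!is.na(pal)])
      # single participant or single day: the component is inestimable
      if (!is.finite(cv_w)) { cv_w <- 0; inform("within-person intake CV inestimable; set to 0") }
      if (!is.finite(cv_p)) { cv_p <- 0; inform("between-person PAL CV inestimable; set to 0") }
      s <- s_factor(cv_w, cv_w_b, cv_p, n_days)
    } else {
      bd <- black_defaults()
      s <- s_factor(bd[["cv_w_tdei"]], cv_w_b, bd[["cv_t_p"]], n_days)
    }
    ok <- !is.na(pal) & !is.na(denom)
    n_eff <- sum(ok) - (n_mode == "n-1")
    pal_ref <- mean(pal[ok])
    b <- goldberg_bounds(pal_ref, s, max(n_eff, 1), z)
    ratio <- analysis[[paste0("tdei_", tool)]] / denom
    lab <- classify_goldberg(ifelse(ok, ratio, NA_real_), b)
    tibble(tool = tool, denominator = denominator,
           pal_variant = pal_variant, s_mode = s_mode,
           s = s, pal_ref = pal_ref, lower = b[["lower"]], upper = b[["upper"]],
           n_under = sum(lab == "under"),
           n_plausible = sum(lab == "plausible"),
           n_over = sum(lab == "over"),
           n_unclassifiable = sum(lab == "unclassifiable"))
  })
  dplyr::mutate(dplyr::group_by(rows, .data$tool),
                best = .data$n_plausible == max(.data$n_plausible)) |>
    dplyr::ungroup()
}
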