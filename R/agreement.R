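# Method-comparison statistics: Bland-Altman agreement with explicit divisor
# conventions, Pearson association with a signed R^2 variant, and paired
# testing gated on Shapiro-Wilk normality of the differences.

new_agreement_result <- function(bias, sd_bias, n, m, convention,
                                 loa_z, conf, unit = "kcal/day") {
  se_bias <- sd_bias / sqrt(m)
  se_loa <- sd_bias * sqrt(3 / m)
  df <- m - 1
  tcrit <- qt(1 - (1 - conf) / 2, df)
  structure(
    list(n = n, m = m, convention = convention, df = df,
         bias = bias, sd_bias = sd_bias,
         se_bias = se_bias,
         ci_bias = c(lower = bias - tcrit * se_bias,
                     upper = bias + tcrit * se_bias),
         loa = c(lower = bias - loa_z * sd_bias,
                 upper = bias + loa_z * sd_bias),
         se_loa = se_loa, loa_z = loa_z, conf = conf, unit = unit),
    class = "agreement_result"
  )
}

#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean of `a - b`, with `b` the reference method), its
#' standard deviation, standard errors, a t-based confidence interval for the
#' bias, and the 95% limits of agreement `bias +/- 1.96 * SD`. The divisor
#' `m` entering the standard errors (`se_bias = sd/sqrt(m)`,
#' `se_loa = sd*sqrt(3/m)`) and the t degrees of freedom (`m - 1`) is set by
#' `convention`: `"n"` uses the number of pairs, `"n-1"` uses one fewer —
#' both appear in the applied literature, so the choice is explicit and
#' carried in the result.
#'
#' @param a,b Paired measurements; `b` is the reference.
#' @param convention `"n"` (default) or `"n-1"`.
#' @param loa_z Multiplier for the limits of agreement; default 1.96.
#' @param conf Confidence level of the bias CI; default 0.95.
#' @param unit Unit label carried in the result.
#' @return An `agreement_result`: `bias`, `sd_bias`, `se_bias`, `ci_bias`,
#'   `loa`, `se_loa`, `n`, `m`, `df`.
#' @examples
#' bland_altman(c(9, 8, 7), c(10, 10, 10))
#' @export
bland_altman <- function(a, b, convention = c("n", "n-1"),
                         loa_z = 1.96, conf = 0.95, unit = "kcal/day") {
  convention <- match.arg(convention)
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  ok <- complete.cases(a, b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2) abort("need at least 2 complete pairs for an agreement analysis")
  m <- if (convention == "n") n else n - 1
  new_agreement_result(mean(d), stats::sd(d), n, m, convention, loa_z, conf,
                       unit)
}

#' Bland-Altman summaries from published bias and SD
#'
#' Reconstructs standard errors, bias CI and limits of agreement from the
#' summary numbers (bias, SD of differences, n) that method-comparison tables
#' print, under an explicit divisor convention.
#'
#' @param bias Mean difference.
#' @param sd_bias SD of the differences.
#' @param n Number of pairs.
#' @inheritParams bland_altman
#' @return An `agreement_result`.
#' @examples
#' ba_from_summary(-817.3, 1474.5, 20, convention = "n")
#' @export
ba_from_summary <- function(bias, sd_bias, n, convention = c("n", "n-1"),
                            loa_z = 1.96, conf = 0.95, unit = "kcal/day") {
  convention <- match.arg(convention)
  if (sd_bias < 0) abort("`sd_bias` must be >= 0")
  if (n < 2) abort("`n` must be >= 2")
  m <- if (convention == "n") n else n - 1
  new_agreement_result(bias, sd_bias, n, m, convention, loa_z, conf, unit)
}

#' Limits of agreement from bias and SD
#'
#' `bias +/- 1.96 * sd`, exactly.
#'
#' @param bias Mean difference.
#' @param sd SD of the differences, >= 0.
#' @param z Multiplier; default 1.96.
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' loa_from_summary(-1479.5, 635.5)
#' @export
loa_from_summary <- function(bias, sd, z = 1.96) {
  if (any(sd < 0)) abort("`sd` must be >= 0")
  c(lower = bias - z * sd, upper = bias + z * sd)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("Bland-Altman agreement (", x$unit, ", divisor convention ",
      x$convention, ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("  bias %8.1f  [%0.f%% CI %.1f, %.1f]  SD %.1f  SE %.1f\n",
              x$bias, 100 * x$conf, x$ci_bias[["lower"]],
              x$ci_bias[["upper"]], x$sd_bias, x$se_bias))
  cat(sprintf("  LoA  (%.1f, %.1f)  SE(LoA) %.1f\n",
              x$loa[["lower"]], x$loa[["upper"]], x$se_loa))
  invisible(x)
}

#' @export
as_tibble.agreement_result <- function(x, ...) {
  tibble(n = x$n, convention = x$convention,
         bias = x$bias, ci_bias_lower = x$ci_bias[["lower"]],
         ci_bias_upper = x$ci_bias[["upper"]],
         sd_bias = x$sd_bias, se_bias = x$se_bias,
         loa_lower = x$loa[["lower"]], loa_upper = x$loa[["upper"]],
         se_loa = x$se_loa)
}

#' Pearson association between two methods
#'
#' Product-moment correlation, its square, the p-value, and a signed
#' coefficient of determination `sign(r) * r^2` — useful in validity
#' scorecards where the direction of an (expected-positive) relationship is
#' itself informative.
#'
#' @param a,b Paired measurements, n >= 3.
#' @return A list: `r`, `r2`, `signed_r2`, `p`, `n`.
#' @export
pearson_assoc <- function(a, b) {
  ok <- complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) abort("need at least 3 complete pairs for a correlation")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warn("zero variance in one method; correlation undefined")
    return(list(r = NA_real_, r2 = NA_real_, signed_r2 = NA_real_,
                p = NA_real_, n = length(a)))
  }
  ct <- cor.test(a, b, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r2 = r^2, signed_r2 = sign(r) * r^2,
       p = ct$p.value, n = length(a))
}

#' Paired comparison with a normality gate and Bonferroni correction
#'
#' Shapiro-Wilk on the paired differences (at `alpha`) selects the test: a
#' paired t-test when normality is not rejected, a Wilcoxon signed-rank test
#' otherwise. The raw p-value is Bonferroni-adjusted for `bonferroni_k`
#' comparisons and capped at 1.
#'
#' @param a,b Paired measurements, n >= 3.
#' @param alpha Significance level of the Shapiro-Wilk gate.
#' @param bonferroni_k Size of the comparison family.
#' @return A list: `test` (`"paired t"` or `"wilcoxon"`), `statistic`,
#'   `p_raw`, `p_adjusted`, `shapiro_p`, `n`.
#' @export
paired_compare <- function(a, b, alpha = 0.05, bonferroni_k = 3) {
  ok <- complete.cases(a, b)
  d <- a[ok] - b[ok]
  if (length(d) < 3) abort("need at least 3 complete pairs")
  if (stats::sd(d) == 0) {
    warn("constant differences; paired test degenerate")
    return(list(test = "degenerate", statistic = NA_real_, p_raw = NA_real_,
                p_adjusted = NA_real_, shapiro_p = NA_real_, n = length(d)))
  }
  sw <- shapiro.test(d)
  if (sw$p.value >= alpha) {
    tt <- t.test(d)
    test <- "paired t"
  } else {
    tt <- suppressWarnings(wilcox.test(d, exact = FALSE))
    test <- "wilcoxon"
  }
  list(test = test, statistic = unname(tt$statistic),
       p_raw = tt$p.value,
       p_adjusted = min(1, bonferroni_k * tt$p.value),
       shapiro_p = sw$p.value, n = length(d))
}
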