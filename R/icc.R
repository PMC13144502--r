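# Two-way random-effects intraclass correlation, single measure, absolute
# agreement — ICC(2,1) in the Shrout-Fleiss taxonomy. Used here for the
# day-to-day stability of reported intake (participants x days).

#' Two-way random-effects ICC (single measure, absolute agreement)
#'
#' Computes ICC(2,1) from the two-way ANOVA mean squares of a complete
#' participants-by-occasions matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, where MSR, MSC and
#' MSE are the row (participant), column (occasion) and residual mean
#' squares. The confidence interval is the F-based interval with a
#' Satterthwaite-approximated denominator degrees of freedom.
#'
#' @param mat Numeric matrix, participants in rows, occasions (e.g. days) in
#'   columns. Rows containing missing values are dropped with a message.
#' @param conf Confidence level; default 0.95.
#' @return A list of class `icc_result`: `icc`, `ci` (lower, upper),
#'   `model` label, `n`, `k`, variance components (`var_between`,
#'   `var_occasion`, `var_residual`), mean squares, and the F test of the
#'   participant effect (`f`, `p`).
#' @examples
#' m <- outer(1:6, rep(1, 3)) + matrix(rnorm(18, sd = .2), 6)
#' icc_two_way_random(m)$icc
#' @export
icc_two_way_random <- function(mat, conf = 0.95) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) abort("need at least 2 occasions (columns)")
  keep <- complete.cases(mat)
  if (!all(keep)) {
    inform(paste("dropping", sum(!keep), "row(s) with missing occasions"))
    mat <- mat[keep, , drop = FALSE]
  }
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2) abort("need at least 2 complete participants (rows)")

  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-based CI (Shrout & Fleiss 1979, eq. for ICC(2,1))
  alpha <- 1 - conf
  fj <- msc / mse
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  f_stat <- msr / mse
  p <- pf(f_stat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  structure(
    list(icc = icc, ci = c(lower = lower, upper = upper),
         model = "two-way random effects, single measure, absolute agreement (ICC(2,1))",
         n = n, k = k,
         var_between = (msr - mse) / k,
         var_occasion = (msc - mse) / n,
         var_residual = mse,
         ms = c(rows = msr, cols = msc, error = mse),
         f = f_stat, p = p, conf = conf),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat("ICC(2,1):", sprintf("%.3f", x$icc),
      sprintf("[%0.f%% CI %.3f, %.3f]", 100 * x$conf,
              x$ci[["lower"]], x$ci[["upper"]]), "\n")
  cat(" ", x$model, "\n")
  cat("  n =", x$n, "participants x", x$k, "occasions;",
      sprintf("F = %.2f, p = %.3g", x$f, x$p), "\n")
  invisible(x)
}
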