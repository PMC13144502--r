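#' Bland-Altman plot
#'
#' Differences against means with the bias (dashed blue) and 95% limits of
#' agreement (dashed brown) drawn as horizontal lines.
#'
#' @param a,b Paired measurements; `b` is the reference.
#' @param convention Divisor convention, see [bland_altman()].
#' @param unit Axis unit label.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(a, b, convention = "n", unit = "kcal/day") {
  ba <- bland_altman(a, b, convention = convention, unit = unit)
  df <- tibble(mean = (a + b) / 2, diff = a - b)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = ba$loa, linetype = "dashed",
                        colour = "tan4") +
    ggplot2::labs(x = paste0("Mean of methods (", unit, ")"),
                  y = paste0("Difference (", unit, ")"),
                  title = sprintf("Bias %.1f, LoA (%.1f, %.1f)",
                                  ba$bias, ba$loa[["lower"]],
                                  ba$loa[["upper"]])) +
    ggplot2::theme_minimal()
}
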