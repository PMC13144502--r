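#' Convert between kcal and kJ
#'
#' Exact conversion by the thermochemical factor 4.184 kJ/kcal.
#'
#' @param x Numeric vector of energies.
#' @param to Target unit, `"kJ"` or `"kcal"`.
#' @return Numeric vector in the target unit.
#' @examples
#' kcal_kj(3004.2, "kJ")
#' kcal_kj(kcal_kj(100, "kJ"), "kcal") # identity
#' @export
kcal_kj <- function(x, to = c("kJ", "kcal")) {
  to <- match.arg(to)
  stopifnot(is.numeric(x))
  if (to == "kJ") x * KCAL_TO_KJ else x / KCAL_TO_KJ
}

# draw from a normal truncated to [lower, upper]; sd = 0 degenerates to mean
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) abort("sd must be >= 0")
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    guard <- guard + 1L
    if (guard > 10000L) abort("truncated-normal rejection sampling failed to converge")
  }
  out
}

# lognormal multiplicative factor with mean 1 and coefficient of variation cv (%)
rlnorm_cv <- function(n, cv_percent) {
  if (cv_percent < 0) abort("coefficient of variation must be >= 0")
  if (cv_percent == 0) return(rep(1, n))
  sdlog <- sqrt(log1p((cv_percent / 100)^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# coefficient of variation in percent
cv_percent <- function(x) 100 * stats::sd(x) / mean(x)

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", name, "` must be finite and > 0"))
  }
  invisible(x)
}
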