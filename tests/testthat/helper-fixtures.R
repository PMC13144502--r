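# Shared fixture builders for the suite. Everything is generated in code.

# small noise-free simulated cohort, cached per (n, seed)
noise_free_sim <- local({
  cache <- list()
  function(n = 5, seed = 3) {
    key <- paste(n, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_cohort(
        cohort_params(n = n, seed = seed, isotope_noise_sd = 0))
    }
    cache[[key]]
  }
})

# participants-by-occasions matrix with a target intraclass correlation,
# built from independent between- and within-person normal components
icc_matrix <- function(n, k, rho, seed) {
  set.seed(seed)
  vb <- rho
  ve <- 1 - rho
  b <- if (vb > 0) rnorm(n, 0, sqrt(vb)) else numeric(n)
  e <- if (ve > 0) matrix(rnorm(n * k, 0, sqrt(ve)), n, k) else matrix(0, n, k)
  10 + outer(b, rep(1, k)) + e
}

# brute-force ICC(2,1) oracle: mean squares straight from aov(), plugged into
# the variance-component definition of absolute agreement
icc_oracle_aov <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(seq_len(n), k)),
                   occ = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + occ, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
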