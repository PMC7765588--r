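# shared fixtures: small cohort configurations built in code

# compact cohort for fast structural tests
small_config <- function(...) {
  cohort_config(n_families = 25, n_controls = 20, ...)
}

# all-paths-zero configuration on a reduced four-marker panel, used for
# null-model and calibration checks
null_config <- function(n_families = 100, n_controls = 79,
                        markers = dd_marker_panel()[c(4, 7, 6, 2), ],
                        ...) {
  p <- nrow(markers)
  cohort_config(
    n_families = n_families, n_controls = n_controls, markers = markers,
    A = matrix(0, 5, p), B = rep(0, 5), Cp = rep(0, p),
    age_paths = rep(0, 5), ...
  )
}

# independent brute-force HWE chi-square: expected counts written out
# longhand from the allele frequency
hwe_chi2_brute <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  e <- c(n * p * p, n * 2 * p * q, n * q * q)
  o <- c(n_aa, n_ab, n_bb)
  sum((o - e)^2 / e)
}

# brute-force Pearson correlation from the covariance formula
pearson_brute <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}
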