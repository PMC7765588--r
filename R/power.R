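# Post-hoc power: RMSEA-based model-fit power via the noncentral chi-square,
# and joint-significance power for specific indirect effects.

#' Post-hoc power of the RMSEA test of model fit
#'
#' Power of the likelihood-ratio test of exact (or close) fit using the
#' noncentral chi-square approximation: the noncentrality induced by a
#' population RMSEA `epsilon` is `lambda = (n - 1) df epsilon^2`; the
#' critical value is the upper-`alpha` quantile of the noncentral chi-square
#' under the null RMSEA, and power is the exceedance probability under the
#' alternative RMSEA.
#'
#' The default null is exact fit (`rmsea0 = 0`); a close-fit null (e.g.
#' `rmsea0 = 0.05`) is available through the parameter.
#'
#' @param df Model degrees of freedom (>= 1).
#' @param n Sample size (> 1).
#' @param rmsea Alternative (population) RMSEA, > `rmsea0`.
#' @param rmsea0 Null RMSEA (default 0 = exact fit).
#' @param alpha Test size (default 0.05).
#' @return Object of class `power_result`: `power`, `alpha`, `lambda`
#'   (alternative noncentrality) and the echoed inputs.
#' @examples
#' rmsea_power(df = 8, n = 302, rmsea = 0.087)  # about 0.88
#' @export
rmsea_power <- function(df, n, rmsea, rmsea0 = 0, alpha = 0.05) {
  stopifnot(df >= 1, n > 1, rmsea >= rmsea0, rmsea0 >= 0,
            alpha > 0, alpha < 1)
  lam0 <- (n - 1) * df * rmsea0^2
  lam_a <- (n - 1) * df * rmsea^2
  crit <- stats::qchisq(1 - alpha, df, ncp = lam0)
  power <- stats::pchisq(crit, df, ncp = lam_a, lower.tail = FALSE)
  structure(list(power = power, alpha = alpha, lambda = lam_a,
                 inputs = list(df = df, n = n, rmsea = rmsea,
                               rmsea0 = rmsea0)),
            class = "power_result")
}

#' Joint-significance power for a specific indirect effect
#'
#' Power of the test of the indirect effect `a * b` by the
#' joint-significance rule: the effect is declared present when both the
#' gene-to-mediator path `a` and the mediator-to-outcome path `b` are
#' individually significant at two-sided level `alpha`. With standardized
#' paths, the large-sample standard errors are
#' `SE(a) = sqrt((1 - a^2) / (n - 2))` and
#' `SE(b) = sqrt((1 - R2_Y) / ((n - 3)(1 - a^2)))` where
#' `R2_Y = b^2 + c'^2 + 2 a b c'`, and the power is the product of the two
#' normal rejection probabilities
#' `pnorm(|a|/SE(a) - z) * pnorm(|b|/SE(b) - z)` with `z` the two-sided
#' critical value.
#'
#' A Monte-Carlo mode (`n_sim > 0`) simulates the trivariate system and
#' counts joint rejections, for verification of the analytic approximation.
#'
#' @param a Standardized predictor-to-mediator path (|a| < 1).
#' @param b Standardized mediator-to-outcome path (|b| < 1).
#' @param c_prime Standardized direct path (default 0).
#' @param n Sample size.
#' @param alpha Two-sided test size (default 0.05).
#' @param n_sim If > 0, also return a Monte-Carlo power estimate over
#'   `n_sim` simulated datasets.
#' @param seed Seed for the Monte-Carlo mode.
#' @return Object of class `power_result` with `power`, `power_a`,
#'   `power_b`, the standard errors, optional `power_mc`, and the inputs.
#' @examples
#' mediation_power_joint(a = -0.188, b = 0.298, c_prime = -0.111, n = 302)
#' @export
mediation_power_joint <- function(a, b, c_prime = 0, n, alpha = 0.05,
                                  n_sim = 0, seed = 1L) {
  stopifnot(abs(a) < 1, abs(b) < 1, abs(c_prime) < 1, n > 3)
  r2_y <- b^2 + c_prime^2 + 2 * a * b * c_prime
  # implied correlation matrix of (X, M, Y) must be admissible
  r_xm <- a
  r_xy <- c_prime + a * b
  r_my <- b + a * c_prime
  R <- matrix(c(1, r_xm, r_xy, r_xm, 1, r_my, r_xy, r_my, 1), 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("paths imply a non-positive-semi-definite correlation matrix")
  if (r2_y >= 1) stop("paths imply outcome R-squared >= 1")

  se_a <- sqrt((1 - a^2) / (n - 2))
  se_b <- sqrt((1 - r2_y) / ((n - 3) * (1 - a^2)))
  z <- stats::qnorm(1 - alpha / 2)
  power_a <- stats::pnorm(abs(a) / se_a - z)
  power_b <- stats::pnorm(abs(b) / se_b - z)
  out <- structure(list(power = power_a * power_b,
                        power_a = power_a, power_b = power_b,
                        se_a = se_a, se_b = se_b, alpha = alpha,
                        inputs = list(a = a, b = b, c_prime = c_prime,
                                      n = n)),
                   class = "power_result")
  if (n_sim > 0) {
    set.seed(as.integer(seed))
    rej <- logical(n_sim)
    sd_m <- sqrt(1 - a^2)
    sd_y <- sqrt(max(1 - r2_y, 1e-12))
    for (i in seq_len(n_sim)) {
      x <- stats::rnorm(n)
      m <- a * x + stats::rnorm(n, sd = sd_m)
      y <- c_prime * x + b * m + stats::rnorm(n, sd = sd_y)
      fa <- stats::summary.lm(stats::lm(m ~ x))$coefficients
      fb <- stats::summary.lm(stats::lm(y ~ x + m))$coefficients
      rej[i] <- fa["x", 4] < alpha && fb["m", 4] < alpha
    }
    out$power_mc <- mean(rej)
    out$n_sim <- n_sim
  }
  out
}

#' @export
#' @method print power_result
print.power_result <- function(x, ...) {
  cat(sprintf("Post-hoc power = %.4f (alpha = %.3g)\n", x$power, x$alpha))
  if (!is.null(x$power_a))
    cat(sprintf("  path tests: power(a) = %.4f, power(b) = %.4f\n",
                x$power_a, x$power_b))
  if (!is.null(x$lambda))
    cat(sprintf("  noncentrality lambda = %.3f\n", x$lambda))
  if (!is.null(x$power_mc))
    cat(sprintf("  Monte-Carlo check: %.4f (%d simulations)\n",
                x$power_mc, x$n_sim))
  cat("  inputs:", paste(names(x$inputs), unlist(x$inputs), sep = " = ",
                         collapse = ", "), "\n")
  invisible(x)
}
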