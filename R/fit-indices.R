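# Model-implied covariance, maximum-likelihood discrepancy and the standard
# SEM fit indices (chi-square, RMSEA with CI, CFI, SRMR).

#' Model-implied covariance matrix of a fitted path model
#'
#' Propagates the fitted standardized path coefficients, residual variances
#' and free residual covariances through the recursive system to the implied
#' covariance of all observed variables (predictors and age form a free
#' exogenous block whose covariance is taken from the sample).
#'
#' @param object A fitted [path_mediation()] model.
#' @return Symmetric covariance matrix over (predictors, covariate,
#'   mediators, outcome) on the standardized scale, with an error if the
#'   result is not positive semi-definite.
#' @export
model_implied_covariance <- function(object) {
  stopifnot(inherits(object, "path_mediation"))
  meta <- object$meta
  est <- object$estimates
  Z <- standardize(object$data)
  exog <- c(meta$predictors, meta$covariate)
  S <- stats::cov(as.matrix(Z))
  S_zz <- S[exog, exog, drop = FALSE]

  # Gamma: mediators x exogenous (age path 0 where the edge is absent)
  Gamma <- cbind(est$a,
                 if (!is.null(meta$covariate))
                   matrix(ifelse(is.na(est$age), 0, est$age), ncol = 1,
                          dimnames = list(meta$mediators, meta$covariate)))
  Gamma <- Gamma[, exog, drop = FALSE]

  # mediator residual covariance: diagonal + declared free pairs
  Psi <- diag(est$resid_var[meta$mediators],
              nrow = length(meta$mediators))
  dimnames(Psi) <- list(meta$mediators, meta$mediators)
  for (pr in meta$residual_pairs) {
    v <- est$resid_cov[[paste(pr, collapse = "~~")]]
    Psi[pr[1], pr[2]] <- v
    Psi[pr[2], pr[1]] <- v
  }

  w <- stats::setNames(numeric(length(exog)), exog)
  w[meta$predictors] <- est$cp
  w <- w + drop(est$b %*% Gamma)   # reduced-form outcome loadings on exog
  psi_y <- est$resid_var[[meta$outcome]]

  Sigma_mz <- Gamma %*% S_zz
  Sigma_mm <- Gamma %*% S_zz %*% t(Gamma) + Psi
  Sigma_yz <- drop(w %*% S_zz)
  Sigma_ym <- drop(w %*% S_zz %*% t(Gamma) + est$b %*% Psi)
  Sigma_yy <- drop(w %*% S_zz %*% w) + drop(est$b %*% Psi %*% est$b) + psi_y

  vars <- c(exog, meta$mediators, meta$outcome)
  Sigma <- matrix(0, length(vars), length(vars),
                  dimnames = list(vars, vars))
  Sigma[exog, exog] <- S_zz
  Sigma[meta$mediators, exog] <- Sigma_mz
  Sigma[exog, meta$mediators] <- t(Sigma_mz)
  Sigma[meta$mediators, meta$mediators] <- Sigma_mm
  Sigma[meta$outcome, exog] <- Sigma_yz
  Sigma[exog, meta$outcome] <- Sigma_yz
  Sigma[meta$outcome, meta$mediators] <- Sigma_ym
  Sigma[meta$mediators, meta$outcome] <- Sigma_ym
  Sigma[meta$outcome, meta$outcome] <- Sigma_yy
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied covariance is not positive semi-definite (smallest ",
         "eigenvalue ", format(min(ev)), ")")
  Sigma
}

# degrees of freedom of the path model: observed moments minus free
# parameters (free exogenous block, a-paths, age edges, c', b, mediator and
# outcome residual variances, declared residual covariances)
.model_df <- function(meta) {
  p <- length(meta$predictors)
  q <- p + length(meta$covariate)
  nm <- length(meta$mediators)
  P <- q + nm + 1
  n_age <- if (is.null(meta$covariate)) 0 else
    length(intersect(meta$covariate_on, meta$mediators))
  free <- q * (q + 1) / 2 + nm * p + n_age + p + nm + nm +
    length(meta$residual_pairs) + 1
  P * (P + 1) / 2 - free
}

#' SEM fit indices from sample and implied covariance matrices
#'
#' Computes the maximum-likelihood discrepancy
#' `F = ln|Sigma| - ln|S| + tr(S Sigma^-1) - p`, the chi-square statistic
#' `(n - 1) F` with its p-value, RMSEA with a 90% confidence interval from
#' noncentral chi-square inversion, CFI against the independence baseline
#' (free variances), and SRMR over the standardized residual covariances
#' (diagonal included by default; a no-diagonal variant is selectable).
#'
#' @param sample_cov Sample covariance matrix `S` (positive definite).
#' @param implied_cov Model-implied covariance `Sigma`, same dimension.
#' @param n Sample size.
#' @param df Model degrees of freedom.
#' @param ci_level Level of the RMSEA interval (default 0.90).
#' @param srmr_diagonal Include the variance residuals in SRMR
#'   (default `TRUE`).
#' @param n_convention `"n-1"` (default) or `"n"`: the multiplier turning
#'   the discrepancy into the chi-square statistic and the RMSEA scaling.
#' @return Object of class `sem_fit`: list with `chi2`, `df`, `p`, `rmsea`,
#'   `rmsea_ci`, `cfi`, `srmr`, `fml`, `n`.
#' @examples
#' S <- matrix(c(1, .5, .5, 1), 2)
#' fit_indices(S, diag(2), n = 101, df = 1)  # chi2 = -100 * log(0.75)
#' @export
fit_indices <- function(sample_cov, implied_cov, n, df,
                        ci_level = 0.90, srmr_diagonal = TRUE,
                        n_convention = c("n-1", "n")) {
  n_convention <- match.arg(n_convention)
  S <- as.matrix(sample_cov); Sigma <- as.matrix(implied_cov)
  stopifnot(all(dim(S) == dim(Sigma)))
  p <- ncol(S)
  ldS <- determinant(S, logarithm = TRUE)
  if (ldS$sign <= 0) stop("sample covariance must be positive definite")
  ldSig <- determinant(Sigma, logarithm = TRUE)
  if (ldSig$sign <= 0) stop("implied covariance is singular")
  fml <- as.numeric(ldSig$modulus - ldS$modulus) +
    sum(diag(S %*% solve(Sigma))) - p
  fml <- max(fml, 0)
  N <- if (n_convention == "n-1") n - 1 else n
  chi2 <- N * fml
  if (df > 0) {
    pval <- stats::pchisq(chi2, df, lower.tail = FALSE)
    rmsea <- sqrt(max(chi2 - df, 0) / (df * N))
    rmsea_ci <- .rmsea_ci(chi2, df, N, ci_level)
  } else {
    # saturated model: the fit test is vacuous
    pval <- NA_real_
    rmsea <- 0
    rmsea_ci <- c(lower = 0, upper = 0)
  }

  # independence baseline: free variances, zero covariances
  fml_b <- sum(log(diag(S))) - as.numeric(ldS$modulus)
  chi2_b <- N * fml_b
  df_b <- p * (p - 1) / 2
  denom <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2 - df, 0) / denom

  d <- sqrt(diag(S))
  res <- (S - Sigma) / tcrossprod(d)
  mask <- if (srmr_diagonal) lower.tri(res, diag = TRUE) else lower.tri(res)
  srmr <- sqrt(mean(res[mask]^2))

  structure(list(chi2 = chi2, df = df, p = pval,
                 rmsea = rmsea, rmsea_ci = rmsea_ci,
                 cfi = cfi, srmr = srmr, fml = fml, n = n),
            class = "sem_fit")
}

# RMSEA confidence interval via inversion of the noncentral chi-square
.rmsea_ci <- function(chi2, df, N, level = 0.90) {
  alpha <- (1 - level) / 2
  up <- function(lam) stats::pchisq(chi2, df, ncp = lam)
  lam_max <- max(chi2 * 5, 100)
  lo <- if (up(0) < 1 - alpha) 0 else
    stats::uniroot(function(l) up(l) - (1 - alpha), c(0, lam_max))$root
  hi <- if (up(0) < alpha) 0 else if (up(lam_max) > alpha) lam_max else
    stats::uniroot(function(l) up(l) - alpha, c(0, lam_max))$root
  sqrt(c(lower = lo, upper = hi) / (df * N))
}

#' @export
#' @method print sem_fit
print.sem_fit <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, p = %.3g\n", x$df, x$chi2, x$p))
  cat(sprintf("RMSEA = %.3f (90%% CI %.3f-%.3f), CFI = %.3f, SRMR = %.3f\n",
              x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2], x$cfi, x$srmr))
  invisible(x)
}

#' Goodness of fit of a fitted path model
#'
#' Convenience wrapper: sample covariance of the standardized analysis
#' variables, [model_implied_covariance()], the model's own degrees of
#' freedom, and [fit_indices()].
#'
#' @param object A fitted [path_mediation()] model.
#' @param ... Passed to [fit_indices()].
#' @return A `sem_fit` object.
#' @export
model_fit <- function(object, ...) {
  stopifnot(inherits(object, "path_mediation"))
  Z <- standardize(object$data)
  S <- stats::cov(as.matrix(Z))
  vars <- c(object$meta$predictors, object$meta$covariate,
            object$meta$mediators, object$meta$outcome)
  fit_indices(S[vars, vars], model_implied_covariance(object),
              n = object$n, df = .model_df(object$meta), ...)
}
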