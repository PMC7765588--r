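# The multiple-predictor/multiple-mediator path model: standardization,
# equation-wise least-squares estimation, and indirect-effect arithmetic.

#' Standardize analysis columns
#'
#' Centers every numeric column to mean 0 and scales it to unit SD,
#' recording the constants in attributes `"center"` and `"scale"` for exact
#' back-transformation. Zero-variance columns raise an error naming the
#' column.
#'
#' @param data data.frame or matrix of numeric columns.
#' @return Standardized object of the same shape with `"center"`/`"scale"`
#'   attributes.
#' @export
standardize <- function(data) {
  x <- as.matrix(data)
  ctr <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  bad <- !is.finite(sc) | sc <= 0
  if (any(bad))
    stop("zero-variance column(s): ", paste(colnames(x)[bad], collapse = ", "))
  z <- sweep(sweep(x, 2, ctr), 2, sc, "/")
  if (is.data.frame(data)) z <- as.data.frame(z)
  attr(z, "center") <- ctr
  attr(z, "scale") <- sc
  z
}

#' Undo a standardization
#'
#' @param z Output of [standardize()].
#' @return Matrix/data.frame on the original scale.
#' @export
unstandardize <- function(z) {
  ctr <- attr(z, "center"); sc <- attr(z, "scale")
  stopifnot(!is.null(ctr), !is.null(sc))
  x <- sweep(sweep(as.matrix(z), 2, sc, "*"), 2, ctr, "+")
  if (is.data.frame(z)) x <- as.data.frame(x)
  x
}

# Equation-wise least squares on a standardized matrix Z. For this recursive
# observed-variable system the OLS point estimates coincide with the ML path
# estimates, which keeps the bootstrap loop fast and transparent.
# meta: list(predictors, covariate (or NULL), covariate_on, mediators,
#            outcome, residual_pairs)
.fit_path_core <- function(Z, meta) {
  n <- nrow(Z)
  p <- length(meta$predictors)
  P <- Z[, meta$predictors, drop = FALSE]
  M <- Z[, meta$mediators, drop = FALSE]
  y <- Z[, meta$outcome]
  has_cov <- !is.null(meta$covariate)

  .solve_eq <- function(X, Y, label) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop("rank-deficient design in ", label, " equation(s); collinear: ",
           paste(bad, collapse = ", "))
    }
    cf <- qr.coef(qx, Y)
    res <- Y - X %*% cf
    list(coef = cf, resid = res)
  }

  # mediator equations: all predictors, plus age where the covariate applies
  a <- matrix(0, length(meta$mediators), p,
              dimnames = list(meta$mediators, meta$predictors))
  age_coef <- stats::setNames(rep(NA_real_, length(meta$mediators)),
                              meta$mediators)
  E_M <- matrix(0, n, length(meta$mediators),
                dimnames = list(NULL, meta$mediators))
  with_cov <- if (has_cov) intersect(meta$mediators, meta$covariate_on)
              else character(0)
  without_cov <- setdiff(meta$mediators, with_cov)
  if (length(with_cov)) {
    X1 <- cbind(`(Intercept)` = 1, P, Z[, meta$covariate, drop = FALSE])
    f1 <- .solve_eq(X1, M[, with_cov, drop = FALSE], "mediator")
    a[with_cov, ] <- t(f1$coef[meta$predictors, , drop = FALSE])
    age_coef[with_cov] <- f1$coef[meta$covariate, ]
    E_M[, with_cov] <- f1$resid
  }
  if (length(without_cov)) {
    X0 <- cbind(`(Intercept)` = 1, P)
    f0 <- .solve_eq(X0, M[, without_cov, drop = FALSE], "mediator")
    a[without_cov, ] <- t(f0$coef[meta$predictors, , drop = FALSE])
    E_M[, without_cov] <- f0$resid
  }

  # outcome equation: all predictors and all mediators
  XY <- cbind(`(Intercept)` = 1, P, M)
  fy <- .solve_eq(XY, y, "outcome")
  cp <- fy$coef[meta$predictors]
  b <- fy$coef[meta$mediators]
  e_y <- drop(fy$resid)

  resid_var <- c(colSums(E_M^2), sum(e_y^2)) / (n - 1)
  names(resid_var) <- c(meta$mediators, meta$outcome)
  resid_cov <- vapply(meta$residual_pairs, function(pr)
    sum(E_M[, pr[1]] * E_M[, pr[2]]) / (n - 1), numeric(1))
  names(resid_cov) <- vapply(meta$residual_pairs, paste, character(1),
                             collapse = "~~")
  r2 <- 1 - resid_var[[meta$outcome]] / stats::var(y)

  list(a = a, age = age_coef, b = b, cp = cp,
       resid_var = resid_var, resid_cov = resid_cov,
       R2 = unname(r2), residuals = cbind(E_M, outcome = e_y))
}

#' Specific, total and total indirect+direct effects
#'
#' Product-of-coefficients decomposition: the specific indirect effect of
#' predictor k through mediator j is `a[j,k] * b[j]`; the total indirect
#' effect of predictor k is the sum over mediators; the total effect adds
#' the direct path `c'`. The additivity identity `total = sum(specific)`
#' holds exactly.
#'
#' @param est A `path_mediation` fit or the estimate list it contains
#'   (fields `a`, `b`, `cp`).
#' @return List with `specific` (mediators x predictors), `total` and
#'   `total_effect` (per predictor).
#' @export
indirect_effects <- function(est) {
  if (inherits(est, "path_mediation")) est <- est$estimates
  specific <- est$a * est$b  # row j scaled by b_j
  total <- colSums(specific)
  list(specific = specific, total = total,
       total_effect = est$cp + total)
}

#' Fit the gene-endophenotype-reading path model
#'
#' Estimates the multiple-predictor/multiple-mediator path model: every
#' mediator (endophenotype) is regressed on all coded genotype predictors
#' (plus age, for the mediators listed in `covariate_on`), and the reading
#' outcome is regressed on all predictors and all mediators. All variables
#' are standardized first, so coefficients are standardized paths. Residual
#' covariances among the mediator pairs in `residual_pairs` are estimated
#' from the equation residuals. For this recursive observed-variable system
#' the equation-wise least-squares estimates coincide with the ML point
#' estimates.
#'
#' Specific and total indirect effects are computed by the
#' product-of-coefficients rule; with `n_boot > 0` a family-clustered
#' bias-corrected percentile bootstrap ([cluster_bootstrap()]) provides
#' confidence intervals (clusters = families; unrelated controls are
#' singleton clusters).
#'
#' Rows with a missing value in any used column are dropped listwise, with
#' a message giving the count.
#'
#' @param data data.frame with predictors, mediators, outcome, the age
#'   covariate and the family cluster id (see [mediation_data()]).
#' @param predictors Character vector of predictor column names; by default
#'   every column not otherwise used.
#' @param mediators Mediator column names (default [ep_names()]).
#' @param outcome Outcome column name (default `"reading"`).
#' @param covariate Age covariate column (`NULL` for none).
#' @param covariate_on Mediators receiving the age path.
#' @param residual_pairs Mediator pairs with free residual covariance.
#' @param cluster Family id column for the cluster bootstrap.
#' @param n_boot Bootstrap replicates (0 = no bootstrap; the reference
#'   analysis uses 5000).
#' @param ci_level Confidence level for bootstrap intervals.
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `path_mediation` with components `estimates`
#'   (standardized paths `a`, `b`, `cp`, age coefficients, residual
#'   variances/covariances, outcome R-squared), `indirect`
#'   (see [indirect_effects()]), `boot` (see [cluster_bootstrap()]; `NULL`
#'   if not requested), `n`, `n_dropped`, and the model frame/metadata used
#'   by the methods.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_families = 40, n_controls = 30), seed = 1)
#' fit <- path_mediation(mediation_data(cohort), n_boot = 199, seed = 1)
#' summary(fit)
#' @export
path_mediation <- function(data,
                           predictors = NULL,
                           mediators = ep_names(),
                           outcome = "reading",
                           covariate = "age",
                           covariate_on = c("RTLI_b", "RAP", "RAN_rt"),
                           residual_pairs = default_residual_pairs(),
                           cluster = "family_id",
                           n_boot = 0,
                           ci_level = 0.95,
                           seed = 1L) {
  data <- as.data.frame(data)
  reserved <- c("subject_id", mediators, outcome, covariate, cluster)
  if (is.null(predictors))
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          reserved)
  if (!is.null(covariate) && !covariate %in% names(data)) covariate <- NULL
  stopifnot(length(predictors) > 0,
            all(c(predictors, mediators, outcome) %in% names(data)))
  if (length(miss <- setdiff(unlist(residual_pairs), mediators)))
    stop("residual_pairs mention non-mediators: ",
         paste(miss, collapse = ", "))
  if (any(mediators %in% predictors))
    stop("mediators cannot also be predictors")

  used <- c(predictors, covariate, mediators, outcome)
  ok <- stats::complete.cases(data[, used, drop = FALSE])
  if (any(!ok))
    message(sum(!ok), " of ", length(ok),
            " subjects dropped listwise for missing data")
  dat <- data[ok, , drop = FALSE]
  n <- nrow(dat)
  if (n <= length(predictors) + length(mediators) + 2)
    stop("too few complete cases (", n, ") for the number of coefficients")

  clusters <- if (cluster %in% names(dat)) as.character(dat[[cluster]])
  else {
    message("no `", cluster, "` column: treating subjects as independent ",
            "singleton clusters")
    as.character(seq_len(n))
  }

  X <- as.matrix(dat[, used, drop = FALSE])
  Z <- standardize(X)
  meta <- list(predictors = predictors, covariate = covariate,
               covariate_on = covariate_on, mediators = mediators,
               outcome = outcome, residual_pairs = residual_pairs)
  est <- .fit_path_core(Z, meta)

  obj <- structure(list(
    call = match.call(),
    estimates = est,
    indirect = indirect_effects(est),
    meta = meta,
    data = X,
    scales = list(center = attr(Z, "center"), scale = attr(Z, "scale")),
    clusters = clusters,
    n = n,
    n_dropped = sum(!ok),
    ci_level = ci_level,
    boot = NULL
  ), class = "path_mediation")

  if (n_boot > 0)
    obj$boot <- cluster_bootstrap(obj, n_boot = n_boot,
                                  ci_level = ci_level, seed = seed)
  obj
}
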