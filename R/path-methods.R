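# S3 methods for fitted path_mediation models.

#' @export
#' @method print path_mediation
print.path_mediation <- function(x, ...) {
  cat("Multiple-predictor/multiple-mediator path model\n")
  cat("  n =", x$n, "complete subjects",
      if (x$n_dropped) paste0("(", x$n_dropped, " dropped)"), "\n")
  cat("  predictors:", length(x$meta$predictors),
      " mediators:", length(x$meta$mediators),
      " clusters:", length(unique(x$clusters)), "\n")
  cat(sprintf("  outcome R-squared: %.3f\n", x$estimates$R2))
  if (!is.null(x$boot)) {
    sig <- x$boot[x$boot$significant & x$boot$type == "total", ]
    cat("  significant total indirect effects (bootstrap ",
        round(100 * attr(x$boot, "ci_level")), "% CI): ",
        if (nrow(sig)) paste(sig$predictor, collapse = ", ") else "none",
        "\n", sep = "")
  }
  cat("Use summary() for paths, indirect effects and fit indices.\n")
  invisible(x)
}

#' @export
coef.path_mediation <- function(object, ...) {
  est <- object$estimates
  a <- est$a
  nm <- c(as.vector(outer(rownames(a), colnames(a),
                          function(m, p) paste0(m, "~", p))),
          paste0(object$meta$outcome, "~", names(est$b)),
          paste0(object$meta$outcome, "~", names(est$cp)))
  stats::setNames(c(as.vector(a), est$b, est$cp), nm)
}

#' @export
residuals.path_mediation <- function(object, ...) {
  object$estimates$residuals
}

#' Predicted reading outcome
#'
#' Evaluates the fitted outcome equation (direct genotype paths plus
#' mediator paths) on new standardized data and returns predictions on the
#' original outcome scale.
#'
#' @param object A fitted [path_mediation()] model.
#' @param newdata Optional data.frame with the predictor and mediator
#'   columns; defaults to the estimation data.
#' @param ... Unused.
#' @return Numeric vector of predicted outcome values.
#' @export
predict.path_mediation <- function(object, newdata = NULL, ...) {
  meta <- object$meta
  cols <- c(meta$predictors, meta$mediators)
  X <- if (is.null(newdata)) object$data[, cols, drop = FALSE] else {
    stopifnot(all(cols %in% names(newdata)))
    as.matrix(newdata[, cols, drop = FALSE])
  }
  ctr <- object$scales$center[cols]
  sc <- object$scales$scale[cols]
  Z <- sweep(sweep(X, 2, ctr), 2, sc, "/")
  yz <- drop(Z %*% c(object$estimates$cp, object$estimates$b))
  yz * object$scales$scale[[meta$outcome]] +
    object$scales$center[[meta$outcome]]
}

#' Simulate data from a fitted path model
#'
#' Parametric simulation: exogenous rows (coded genotypes and age) are
#' resampled from the estimation data, mediators and outcome are drawn from
#' the fitted linear-Gaussian system with the estimated residual variances
#' and declared residual covariances. Useful for parametric-bootstrap style
#' checks of downstream statistics.
#'
#' @param object A fitted [path_mediation()] model.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` data.frames on the standardized scale.
#' @export
simulate.path_mediation <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  meta <- object$meta
  est <- object$estimates
  Z <- standardize(object$data)
  exog <- c(meta$predictors, meta$covariate)
  n <- object$n
  Gamma <- cbind(est$a,
                 if (!is.null(meta$covariate))
                   matrix(ifelse(is.na(est$age), 0, est$age), ncol = 1,
                          dimnames = list(meta$mediators, meta$covariate)))
  Psi <- diag(est$resid_var[meta$mediators],
              nrow = length(meta$mediators))
  dimnames(Psi) <- list(meta$mediators, meta$mediators)
  for (pr in meta$residual_pairs) {
    v <- est$resid_cov[[paste(pr, collapse = "~~")]]
    Psi[pr[1], pr[2]] <- Psi[pr[2], pr[1]] <- v
  }
  ev <- eigen(Psi, symmetric = TRUE)
  Prt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    rows <- sample.int(n, n, replace = TRUE)
    Xe <- as.matrix(Z)[rows, exog, drop = FALSE]
    M <- Xe %*% t(Gamma[, exog, drop = FALSE]) +
      matrix(stats::rnorm(n * nrow(Gamma)), n) %*% Prt
    y <- drop(Xe[, meta$predictors, drop = FALSE] %*% est$cp +
                M %*% est$b) +
      stats::rnorm(n, sd = sqrt(est$resid_var[[meta$outcome]]))
    d <- data.frame(Xe, M, y, check.names = FALSE)
    names(d) <- c(exog, meta$mediators, meta$outcome)
    out[[s]] <- d
  }
  out
}

#' @export
confint.path_mediation <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$boot))
    stop("no bootstrap stored; refit with n_boot > 0 or call cluster_bootstrap()")
  if (!missing(level) && !isTRUE(all.equal(level, attr(object$boot, "ci_level"))))
    warning("returning the stored ", attr(object$boot, "ci_level"),
            " level intervals; refit the bootstrap for a different level")
  object$boot
}

#' Summarize a fitted path model
#'
#' @param object A fitted [path_mediation()] model.
#' @param ... Passed to [model_fit()].
#' @return Object of class `summary.path_mediation` holding the path
#'   coefficient tables, indirect effects (with bootstrap CIs when
#'   available), fit indices and outcome R-squared.
#' @export
summary.path_mediation <- function(object, ...) {
  structure(list(
    call = object$call,
    n = object$n,
    n_dropped = object$n_dropped,
    a = object$estimates$a,
    age = object$estimates$age,
    b = object$estimates$b,
    cp = object$estimates$cp,
    R2 = object$estimates$R2,
    indirect = object$indirect,
    boot = object$boot,
    fit = model_fit(object, ...)
  ), class = "summary.path_mediation")
}

#' @export
#' @method print summary.path_mediation
print.summary.path_mediation <- function(x, digits = 3, ...) {
  cat("Multiple-predictor/multiple-mediator path model (n =", x$n, ")\n\n")
  cat("Mediator -> reading paths (b):\n")
  print(round(x$b, digits))
  cat("\nGene -> mediator paths (a), mediators x predictors:\n")
  print(round(x$a, digits))
  cat("\nAge -> mediator paths:\n")
  print(round(x$age, digits))
  cat("\nDirect gene -> reading paths (c'):\n")
  print(round(x$cp, digits))
  cat("\nTotal indirect effects per predictor:\n")
  print(round(x$indirect$total, digits))
  if (!is.null(x$boot)) {
    cat("\nBootstrap inference:\n")
    print(x$boot, digits = digits)
  }
  cat(sprintf("\nOutcome R-squared: %.3f\n", x$R2))
  cat("Fit: ")
  print(x$fit)
  invisible(x)
}

#' Forest plot of indirect effects
#'
#' Plots the total indirect effect of every predictor (and, when a single
#' predictor is chosen, its five specific indirect effects) with the
#' bootstrap confidence intervals when present.
#'
#' @param x A fitted [path_mediation()] model.
#' @param predictor Optional single predictor name: plot its specific
#'   indirect effects instead of the totals.
#' @param ... Further graphical parameters passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
#' @method plot path_mediation
plot.path_mediation <- function(x, predictor = NULL, ...) {
  if (is.null(predictor)) {
    eff <- x$indirect$total
    labels <- names(eff)
    sel <- if (!is.null(x$boot)) x$boot$type == "total" else NULL
    main <- "Total indirect effects"
  } else {
    stopifnot(predictor %in% x$meta$predictors)
    eff <- x$indirect$specific[, predictor]
    labels <- names(eff)
    sel <- if (!is.null(x$boot))
      x$boot$type == "specific" & x$boot$predictor == predictor else NULL
    main <- paste("Specific indirect effects of", predictor)
  }
  k <- length(eff)
  lo <- hi <- NULL
  if (!is.null(sel)) {
    bt <- x$boot[sel, ]
    ord <- match(labels, if (is.null(predictor)) bt$predictor else bt$mediator)
    lo <- bt$lower[ord]; hi <- bt$upper[ord]
  }
  xlim <- range(0, eff, lo, hi, na.rm = TRUE)
  graphics::plot(eff, seq_len(k), yaxt = "n", xlab = "standardized effect",
                 ylab = "", xlim = xlim, pch = 19, main = main, ...)
  graphics::axis(2, at = seq_len(k), labels = labels, las = 2, cex.axis = 0.7)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  if (!is.null(lo))
    graphics::segments(lo, seq_len(k), hi, seq_len(k))
  invisible(x)
}
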