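# Family-clustered bias-corrected percentile bootstrap for indirect effects.

# flatten the indirect-effect arrays of one fit into a named vector
.indirect_vector <- function(ind) {
  sp <- ind$specific
  c(stats::setNames(as.vector(sp),
                    as.vector(outer(rownames(sp), colnames(sp), paste,
                                    sep = "|"))),
    stats::setNames(ind$total, paste0("total|", names(ind$total))),
    stats::setNames(ind$total_effect,
                    paste0("total_effect|", names(ind$total_effect))))
}

# bias-corrected percentile interval for one effect
.bc_interval <- function(reps, est, level) {
  B <- length(reps)
  prop <- sum(reps < est) / B
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(prop)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  probs <- stats::pnorm(2 * z0 + c(-zq, zq))
  stats::quantile(reps, probs, names = FALSE, type = 7)
}

#' Family-clustered bias-corrected bootstrap for indirect effects
#'
#' Resamples whole families (clusters) with replacement, keeping the
#' original cluster count; unrelated controls are singleton clusters, so
#' family composition is preserved and the within-family dependence of
#' siblings is honoured. Each replicate re-standardizes the resampled data,
#' refits the full path model and recomputes every specific, total and
#' total (indirect + direct) effect. Confidence intervals are bias-corrected
#' percentile intervals: with `z0 = qnorm(P(replicate < point estimate))`
#' and `zq` the normal quantile of the interval level, the bounds are the
#' `pnorm(2 z0 -/+ zq)` percentiles of the replicate distribution.
#'
#' Replicates in which an equation becomes rank-deficient or a column
#' becomes constant (e.g. a rare coded marker drawn without carriers) are
#' counted as failed and excluded; more than 5% failures warns, more than
#' 25% is an error.
#'
#' @param object A fitted [path_mediation()] model.
#' @param n_boot Number of bootstrap replicates (reference analysis: 5000;
#'   at least 100).
#' @param ci_level Confidence level (default 0.95). An interval excluding
#'   zero flags the effect as significant.
#' @param seed Integer seed; the same seed reproduces the intervals exactly.
#' @return Object of class `boot_indirect`: a data.frame with `type`
#'   (`specific`, `total`, `total_effect`), `predictor`, `mediator`,
#'   `estimate`, `boot_se`, `lower`, `upper`, `significant`, plus attributes
#'   `n_boot`, `n_failed`, `seed`, `ci_level`.
#' @export
cluster_bootstrap <- function(object, n_boot = 5000, ci_level = 0.95,
                              seed = 1L) {
  stopifnot(inherits(object, "path_mediation"), n_boot >= 100)
  set.seed(as.integer(seed))
  X <- object$data
  meta <- object$meta
  idx <- split(seq_len(nrow(X)), object$clusters)
  n_cl <- length(idx)

  point <- .indirect_vector(object$indirect)
  reps <- matrix(NA_real_, n_boot, length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (r in seq_len(n_boot)) {
    rows <- unlist(idx[sample.int(n_cl, n_cl, replace = TRUE)],
                   use.names = FALSE)
    Xb <- X[rows, , drop = FALSE]
    m <- colMeans(Xb)
    s <- sqrt((colSums(Xb^2) - nrow(Xb) * m^2) / (nrow(Xb) - 1))
    if (any(!is.finite(s)) || any(s <= 1e-12)) {
      n_failed <- n_failed + 1L
      next
    }
    Zb <- sweep(sweep(Xb, 2, m), 2, s, "/")
    fit <- tryCatch(.fit_path_core(Zb, meta), error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    reps[r, ] <- .indirect_vector(indirect_effects(fit))
  }
  ok <- !is.na(reps[, 1])
  frac_failed <- n_failed / n_boot
  if (frac_failed > 0.25)
    stop("bootstrap failed in ", round(100 * frac_failed, 1),
         "% of replicates; data too fragile for resampling")
  if (frac_failed > 0.05)
    warning(round(100 * frac_failed, 1), "% of bootstrap replicates failed ",
            "and were dropped")
  reps <- reps[ok, , drop = FALSE]

  ci <- t(vapply(names(point),
                 function(nm) .bc_interval(reps[, nm], point[[nm]], ci_level),
                 numeric(2)))
  parts <- strsplit(names(point), "|", fixed = TRUE)
  type <- vapply(parts, function(p)
    if (p[1] %in% c("total", "total_effect")) p[1] else "specific",
    character(1))
  out <- data.frame(
    type = type,
    predictor = vapply(parts, `[`, character(1), 2),
    mediator = ifelse(type == "specific",
                      vapply(parts, `[`, character(1), 1), NA_character_),
    estimate = unname(point),
    boot_se = unname(apply(reps, 2, stats::sd)),
    lower = unname(ci[, 1]),
    upper = unname(ci[, 2]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$significant <- out$lower > 0 | out$upper < 0
  structure(out, class = c("boot_indirect", "data.frame"),
            n_boot = as.integer(n_boot), n_failed = n_failed,
            seed = as.integer(seed), ci_level = ci_level)
}

#' @export
#' @method print boot_indirect
print.boot_indirect <- function(x, digits = 3, ...) {
  cat("Family-clustered bias-corrected bootstrap (",
      attr(x, "n_boot"), " replicates, ", attr(x, "n_failed"),
      " failed, ", round(100 * attr(x, "ci_level")), "% CI)\n\n", sep = "")
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, digits)
  df$boot_se <- round(df$boot_se, digits)
  df$lower <- round(df$lower, digits)
  df$upper <- round(df$upper, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
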