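# Psychometric (logistic) fit of the rotating-tilted-lines illusion curve.

#' Fit the illusion psychometric function for one subject
#'
#' Least-squares fit of the two-parameter logistic
#' `y = 1 / (1 + exp(-b (x - t)))` (lower bound 0, upper bound 1) to
#' observed perceived-rotation proportions over contrast levels `x`. The
#' slope `b` (> 0) and 50% threshold `t` are found by multi-start
#' box-constrained quasi-Newton minimization of the residual sum of squares
#' over a coarse `(b, t)` grid; by construction the fitted curve passes
#' through 0.5 at `x = t`.
#'
#' Degenerate curves (all responses 0 or all 1) carry no threshold
#' information: the fit is flagged non-converged and the parameters are
#' missing.
#'
#' @param contrast Contrast levels `x` (% increments, e.g. 0..10).
#' @param n_perceived Perceived-rotation counts (or proportions when
#'   `n_presented = 1`).
#' @param n_presented Presentations per level (scalar or vector).
#' @return List of class `rtli_fit`: `b`, `t`, `rss`, `converged`.
#' @examples
#' x <- 0:10
#' y <- 1 / (1 + exp(-2 * (x - 5)))
#' fit_rtli(x, y * 5, 5)  # recovers b = 2, t = 5
#' @export
fit_rtli <- function(contrast, n_perceived, n_presented = 5) {
  stopifnot(length(contrast) == length(n_perceived))
  y <- n_perceived / n_presented
  if (length(unique(contrast)) < 2)
    stop("need at least 2 distinct contrast levels")
  if (any(y < -1e-9 | y > 1 + 1e-9))
    stop("perceived proportions must lie in [0, 1]")
  out <- list(b = NA_real_, t = NA_real_, rss = NA_real_, converged = FALSE)
  class(out) <- "rtli_fit"
  if (all(y <= 0) || all(y >= 1)) return(out)  # flat curve: unidentifiable

  rss <- function(par) sum((y - stats::plogis(par[1] * (contrast - par[2])))^2)
  t_grid <- stats::quantile(contrast, c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE)
  starts <- expand.grid(b = c(0.2, 0.5, 1, 2, 4), t = unique(t_grid))
  lower <- c(1e-3, min(contrast) - diff(range(contrast)))
  upper <- c(50, max(contrast) + diff(range(contrast)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), rss,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(factr = 1e3, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(out)
  # unconstrained polish from the best start; keep it only if admissible
  polish <- try(stats::optim(best$par, rss,
                             control = list(reltol = 1e-12, maxit = 1000)),
                silent = TRUE)
  if (!inherits(polish, "try-error") && polish$par[1] > 0 &&
      polish$value < best$value)
    best <- polish
  out$b <- best$par[1]
  out$t <- best$par[2]
  out$rss <- best$value
  # code 52 (abnormal line-search termination) occurs when the minimum is
  # already attained to machine precision; the solution is still valid
  out$converged <- best$convergence %in% c(0L, 52L)
  out
}

#' @export
#' @method print rtli_fit
print.rtli_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("Psychometric fit: b = %.4f, t = %.4f%% contrast (RSS %.3g)\n",
                x$b, x$t, x$rss))
  else
    cat("Psychometric fit: not converged (degenerate response curve)\n")
  invisible(x)
}

#' Fit the illusion psychometric function for every subject of a table
#'
#' @param responses data.frame with `subject_id`, `contrast`, `n_presented`,
#'   `n_perceived` (as emitted by [simulate_rtli_responses()]).
#' @return data.frame with `subject_id`, raw `RTLI_b` (slope), `RTLI_t`
#'   (threshold), `rss` and `converged`. Apply [transform_eps()] before
#'   modelling.
#' @export
fit_rtli_table <- function(responses) {
  stopifnot(all(c("subject_id", "contrast", "n_presented", "n_perceived")
                %in% names(responses)))
  ids <- unique(responses$subject_id)
  rows <- lapply(ids, function(id) {
    d <- responses[responses$subject_id == id, ]
    f <- fit_rtli(d$contrast, d$n_perceived, d$n_presented)
    data.frame(subject_id = id, RTLI_b = f$b, RTLI_t = f$t,
               rss = f$rss, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
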