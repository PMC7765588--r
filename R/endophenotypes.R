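# Trial-level scoring of the four endophenotype tasks, the reading
# composite, distributional transforms and the bivariate correlation screen.

#' Score rapid auditory processing (temporal order judgment)
#'
#' Per subject and inter-stimulus interval (ISI), accuracy (%) is computed
#' over trials; per ISI the 25th and 75th percentiles of the accuracy
#' distribution over the whole sample define a three-level code: 1 at or
#' below the 25th percentile, 3 at or above the 75th, 2 between. The
#' subject's RAP score is the mean of the five per-ISI codes (higher =
#' better temporal processing). Percentiles use linear interpolation between
#' order statistics (`quantile` type 7). If the two percentiles coincide at
#' an ISI the rule order (`<= P25` first) codes every subject 1 there, with
#' a warning.
#'
#' @param trials data.frame with `subject_id`, `isi` (ms), `correct` (0/1).
#' @return data.frame with `subject_id` and `RAP`.
#' @export
score_rap <- function(trials) {
  stopifnot(all(c("subject_id", "isi", "correct") %in% names(trials)))
  subjects <- unique(trials$subject_id)
  if (length(subjects) < 4)
    stop("RAP percentile coding needs at least 4 subjects")
  acc <- tapply(trials$correct * 100,
                list(trials$subject_id, trials$isi), mean)
  acc <- acc[match(as.character(subjects), rownames(acc)), , drop = FALSE]
  codes <- matrix(NA_real_, nrow(acc), ncol(acc), dimnames = dimnames(acc))
  for (j in seq_len(ncol(acc))) {
    qs <- stats::quantile(acc[, j], c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    if (qs[1] == qs[2])
      warning("degenerate accuracy distribution at ISI ", colnames(acc)[j],
              " ms (P25 = P75); all subjects coded 1 by rule order")
    codes[, j] <- ifelse(acc[, j] <= qs[1], 1,
                         ifelse(acc[, j] >= qs[2], 3, 2))
  }
  data.frame(subject_id = subjects,
             RAP = rowMeans(codes, na.rm = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score rapid automatized naming
#'
#' Mean vocal reaction time over correctly named trials, after excluding
#' outlier RTs longer than 1000 ms; the mean is then z-normalized across the
#' sample (`RAN_rt`, higher = slower naming). Subjects without a usable
#' trial get `NA`, with a message.
#'
#' @param trials data.frame with `subject_id`, `rt` (ms), `correct` (0/1).
#' @param rt_max Outlier cutoff in ms (default 1000).
#' @param normalize If `FALSE`, return raw per-subject mean RTs in ms.
#' @return data.frame with `subject_id`, `ran_mean_rt` (ms) and, when
#'   `normalize`, `RAN_rt` (z-scored).
#' @export
score_ran <- function(trials, rt_max = 1000, normalize = TRUE) {
  stopifnot(all(c("subject_id", "rt", "correct") %in% names(trials)))
  subjects <- unique(trials$subject_id)
  usable <- trials$correct == 1 & trials$rt <= rt_max
  mrt <- tapply(trials$rt[usable], trials$subject_id[usable], mean)
  out <- data.frame(subject_id = subjects,
                    ran_mean_rt = as.numeric(mrt[as.character(subjects)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (anyNA(out$ran_mean_rt))
    message(sum(is.na(out$ran_mean_rt)),
            " subject(s) with no usable naming trial: RAN set to missing")
  if (normalize)
    out$RAN_rt <- as.numeric(scale(out$ran_mean_rt))
  out
}

#' Score the multisensory warning effect
#'
#' Response-trial RTs outside [150, 1500] ms are excluded as outliers. Per
#' SOA (100, 250 ms) a composite is formed as the mean over the four cell
#' means (visual/auditory x valid/invalid); the warning effect is
#' `WE = composite(250) - composite(100)` in ms. Subjects with an empty cell
#' after filtering get `NA`, with a message.
#'
#' @param trials data.frame with `subject_id`, `modality`, `soa`, `validity`,
#'   `rt`; catch trials (no RT) are ignored.
#' @param rt_range Inclusion bounds in ms (default `c(150, 1500)`).
#' @return data.frame with `subject_id` and `WE` (ms).
#' @export
score_attention_we <- function(trials, rt_range = c(150, 1500)) {
  stopifnot(all(c("subject_id", "modality", "soa", "validity", "rt")
                %in% names(trials)))
  subjects <- unique(trials$subject_id)
  resp <- trials[trials$validity %in% c("valid", "invalid") &
                   !is.na(trials$rt), , drop = FALSE]
  keep <- resp$rt >= rt_range[1] & resp$rt <= rt_range[2]
  resp <- resp[keep, , drop = FALSE]
  cell <- tapply(resp$rt,
                 list(resp$subject_id,
                      interaction(resp$modality, resp$soa, resp$validity)),
                 mean)
  cols_100 <- grep("\\.100\\.", colnames(cell))
  cols_250 <- grep("\\.250\\.", colnames(cell))
  comp100 <- rowMeans(cell[, cols_100, drop = FALSE])
  comp250 <- rowMeans(cell[, cols_250, drop = FALSE])
  we <- (comp250 - comp100)[as.character(subjects)]
  if (anyNA(we))
    message(sum(is.na(we)),
            " subject(s) with an empty attention cell after RT filtering: WE missing")
  data.frame(subject_id = subjects, WE = as.numeric(we),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the distributional transforms to the psychometric parameters
#'
#' The illusion slope is log-transformed (`RTLI_b <- ln b`) and the 50%
#' threshold square-root transformed (`RTLI_t <- sqrt t`) to obtain
#' acceptable distributions for the linear path model; other columns pass
#' through. Non-positive slopes (for which the log is undefined) become
#' missing, with a message. Transform provenance is recorded in the
#' `"transforms"` attribute.
#'
#' @param table data.frame containing raw `RTLI_b` (> 0) and `RTLI_t` (>= 0).
#' @return The table with transformed columns.
#' @export
transform_eps <- function(table) {
  stopifnot(all(c("RTLI_b", "RTLI_t") %in% names(table)))
  bad_b <- !is.na(table$RTLI_b) & table$RTLI_b <= 0
  bad_t <- !is.na(table$RTLI_t) & table$RTLI_t < 0
  if (any(bad_b))
    message(sum(bad_b), " non-positive slope(s): RTLI_b set to missing")
  if (any(bad_t))
    message(sum(bad_t), " negative threshold(s): RTLI_t set to missing")
  table$RTLI_b[bad_b] <- NA_real_
  table$RTLI_t[bad_t] <- NA_real_
  table$RTLI_b <- log(table$RTLI_b)
  table$RTLI_t <- sqrt(table$RTLI_t)
  attr(table, "transforms") <- c(RTLI_b = "log", RTLI_t = "sqrt")
  table
}

#' Reading composite score
#'
#' Each reading measure is z-scored across the sample; error-count measures
#' are sign-flipped first so that higher always means better reading. The
#' composite is the mean of the available z-scores per subject (the number
#' of contributing measures is recorded).
#'
#' @param scores data.frame or matrix of reading measures (rows = subjects).
#' @param higher_is_better Logical vector, one entry per measure; `FALSE`
#'   for error counts and time-to-read measures, which are sign-flipped.
#' @return data.frame with `reading` (composite) and `n_measures`.
#' @export
reading_composite <- function(scores,
                              higher_is_better = rep(TRUE, ncol(scores))) {
  scores <- as.matrix(scores)
  stopifnot(length(higher_is_better) == ncol(scores))
  z <- scale(scores)
  z[, !higher_is_better] <- -z[, !higher_is_better, drop = FALSE]
  n_meas <- rowSums(!is.na(z))
  comp <- rowMeans(z, na.rm = TRUE)
  comp[n_meas == 0] <- NA_real_
  data.frame(reading = comp, n_measures = n_meas, row.names = NULL)
}

#' Bivariate correlation screen
#'
#' Two-tailed Pearson correlations, on pairwise-complete observations,
#' between every coded genotype predictor and each endophenotype and the
#' reading composite, and between each endophenotype and reading.
#'
#' @param coded Subjects x markers coded genotype matrix.
#' @param eps data.frame of endophenotype scores (columns [ep_names()]).
#' @param reading Numeric reading composite.
#' @return data.frame with `x`, `y`, `r`, `p`, `n` per pair.
#' @export
correlation_screen <- function(coded, eps, reading) {
  eps <- as.data.frame(eps)[, intersect(ep_names(), colnames(eps)),
                            drop = FALSE]
  vars_y <- cbind(eps, reading = reading)
  pairs <- rbind(
    expand.grid(x = colnames(coded), y = colnames(vars_y),
                stringsAsFactors = FALSE),
    expand.grid(x = colnames(eps), y = "reading", stringsAsFactors = FALSE)
  )
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    xv <- if (pairs$x[i] %in% colnames(coded)) coded[, pairs$x[i]]
          else vars_y[[pairs$x[i]]]
    yv <- vars_y[[pairs$y[i]]]
    ok <- stats::complete.cases(xv, yv)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for ",
                          pairs$x[i], " vs ", pairs$y[i])
    ct <- stats::cor.test(xv[ok], yv[ok], method = "pearson",
                          alternative = "two.sided")
    data.frame(x = pairs$x[i], y = pairs$y[i],
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Score a cohort's trial tables into the endophenotype table
#'
#' Runs the four task scorers on a cohort's emitted trial data, applies the
#' log/sqrt transforms to the psychometric parameters, and returns one row
#' per subject with the five endophenotype scores and age.
#'
#' @param cohort A `dd_cohort` whose `trials` component is present.
#' @return data.frame with `subject_id`, the five columns of [ep_names()]
#'   and `age`.
#' @export
score_cohort_trials <- function(cohort) {
  stopifnot(inherits(cohort, "dd_cohort"))
  if (is.null(cohort$trials))
    stop("cohort has no trial data; generate with emit_trials = TRUE")
  tr <- cohort$trials
  rap <- score_rap(tr$rap)
  ran <- score_ran(tr$ran)
  we <- score_attention_we(tr$attention)
  psy <- fit_rtli_table(tr$rtli)
  psy <- transform_eps(psy)
  out <- data.frame(subject_id = cohort$subjects$subject_id,
                    stringsAsFactors = FALSE)
  out$WE <- we$WE[match(out$subject_id, we$subject_id)]
  out$RTLI_b <- psy$RTLI_b[match(out$subject_id, psy$subject_id)]
  out$RTLI_t <- psy$RTLI_t[match(out$subject_id, psy$subject_id)]
  out$RAP <- rap$RAP[match(out$subject_id, rap$subject_id)]
  out$RAN_rt <- ran$RAN_rt[match(out$subject_id, ran$subject_id)]
  out$age <- cohort$subjects$age
  out
}
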