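# Raw trial-level task emission: the inverse of the scoring module. Latent
# standardized mediator values are mapped to natural task scales, then trial
# tables are drawn so that scoring them recovers the latent values up to
# sampling noise.

# natural-scale anchors for the latent -> task maps
.trial_anchors <- function() {
  list(
    rap_base = c("20" = 0.55, "40" = 0.65, "80" = 0.75, "120" = 0.85,
                 "280" = 0.95),  # mean accuracy by ISI (chance = 0.5)
    rap_slope = 1.2,             # logit-accuracy change per SD of latent RAP
    ran_mean = 600, ran_sd = 90, # naming RT mean (ms) and between-subject SD
    ran_trial_sd = 80,           # within-subject trial RT SD (ms)
    ran_acc = 0.97,              # naming accuracy
    we_mean = -20, we_sd = 30,   # warning effect (ms): RT(250) - RT(100)
    att_base = c(visual = 380, auditory = 420),  # detection RT baselines (ms)
    att_trial_sd = 60,
    logb_mean = log(1.2), logb_sd = 0.5,  # illusion slope, log scale
    sqrt_t_mean = 2, sqrt_t_sd = 0.3      # illusion threshold, sqrt scale
  )
}

#' Simulate rapid-auditory-processing (temporal order judgment) trials
#'
#' Two-alternative temporal order judgments of tone pairs at five
#' inter-stimulus intervals (20, 40, 80, 120, 280 ms), 8 trials per ISI.
#' Accuracy rises with ISI and with the subject's latent skill.
#'
#' @param latent Vector of latent standardized RAP skill values, one per
#'   subject.
#' @param n_per_isi Trials per ISI (task default 8).
#' @param subject_id Optional subject ids.
#' @return data.frame with `subject_id`, `isi` (ms), `trial`, `correct`.
#' @export
simulate_rap_trials <- function(latent, n_per_isi = 8,
                                subject_id = seq_along(latent)) {
  an <- .trial_anchors()
  isis <- as.integer(names(an$rap_base))
  grid <- expand.grid(i = seq_along(latent), isi = isis,
                      trial = seq_len(n_per_isi))
  pr <- stats::plogis(stats::qlogis(an$rap_base[as.character(grid$isi)]) +
                        an$rap_slope * latent[grid$i])
  data.frame(subject_id = subject_id[grid$i],
             isi = grid$isi,
             trial = grid$trial,
             correct = as.integer(stats::runif(nrow(grid)) < pr),
             stringsAsFactors = FALSE)
}

#' Simulate discrete rapid-naming trials
#'
#' Vocal reaction times for 32 discrete color-naming trials per subject.
#'
#' @param mean_rt Per-subject true mean RT in ms.
#' @param n_trials Trials per subject (task default 32).
#' @param subject_id Optional subject ids.
#' @param trial_sd Within-subject RT standard deviation (ms).
#' @param accuracy Probability a trial is named correctly.
#' @return data.frame with `subject_id`, `trial`, `rt` (ms), `correct`.
#' @export
simulate_ran_trials <- function(mean_rt, n_trials = 32,
                                subject_id = seq_along(mean_rt),
                                trial_sd = .trial_anchors()$ran_trial_sd,
                                accuracy = .trial_anchors()$ran_acc) {
  grid <- expand.grid(i = seq_along(mean_rt), trial = seq_len(n_trials))
  rt <- pmax(stats::rnorm(nrow(grid), mean_rt[grid$i], trial_sd), 1)
  data.frame(subject_id = subject_id[grid$i],
             trial = grid$trial,
             rt = rt,
             correct = as.integer(stats::runif(nrow(grid)) < accuracy),
             stringsAsFactors = FALSE)
}

#' Simulate cued-detection (attention) trials
#'
#' Visual and auditory cued detection with cue-target SOAs of 100 and 250 ms.
#' Per modality the session holds 16 valid and 16 invalid response trials per
#' SOA plus 16 catch trials (no target, no RT), i.e. 80 trials per modality.
#' The subject's warning effect (`we_ms`) is the RT difference between the
#' 250 ms and 100 ms SOA.
#'
#' @param we_ms Per-subject true warning effect in ms.
#' @param n_per_cell Response trials per modality x SOA x validity cell
#'   (task default 16).
#' @param subject_id Optional subject ids.
#' @param trial_sd Trial RT standard deviation (ms).
#' @return data.frame with `subject_id`, `modality`, `soa` (ms), `validity`
#'   (`valid`, `invalid` or `catch`), `block`, `rt` (ms; `NA` on catch
#'   trials) and `responded`.
#' @export
simulate_attention_trials <- function(we_ms, n_per_cell = 16,
                                      subject_id = seq_along(we_ms),
                                      trial_sd = .trial_anchors()$att_trial_sd) {
  an <- .trial_anchors()
  resp <- expand.grid(i = seq_along(we_ms),
                      modality = c("visual", "auditory"),
                      soa = c(100L, 250L),
                      validity = c("valid", "invalid"),
                      trial = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  mu <- an$att_base[resp$modality] + ifelse(resp$soa == 250L, we_ms[resp$i], 0)
  resp$rt <- pmax(stats::rnorm(nrow(resp), mu, trial_sd), 151)
  resp$responded <- TRUE
  n_catch <- max(1L, round(n_per_cell))  # 16 catch trials per modality
  catch <- expand.grid(i = seq_along(we_ms),
                       modality = c("visual", "auditory"),
                       soa = NA_integer_,
                       validity = "catch",
                       trial = seq_len(n_catch),
                       stringsAsFactors = FALSE)
  catch$rt <- NA_real_
  catch$responded <- FALSE
  out <- rbind(resp, catch)
  out$block <- 1L + (out$trial > ceiling(max(out$trial) / 2))
  data.frame(subject_id = subject_id[out$i],
             out[c("modality", "soa", "validity", "block", "rt", "responded")],
             stringsAsFactors = FALSE)
}

#' Simulate rotating-tilted-lines illusion responses
#'
#' Perceived-rotation counts at 11 Michelson contrast levels (0..10%), 5
#' presentations each, from the logistic psychometric function
#' `y = 1 / (1 + exp(-b (x - t)))` with subject-specific slope `b` and 50%
#' threshold `t`.
#'
#' @param b,t Per-subject psychometric slope (> 0) and threshold (% contrast).
#' @param n_per_level Presentations per contrast level (task default 5).
#' @param subject_id Optional subject ids.
#' @param noiseless If `TRUE`, emit expected counts `n_per_level * y`
#'   (continuous) instead of binomial draws, so the psychometric fit recovers
#'   `(b, t)` exactly.
#' @return data.frame with `subject_id`, `contrast` (0..10, %),
#'   `n_presented`, `n_perceived`.
#' @export
simulate_rtli_responses <- function(b, t, n_per_level = 5,
                                    subject_id = seq_along(b),
                                    noiseless = FALSE) {
  stopifnot(length(b) == length(t))
  grid <- expand.grid(i = seq_along(b), contrast = 0:10)
  y <- stats::plogis(b[grid$i] * (grid$contrast - t[grid$i]))
  n_perc <- if (noiseless) n_per_level * y else
    stats::rbinom(nrow(grid), n_per_level, y)
  data.frame(subject_id = subject_id[grid$i],
             contrast = grid$contrast,
             n_presented = n_per_level,
             n_perceived = n_perc,
             stringsAsFactors = FALSE)
}

#' Emit raw trial-level task tables for a synthetic cohort
#'
#' Maps each subject's latent standardized mediator values onto the natural
#' scales of the four tasks and draws trial tables, so that running the
#' scoring pipeline ([score_cohort_trials()]) recovers the latent mediators
#' up to trial sampling noise.
#'
#' @param cohort A `dd_cohort` with latent mediator values.
#' @param config The [cohort_config()] used to generate it (supplies
#'   `trial_scale`); its `emit_trials` flag must be `TRUE`, otherwise the
#'   call is a no-op with a warning.
#' @return List of four data.frames: `rap`, `ran`, `attention`, `rtli`
#'   (or `NULL` when `config$emit_trials` is `FALSE`).
#' @export
emit_trial_data <- function(cohort, config = cohort_config(emit_trials = TRUE)) {
  stopifnot(inherits(cohort, "dd_cohort"), inherits(config, "cohort_config"))
  if (!config$emit_trials) {
    warning("config$emit_trials is FALSE; no trial data emitted")
    return(invisible(NULL))
  }
  an <- .trial_anchors()
  sc <- config$trial_scale
  M <- as.matrix(cohort$mediators[, ep_names()])
  ids <- cohort$mediators$subject_id

  b <- exp(an$logb_mean + an$logb_sd * M[, "RTLI_b"])
  t <- pmax(an$sqrt_t_mean + an$sqrt_t_sd * M[, "RTLI_t"], 0.05)^2
  list(
    rap = simulate_rap_trials(M[, "RAP"], n_per_isi = round(8 * sc),
                              subject_id = ids),
    ran = simulate_ran_trials(an$ran_mean + an$ran_sd * M[, "RAN_rt"],
                              n_trials = round(32 * sc), subject_id = ids),
    attention = simulate_attention_trials(
      an$we_mean + an$we_sd * M[, "WE"],
      n_per_cell = round(16 * sc), subject_id = ids),
    rtli = simulate_rtli_responses(b, t, n_per_level = round(5 * sc),
                                   subject_id = ids)
  )
}
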