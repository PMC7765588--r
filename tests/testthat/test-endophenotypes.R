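# Task scoring: percentile coding, outlier filters, psychometric fitting,
# transforms, the reading composite and the correlation screen.

make_rap_trials <- function(acc_by_subject, n_trials = 10, isi = 80) {
  do.call(rbind, lapply(seq_along(acc_by_subject), function(i) {
    k <- round(acc_by_subject[i] / 100 * n_trials)
    data.frame(subject_id = paste0("s", i), isi = isi,
               correct = c(rep(1L, k), rep(0L, n_trials - k)))
  }))
}

test_that("a floor-performing subject among perfect ones codes 1 at every ISI", {
  trials <- do.call(rbind, lapply(c(20, 40, 80, 120, 280), function(isi) {
    rbind(make_rap_trials(c(50, rep(100, 7)), isi = isi))
  }))
  # with everyone else perfect the quartiles coincide, which the scorer warns
  # about before coding by rule order
  sc <- suppressWarnings(score_rap(trials))
  expect_equal(sc$RAP[sc$subject_id == "s1"], 1)
})

test_that("percentile codes follow the quantile rule at one ISI", {
  acc <- seq(10, 100, by = 10)  # ten subjects
  sc <- score_rap(make_rap_trials(acc))
  q <- quantile(acc, c(0.25, 0.75), names = FALSE)  # type-7 estimator
  want <- ifelse(acc <= q[1], 1, ifelse(acc >= q[2], 3, 2))
  expect_equal(sc$RAP, want)
  expect_equal(sc$RAP[1], 1)    # 10% accuracy
  expect_equal(sc$RAP[10], 3)   # 100% accuracy
})

test_that("degenerate accuracy distributions code everyone 1, with warning", {
  trials <- make_rap_trials(rep(80, 6))
  expect_warning(sc <- score_rap(trials), "degenerate")
  expect_true(all(sc$RAP == 1))
})

test_that("naming RTs are averaged after the 1000 ms outlier cut and z-scored", {
  tr <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                   rt = c(400, 600, 1200, 500, 500, 500),
                   correct = 1L)
  sc <- score_ran(tr, normalize = FALSE)
  expect_equal(sc$ran_mean_rt, c(500, 500))  # 1200 excluded
  tr2 <- data.frame(subject_id = rep(paste0("s", 1:6), each = 2),
                    rt = rep(c(350, 420, 480, 520, 610, 700), each = 2),
                    correct = 1L)
  sc2 <- score_ran(tr2)
  expect_lt(abs(mean(sc2$RAN_rt)), 1e-12)
  expect_lt(abs(sd(sc2$RAN_rt) - 1), 1e-12)
  # incorrect trials are discarded
  tr3 <- data.frame(subject_id = "a", rt = c(500, 900), correct = c(1L, 0L))
  expect_equal(score_ran(tr3, normalize = FALSE)$ran_mean_rt, 500)
})

make_att_trials <- function(rts_100, rts_250, subject = "s1") {
  cells <- expand.grid(modality = c("visual", "auditory"),
                       validity = c("valid", "invalid"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(subject_id = subject, modality = cells$modality[i],
               soa = c(rep(100L, length(rts_100)), rep(250L, length(rts_250))),
               validity = cells$validity[i],
               rt = c(rts_100, rts_250))
  }))
}

test_that("warning effect is the 250 minus 100 ms SOA composite difference", {
  expect_equal(score_attention_we(make_att_trials(400, 400))$WE, 0)
  expect_equal(score_attention_we(make_att_trials(400, 380))$WE, -20)
  # an RT below the 150 ms floor is excluded before averaging
  sc <- score_attention_we(make_att_trials(c(100, 400, 400), 380))
  expect_equal(sc$WE, -20)
  # and above the 1500 ms ceiling likewise
  sc2 <- score_attention_we(make_att_trials(400, c(380, 1600)))
  expect_equal(sc2$WE, -20)
})

test_that("psychometric fit recovers exact logistic proportions", {
  x <- 0:10
  y <- 1 / (1 + exp(-2 * (x - 5)))
  f <- fit_rtli(x, y * 5, 5)
  expect_true(f$converged)
  expect_lt(abs(f$b - 2), 1e-4)
  expect_lt(abs(f$t - 5), 1e-4)
  # the fitted curve passes through one half at the threshold
  expect_equal(1 / (1 + exp(-f$b * (f$t - f$t))), 0.5)
  # degenerate flat curves are flagged, not fitted
  f0 <- fit_rtli(x, rep(0, 11), 5)
  expect_false(f0$converged)
  expect_true(is.na(f0$b))
})

test_that("psychometric fit is consistent under binomial response noise", {
  # independent single-start least-squares oracle for the same criterion
  ls_oracle <- function(x, y) {
    o <- optim(c(1.5, 4), function(p)
      sum((y - 1 / (1 + exp(-p[1] * (x - p[2]))))^2))
    o
  }
  set.seed(123)
  est <- t(replicate(300, {
    resp <- simulate_rtli_responses(b = 1.5, t = 4)
    f <- fit_rtli(resp$contrast, resp$n_perceived, resp$n_presented)
    o <- ls_oracle(resp$contrast, resp$n_perceived / resp$n_presented)
    c(f$b, f$t, f$rss, o$value)
  }))
  # the multi-start fit is never worse than the oracle's local solution
  expect_true(all(est[, 3] <= est[, 4] + 1e-8))
  # threshold recovery: median within 10% of truth
  expect_lt(abs(median(est[, 2], na.rm = TRUE) - 4), 0.4)
  # slope: least squares on 5 draws/level is median-biased upward; the
  # median stays inside the band measured for this design (about +17%)
  med_b <- median(est[, 1], na.rm = TRUE)
  expect_gt(med_b, 1.35)
  expect_lt(med_b, 2.1)
})

test_that("log/sqrt transforms are applied with provenance and monotone", {
  tab <- data.frame(RTLI_b = c(1, 2, 0.5), RTLI_t = c(4, 9, 1))
  out <- transform_eps(tab)
  expect_equal(out$RTLI_b, log(c(1, 2, 0.5)))
  expect_equal(out$RTLI_b[1], 0)
  expect_equal(out$RTLI_t, c(2, 3, 1))
  expect_equal(order(out$RTLI_b), order(tab$RTLI_b))
  expect_equal(attr(out, "transforms"),
               c(RTLI_b = "log", RTLI_t = "sqrt"))
  expect_message(bad <- transform_eps(data.frame(RTLI_b = c(-1, 2),
                                                 RTLI_t = c(1, 1))),
                 "non-positive")
  expect_true(is.na(bad$RTLI_b[1]))
})

test_that("reading composite averages aligned z-scores", {
  set.seed(7)
  base <- rnorm(30)
  scores <- data.frame(speed1 = base, speed2 = base,
                       errors = -base)  # error count: higher = worse
  comp <- reading_composite(scores,
                            higher_is_better = c(TRUE, TRUE, FALSE))
  expect_equal(comp$reading, as.numeric(scale(base)))
  expect_equal(comp$n_measures, rep(3L, 30))
  # two measures at +1 and -1 SD cancel
  two <- data.frame(a = c(rep(0, 8), 1), b = c(rep(0, 8), -1))
  z <- scale(two)
  expect_equal(reading_composite(two)$reading[9],
               mean(c(z[9, 1], z[9, 2])))
  expect_equal(sum(abs(reading_composite(data.frame(a = base, b = -base),
                                         c(TRUE, FALSE))$reading -
                         as.numeric(scale(base)))), 0, tolerance = 1e-12)
})

test_that("six simulated reading measures reproduce the target intercorrelation", {
  set.seed(8)
  n <- 2000; r <- 0.548
  f <- rnorm(n)
  scores <- sapply(1:6, function(j) sqrt(r) * f + sqrt(1 - r) * rnorm(n))
  cm <- cor(scores)
  mean_r <- mean(cm[lower.tri(cm)])
  expect_lt(abs(mean_r - r), 0.05)
  comp <- reading_composite(scores)
  expect_gt(cor(comp$reading, f), 0.9)
})

test_that("correlation screen matches the closed-form Pearson formula", {
  coded <- cbind(snp1 = c(1, 2, 3, 4, 0), snp2 = c(2, 4, 6, 8, 1))
  eps <- data.frame(WE = c(0.3, -1, 2, 0.4, -0.2),
                    RTLI_b = c(1, 0, -1, 0.5, 0.2),
                    RTLI_t = c(0, 1, 0, 1, 0.5),
                    RAP = c(2, 1, 3, 2.5, 1.5),
                    RAN_rt = c(-1, 0, 1, 0.3, 0.1))
  reading <- c(0.2, 0.5, -0.7, 1.1, 0)
  scr <- correlation_screen(coded, eps, reading)
  for (i in seq_len(nrow(scr))) {
    xv <- if (scr$x[i] %in% colnames(coded)) coded[, scr$x[i]]
          else eps[[scr$x[i]]]
    yv <- if (scr$y[i] == "reading") reading else eps[[scr$y[i]]]
    expect_lt(abs(scr$r[i] - pearson_brute(xv, yv)), 1e-12)
  }
  # exact linearity gives r = +/- 1
  lin <- correlation_screen(cbind(x = c(1, 2, 3, 4)),
                            data.frame(WE = c(2, 4, 6, 8),
                                       RTLI_b = c(8, 6, 4, 2),
                                       RTLI_t = 1:4, RAP = 1:4,
                                       RAN_rt = 1:4),
                            reading = c(1, 3, 2, 4))
  expect_equal(lin$r[lin$x == "x" & lin$y == "WE"], 1)
  expect_equal(lin$r[lin$x == "x" & lin$y == "RTLI_b"], -1)
})
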