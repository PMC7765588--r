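# The path model: standardization, equation-wise estimation, indirect
# effect arithmetic and the family-clustered bias-corrected bootstrap.

test_that("standardize centers, scales, back-transforms and is idempotent", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize(d)
  expect_equal(colMeans(as.matrix(z)), c(a = 0, b = 0))
  expect_equal(apply(as.matrix(z), 2, sd), c(a = 1, b = 1))
  z2 <- standardize(z)
  expect_equal(as.matrix(z2), as.matrix(z), tolerance = 1e-12)
  back <- unstandardize(z)
  expect_equal(as.matrix(back), as.matrix(d), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardize(data.frame(a = 1:3, flat = rep(2, 3))), "flat")
})

test_that("a noiseless mediator chain is recovered exactly", {
  set.seed(5)
  x <- rnorm(60)
  m <- 0.9 * x + sqrt(1 - 0.81) * rnorm(60)
  y <- m                      # outcome is the mediator exactly
  d <- data.frame(g = x, M1 = m, reading = y)
  fit <- path_mediation(d, predictors = "g", mediators = "M1",
                        covariate = NULL, residual_pairs = list(),
                        cluster = "none")
  expect_equal(unname(fit$estimates$b[["M1"]]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$estimates$cp[["g"]]), 0, tolerance = 1e-10)
  expect_equal(unname(fit$estimates$a["M1", "g"]), cor(x, m),
               tolerance = 1e-10)
  expect_equal(fit$estimates$R2, 1, tolerance = 1e-10)
})

test_that("estimates are invariant to subject order", {
  co <- generate_cohort(small_config(), seed = 9)
  d <- mediation_data(co)
  f1 <- path_mediation(d)
  f2 <- path_mediation(d[sample(nrow(d)), ])
  expect_equal(f1$estimates$a, f2$estimates$a, tolerance = 1e-10)
  expect_equal(f1$estimates$b, f2$estimates$b, tolerance = 1e-10)
  expect_equal(f1$indirect$total, f2$indirect$total, tolerance = 1e-10)
})

test_that("configured paths are recovered on a large cohort", {
  cfg <- cohort_config(n_families = 1700, n_controls = 1200)
  co <- generate_cohort(cfg, seed = 19)
  fit <- path_mediation(mediation_data(co))
  expect_lt(abs(fit$estimates$a["RAP", "rs9853895"] - (-0.188)), 0.03)
  expect_lt(abs(fit$estimates$a["RTLI_b", "rs9853895"] - (-0.249)), 0.03)
  expect_lt(abs(fit$estimates$b[["RAP"]] - 0.298), 0.04)
  expect_lt(abs(fit$estimates$b[["RTLI_b"]] - 0.249), 0.04)
  expect_lt(abs(fit$estimates$cp[["rs9853895"]] - (-0.111)), 0.04)
  # age paths on the three covaried mediators
  expect_lt(abs(fit$estimates$age[["RAP"]] - 0.3), 0.04)
  expect_lt(abs(fit$estimates$age[["RAN_rt"]] - (-0.3)), 0.04)
})

test_that("total indirect effects are exactly the sum of specifics", {
  co <- generate_cohort(small_config(), seed = 29)
  fit <- path_mediation(mediation_data(co))
  ind <- fit$indirect
  expect_lt(max(abs(ind$total - colSums(ind$specific))), 1e-12)
  expect_lt(max(abs(ind$total_effect - (fit$estimates$cp + ind$total))),
            1e-12)
  expect_equal(ind$specific["RAP", "rs9853895"],
               fit$estimates$a["RAP", "rs9853895"] *
                 fit$estimates$b[["RAP"]])
  # all-zero b wipes out every indirect effect
  est0 <- fit$estimates
  est0$b[] <- 0
  expect_true(all(indirect_effects(est0)$specific == 0))
})

test_that("standardized estimates match an independent lm() route", {
  co <- generate_cohort(small_config(), seed = 39)
  d <- mediation_data(co)
  fit <- path_mediation(d, predictors = co$markers$marker,
                        covariate = NULL, residual_pairs = list())
  zd <- as.data.frame(scale(d[, c(co$markers$marker, ep_names(),
                                  "reading")]))
  for (m in ep_names()) {
    ora <- lm(stats::reformulate(sprintf("`%s`", co$markers$marker), m),
              data = zd)
    expect_equal(unname(fit$estimates$a[m, ]),
                 unname(coef(ora)[-1]), tolerance = 1e-10)
  }
  oy <- lm(stats::reformulate(sprintf("`%s`", c(co$markers$marker,
                                                ep_names())), "reading"),
           data = zd)
  expect_equal(unname(fit$estimates$b),
               unname(coef(oy)[ep_names()]), tolerance = 1e-10)
  expect_equal(unname(fit$estimates$cp),
               unname(coef(oy)[co$markers$marker]), tolerance = 1e-10)
})

test_that("collinear predictors raise an error naming the offenders", {
  co <- generate_cohort(small_config(), seed = 49)
  d <- mediation_data(co)
  d$dup <- d$rs9853895
  expect_error(path_mediation(d, predictors = c(co$markers$marker, "dup")),
               "dup")
})

test_that("bias-corrected intervals reduce to percentile ones when unbiased", {
  set.seed(59)
  reps <- rnorm(4000)
  est <- quantile(reps, 0.5)  # exactly half the replicates below the estimate
  bc <- epmediate:::.bc_interval(reps, est, 0.95)
  plain <- quantile(reps, c(0.025, 0.975), names = FALSE)
  expect_equal(bc, plain, tolerance = 1e-6)
  # and shift appropriately when the estimate sits off-center
  bc_lo <- epmediate:::.bc_interval(reps, quantile(reps, 0.3), 0.95)
  expect_true(all(bc_lo < bc))
})

test_that("the cluster bootstrap is seed-reproducible and stable", {
  co <- generate_cohort(small_config(), seed = 69)
  fit <- path_mediation(mediation_data(co))
  b1 <- cluster_bootstrap(fit, n_boot = 300, seed = 7)
  b2 <- cluster_bootstrap(fit, n_boot = 300, seed = 7)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$lower <= b1$upper))
  expect_equal(b1$significant, b1$lower > 0 | b1$upper < 0)
  b3 <- cluster_bootstrap(fit, n_boot = 300, seed = 8)
  expect_false(identical(b1$lower, b3$lower))
})

test_that("bootstrap uncertainty shrinks with the number of families", {
  small <- generate_cohort(cohort_config(n_families = 40, n_controls = 30),
                           seed = 79)
  big <- generate_cohort(cohort_config(n_families = 400, n_controls = 300),
                         seed = 79)
  bs <- cluster_bootstrap(path_mediation(mediation_data(small)),
                          n_boot = 200, seed = 1)
  bb <- cluster_bootstrap(path_mediation(mediation_data(big)),
                          n_boot = 200, seed = 1)
  se_s <- bs$boot_se[bs$type == "total" & bs$predictor == "rs9853895"]
  se_b <- bb$boot_se[bb$type == "total" & bb$predictor == "rs9853895"]
  expect_lt(se_b, se_s)
})

test_that("model methods expose coefficients, residuals and predictions", {
  co <- generate_cohort(small_config(), seed = 89)
  d <- mediation_data(co)
  fit <- path_mediation(d, n_boot = 150, seed = 2)
  cf <- coef(fit)
  expect_equal(unname(cf[["reading~RAP"]]),
               unname(fit$estimates$b[["RAP"]]))
  res <- residuals(fit)
  expect_equal(dim(res), c(fit$n, 6L))
  expect_lt(max(abs(colMeans(res))), 1e-10)
  pr <- predict(fit)
  expect_equal(length(pr), fit$n)
  expect_gt(cor(pr, d$reading), 0.4)
  ci <- confint(fit)
  expect_s3_class(ci, "boot_indirect")
  sim <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sim, 2)
  expect_equal(nrow(sim[[1]]), fit$n)
  expect_output(print(fit), "path model")
  s <- summary(fit)
  expect_s3_class(s, "summary.path_mediation")
  expect_output(print(s), "RMSEA")
  pdf(NULL)
  plot(fit)
  plot(fit, predictor = "rs9853895")
  dev.off()
})

test_that("missing data are dropped listwise with a message", {
  co <- generate_cohort(small_config(), seed = 99)
  d <- mediation_data(co)
  d$RAP[1:3] <- NA
  expect_message(fit <- path_mediation(d), "3 of")
  expect_equal(fit$n, nrow(d) - 3)
  expect_equal(fit$n_dropped, 3L)
})
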