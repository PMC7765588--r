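---
title: "Gene-endophenotype-reading mediation: model, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-endophenotype-reading mediation: model, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epmediate)
```

## The scientific problem

Developmental dyslexia aggregates in families and candidate genes have been
replicated, yet the route from a variant to poor reading is indirect.
Endophenotypes — heritable cognitive and sensory traits such as rapid
auditory processing (RAP), rapid automatized naming (RAN), multisensory
non-spatial attention and visual motion processing — are intermediate links:
a variant may shift an endophenotype, and the endophenotype in turn shifts
reading. `epmediate` operationalizes that chain as a
multiple-predictor/multiple-mediator path model over 20 biallelic markers
spanning *DYX1C1*, *DCDC2*, *KIAA0319*, *ROBO1* and *GRIN2B* (including the
READ1 microdeletion of *DCDC2* as a presence/absence marker), five
endophenotype scores, age as a covariate, and a reading composite, in a
cohort of nuclear families with affected probands plus unrelated controls.

## The path model

All variables are standardized before estimation, so every coefficient is a
standardized path. With coded genotypes $x_k$, mediators $m_j$
(order: WE, RTLI_b, RTLI_t, RAP, RAN_rt), age $z$ and reading $y$:

$$m_j = \sum_k a_{jk} x_k + d_j z + e_j, \qquad
  y = \sum_k c'_k x_k + \sum_j b_j m_j + e_y .$$

Age paths $d_j$ enter only for RTLI_b, RAP and RAN_rt (the mediators that
show developmental change within the school-age window); residual
covariances are freed for five endophenotype pairs — (WE, RTLI_b),
(RAP, RTLI_b), (RAP, RTLI_t), (RAP, RAN_rt), (RTLI_b, RTLI_t) — as a
collinearity control among correlated tasks. The specific indirect effect
of marker $k$ through mediator $j$ is the product $a_{jk} b_j$, the total
indirect effect is $\sum_j a_{jk} b_j$, and the identity
$\text{total} = \sum \text{specific}$ holds exactly (it is arithmetic, not
estimation).

**Estimation.** The system is recursive with observed variables only, so
the maximum-likelihood point estimates coincide with equation-wise least
squares: each mediator is regressed on all predictors (plus age where the
edge exists) and the outcome on all predictors and mediators. We estimate
by QR-based least squares per equation, which is transparent and fast
enough to live inside a bootstrap loop; residual variances and the declared
residual covariances are taken from the equation residuals (denominator
$n-1$, consistent with the sample covariance).

**Inference.** Families are the sampling units, so ordinary bootstrap
resampling of subjects would understate uncertainty. `cluster_bootstrap()`
resamples whole families with replacement, keeping the number of clusters
fixed at the original count; unrelated controls are singleton clusters.
Every replicate is re-standardized and refit, because standardized
coefficients are functions of the replicate's own scales. Intervals are
*bias-corrected* (BC) percentile intervals: with
$z_0 = \Phi^{-1}\{\Pr(\hat\theta^* < \hat\theta)\}$ the bounds are the
$\Phi(2z_0 \mp z_{\alpha/2})$ percentiles of the replicate distribution. We
deliberately use BC, not BCa — no acceleration term — and resample clusters
only (no second-stage resampling within families), the standard cluster
bootstrap. A replicate in which a coded marker becomes constant or an
equation rank-deficient is counted as failed and dropped; more than 5%
failures warns, more than 25% is an error. The proportion defining $z_0$ is
clamped to $[1/2B,\ 1-1/2B]$ so a point estimate outside the replicate
range cannot produce an infinite correction.

**Missing data** are removed listwise with a reported count; the reference
analyses for this design do not state a missing-data model, and listwise
deletion is the simplest defensible choice for a complete-case covariance
model.

## Genotype handling

Minor alleles are determined from observed frequencies (ties broken
lexicographically, with a message); frequencies for the coding rule are
computed on unrelated subjects only (probands plus controls), because
sibling genotypes are correlated and would distort the estimate. Markers
with MAF at or above 0.35 (inclusive) keep the additive 0/1/2 dosage —
"additive model" implies a linear dose effect, so dosage enters as one
numeric predictor, not two dummies; rarer markers are coded by
presence/absence of the minor allele, which also absorbs the READ1
microdeletion (MAF ≈ 0.078, always presence/absence).

Hardy-Weinberg equilibrium is tested by the $\chi^2$ statistic on 1 df
against expected proportions $p^2, 2pq, q^2$ at the estimated allele
frequency; this matches the smooth p-values conventionally reported for
panels of this kind. An exact (conditional) test is available via
`hwe_test(..., method = "exact")` for small counts. Screening thresholds
are Bonferroni-corrected per gene ($0.05/m$ for $m$ markers in the gene).
Monomorphic markers return $p = 1$ with a warning — the test is undefined.

## Endophenotype scoring

* **RAP** (temporal order judgment): accuracy (%) per inter-stimulus
  interval (20/40/80/120/280 ms, 8 trials each, chance 50%); per ISI the
  sample's 25th/75th accuracy percentiles define codes 1 (≤ P25),
  3 (≥ P75), 2 (between). Percentiles use linear interpolation between
  order statistics (`quantile` type 7, the common default; no estimator is
  canonical for this task). The rule order — "≤ P25" tested first —
  resolves degenerate distributions where the quartiles coincide (everyone
  codes 1, with a warning). The subject's score is the **mean** of the five
  ISI codes: the per-ISI coding is defined by the task, but no aggregate is
  canonical; the mean is the natural single score and keeps the 1–3 scale.
* **RAN**: mean vocal RT over correct trials after excluding RTs > 1000 ms,
  then z-scored within the sample ("normalized" is read as the plain
  z-score, the minimal reading).
* **Warning effect**: response RTs outside [150, 1500] ms are excluded;
  per SOA the composite is the mean of the four modality × validity cell
  means and WE = composite(250) − composite(100), in ms. Negative WE means
  faster responses at the long SOA.
* **RTLI**: perceived-rotation proportions at 11 contrast levels (0–10%,
  5 presentations each) are fitted by least squares with the two-parameter
  logistic $y = 1/(1+e^{-b(x-t)})$, bounds fixed at 0 and 1, $b > 0$.
  The slope is then log-transformed and the threshold square-root
  transformed for distributional acceptability; transform provenance is
  recorded. Age adjustment is *not* applied at scoring time — age travels
  with the table and enters the path model as a covariate.
* **Reading composite**: each of up to six reading measures (text, word and
  pseudo-word reading; speed and accuracy) is z-scored within the sample —
  error counts sign-flipped so higher always means better — and averaged.
  Within-sample z-scores stand in for grade norms, which are instrument-
  and language-specific and not portable.

## Psychometric fitting: numerical choices

The RTLI least-squares criterion is non-convex, so `fit_rtli()` multi-starts
a box-constrained quasi-Newton search over a coarse grid (5 slopes ×
5 threshold quantiles), then polishes the best solution with an
unconstrained simplex refinement. Convergence code 52 from the bounded
optimizer is accepted when the minimum is already attained to machine
precision. Flat response curves (all 0 or all 1) are flagged non-converged
with missing parameters — the threshold is unidentified there. A practical
caveat measured during validation: with only 5 binomial draws per level the
least-squares *slope* is median-biased upward by roughly +17% (the
threshold is essentially unbiased); slope-based analyses should use the log
transform (which the pipeline applies anyway) and more presentations where
possible.

## Fit indices and degrees of freedom

The implied covariance propagates the fitted paths through the system, with
the exogenous block (genotypes, age) left free at its sample covariance.
Fit uses the ML discrepancy
$F = \ln|\Sigma| - \ln|S| + \operatorname{tr}(S\Sigma^{-1}) - p$,
$\chi^2 = (n-1)F$; RMSEA $=\sqrt{\max(\chi^2-df,0)/(df\,(n-1))}$ with a 90%
interval from noncentral-$\chi^2$ inversion; CFI against the independence
baseline with free variances (the universal convention); SRMR over
standardized residual covariances with the diagonal included (a no-diagonal
dialect is flag-selectable). The $(n-1)$ multiplier is the default, with
`n_convention = "n"` exposed because software dialects differ.

Degrees of freedom are counted as observed moments minus free parameters.
For the default model — 20 predictors + age free exogenous block, 100
gene→mediator paths, 3 age edges, 20 direct paths, 5 mediator→outcome
paths, 6 residual variances, 5 residual covariances — this gives **df = 8**,
which is also the value at which the power analysis below is conducted.

## Post-hoc power

* `rmsea_power()` uses the noncentral-$\chi^2$ construction: population
  RMSEA $\varepsilon$ induces noncentrality
  $\lambda = (n-1)\,df\,\varepsilon^2$; power is the probability that the
  statistic exceeds the upper-$\alpha$ quantile under the null RMSEA. The
  default null is **exact fit** ($\varepsilon_0 = 0$): at df = 8, n = 302,
  $\varepsilon = 0.087$ this yields power ≈ 0.88, consistent with the >80%
  benchmark; a close-fit null ($\varepsilon_0 = 0.05$) would fall below
  0.80 and is available through the `rmsea0` parameter for sensitivity.
* `mediation_power_joint()` computes the power of the joint-significance
  rule (both the $a$- and $b$-path tests reject at two-sided $\alpha$) from
  standardized-coefficient standard errors,
  $SE(a) = \sqrt{(1-a^2)/(n-2)}$ and
  $SE(b) = \sqrt{(1-R^2_Y)/((n-3)(1-a^2))}$ with
  $R^2_Y = b^2 + c'^2 + 2abc'$. At the published path pairs
  (−0.188/0.298 and −0.249/0.249, $c' = -0.111$, n = 302) both powers
  exceed 0.90. A Monte-Carlo mode (`n_sim`) verifies the analytic
  approximation (agreement within 2% at typical design points). Note the
  product form uses one-tailed rejection factors: when a path is exactly
  zero its factor is $\alpha/2$, not $\alpha$.

## The synthetic cohort generator

`generate_cohort()` draws the study conditions: 100 nuclear families
(offspring count 2–3, weighted so the mean is ≈ 2.23, reproducing ≈ 223
offspring per 100 families) plus 79 unrelated controls, ≈ 302 subjects in
all; 20 markers at the panel's published minor-allele frequencies under
Hardy-Weinberg proportions. Sibling genotypes come from explicit parental
simulation — two parental genotypes per family, transmitted Mendelianly —
so the family clustering the bootstrap relies on is genetically real, not
merely a label. Ages are uniform over 7–14 years (the age distribution of
such cohorts is not published; a uniform school-age window is the neutral
choice) and standardized by their theoretical moments.

Mediators and outcome follow the linear-Gaussian structural model above —
matching the model's own assumptions — with standardized defaults taken
from the reference effect sizes: gene→RAP = −0.188 and gene→RTLI_b = −0.249
for ROBO1-rs9853895, mediator→reading 0.298 (RAP) and 0.249 (RTLI_b),
direct path −0.111; all other gene paths zero. Age paths default to +0.3
(RAP), +0.2 (RTLI_b), −0.3 (RAN_rt): moderate maturation effects with the
signs developmental data require (faster naming and better temporal
processing with age); their magnitudes are not published and were fixed
once at plausible values. Residual correlation among the five freed
mediator pairs defaults to 0.2, and a within-family intraclass correlation
of 0.2 is applied to the residual of every mediator and the outcome —
familial residual sharing is not quantified in the reference design, and
0.2 is a typical value for cognitive traits in nuclear families. Every
equation's variance budget is validated at construction: a configuration
whose paths imply negative residual variance is rejected with the offending
equation named.

`emit_trial_data()` inverts the scoring pipeline: latent mediator values
are mapped to natural task scales (e.g. naming RT 600 ± 90 ms between
subjects, 80 ms within; illusion slope log-normal around 1.2; warning
effect −20 ± 30 ms) and trial tables are drawn so that scoring recovers the
latent values up to trial sampling noise. "Noiseless" RTLI emission writes
expected counts (continuous), which the fit inverts exactly; rounding
responses to 0/1 would destroy the slope information. At ten times the
battery's real trial counts, scored and latent values correlate above 0.9
for every mediator.

**What the generator does *not* emulate:** linkage disequilibrium between
markers (markers are independent; real panels have LD blocks within genes),
ascertainment (controls are drawn from the same structural model as family
members rather than from a separate typical-reader distribution),
non-Gaussian residuals, genotyping error and informative missingness.
Passing tests therefore demonstrate internal consistency of the estimator
and its inference under the model's own assumptions — not robustness to
violations real cohorts may exhibit.

## Validation design and problem sizes

The test suite checks, among others: exact recovery of noiseless systems;
equality of the equation-wise estimates with an independent `lm()` route to
1e-10; the additivity identity to 1e-12; Hardy-Weinberg $\chi^2$ against a
brute-force implementation on 1000 random count triples to 1e-10;
implied-covariance entries against a $10^6$-draw simulation oracle;
the closed-form 2×2 ML discrepancy; and seed-reproducibility of the
bootstrap. Calibration properties use 500 null cohorts × 500 bootstrap
replicates (type-I behaviour, on a reduced four-marker panel to isolate the
property) and 200 effect-size cohorts × 500 replicates (coverage of the
true specific indirect effect, observed ≈ 94–95%); these sizes give
binomial Monte-Carlo error well under the decision margins while keeping
the suite comfortably runnable on one CPU.

## Known limitations

* Under a *complete* null (both paths of a product zero), interval-based
  tests of $a b$ — the BC bootstrap included — reject far below the nominal
  rate (≈ 1% at the 95% level in our calibration), because both factors
  must look nonzero simultaneously. This conservatism is intrinsic to
  product-of-coefficients inference, well documented in the mediation
  literature, and not a defect of the clustering; rejection approaches the
  nominal rate only when one path is large.
* Clustering is handled by the bootstrap alone; no robust (sandwich)
  standard errors are offered, and latent-variable measurement models,
  moderated mediation and haplotype analyses are out of scope.
* The fit statistic uses the OLS/ML point estimates with a free exogenous
  block; for severely non-normal data the $\chi^2$ calibration inherits the
  usual ML caveats.
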