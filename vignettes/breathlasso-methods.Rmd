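---
title: "Methods: adaptive-LASSO discriminant models for breath volatile compounds"
author: "breathlasso authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-LASSO discriminant models for breath volatile compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific setting

Ion-molecule-reaction mass spectrometry (IMR-MS) can quantify, within
seconds and without chromatographic separation, on the order of a hundred
volatile compounds (VCs) in a 20 mL vial of end-expiratory ("alveolar")
breath. A case/control panel of such measurements is a classic
small-n/large-p problem: roughly 25--50 subjects per clinical group against
~95 measured compounds, most of which carry no disease signal, with
concentrations spanning five orders of magnitude (low ppb for trace masses
to thousands of ppb for acetaldehyde or N2O) and strongly right-skewed
within-group distributions.

`breathlasso` implements the full discriminant workflow for such panels:
sample- and compound-level quality control, an iterated adaptive-LASSO
logistic regression for variable selection and coefficient estimation,
bootstrap percentile intervals, and ROC-based evaluation including the
paired DeLong test for comparing correlated ROC areas. A synthetic cohort
generator, parameterized from published group summary tables, makes the
whole pipeline exercisable and testable without access to patient-level
data.

## Quality control

**Alveolar-origin check.** A breath sample whose CO2 concentration is below
2% either was not sealed airtight or did not capture the end-expiratory
fraction; such samples are discarded. The comparison is strict: a sample at
exactly 2.0% passes. The threshold is a `filter_co2()` argument (percent
CO2, default 2).

**Environmental contamination.** For each compound we compare the paired
room-air measurement (one environmental vial collected alongside each
subject's breath sample, same room and time) with the alveolar
measurement, using a paired two-sided t-test on the per-subject
differences. A compound is excluded only when the environmental mean
*exceeds* the alveolar mean and the test is significant at `alpha`
(default 0.05); the exclusion is deliberately one-directional, since a
compound higher in breath than in room air is informative regardless of
significance. The test variant is a design choice: the sampling design
pairs each environmental vial with a subject, so a paired test is the
natural match; a two-sample variant would discard that pairing. No
multiplicity correction is applied -- the screen is deliberately
conservative about keeping compounds, and `alpha` is configurable. With
fewer than three complete pairs the test is undefined and the compound is
retained with a warning.

**Standardization.** All predictors entering the penalized fits --
retained compounds plus age (years) and sex (0 = female, 1 = male) -- are
centered and scaled to unit sample SD, so one penalty treats ppb-scale and
demographic variables symmetrically. Whether demographic covariates should
be penalized on the same footing as compounds is genuinely open; we chose
uniform treatment for penalty fairness and report coefficients on both the
standardized and the original scales (`original_scale_coefficients()`
maps between them). Constant columns are rejected by name.

## The penalized model

The core fit minimizes the weighted-L1 penalized negative binomial
log-likelihood

$$
-\sum_{i=1}^n \left[ y_i \eta_i - \log(1 + e^{\eta_i}) \right]
\;+\; \lambda \sum_j w_j \lvert \beta_j \rvert,
\qquad \eta_i = \beta_0 + x_i^\top \beta ,
$$

with an unpenalized intercept. With unit weights this is the LASSO; with
$w_j = 1/\lvert \hat\beta_j \rvert$ from a preliminary fit it is the
adaptive LASSO, whose re-weighting preserves strong effects while pushing
weak ones to exactly zero (the oracle-selection property of iterated
procedures in sparse settings). A variable with infinite weight is a hard
exclusion: its coefficient is exactly zero by construction.

**Objective scaling.** The penalty acts against the *sum* log-likelihood,
not the mean. This is the convention of the penalized-likelihood software
family in which tuning parameters of magnitude 1--10 are typical for
cohorts of 50--150 subjects; a mean-scaled penalty of that magnitude would
annihilate every coefficient at these sample sizes. `lambda` values in
this package are therefore directly comparable to the λ ≈ 4.35 scale
familiar from published breath-panel models, and convert to the mean-scaled
convention of `glmnet` by division by $n$.

**Algorithm.** Cyclic coordinate descent on an iteratively reweighted
least-squares (IRLS) quadratic majorization, with soft-thresholding
updates, exact zeros, warm starts along the penalty path, and an
active-set sweep strategy (full sweep, then iterate the nonzero set).
Convergence is declared when the true-gradient KKT residual falls below
`kkt_tol` (default 1e-8) or, for capped/degenerate fits, when the largest
coefficient change over a re-linearization drops below `thresh` (default
1e-7); the cycle budget is 10^4. Every fit can be audited with
`check_kkt()`: uncapped converged fits satisfy the stationarity conditions
to well below 1e-6. IRLS variance weights are floored at 1e-10, and
standardized coefficients are capped at |β| ≤ 30 with a warning, since
complete separation is a real possibility at n below 100 -- a capped fit
signals separation, not a numerical failure.

**Penalty selection.** `cv_penalized_logistic()` minimizes k-fold
cross-validated binomial deviance over a 50-point log-spaced grid spanning
three decades below `lambda_max()` (the smallest penalty with an all-zero
solution, $\max_j |x_j^\top(y-\bar y)|/w_j$). Folds are stratified by
outcome and seeded; k defaults to 50, degrading to leave-one-out when n <
k. Exact ties in the CV curve are broken toward the smallest lambda among
the minimizers, a deterministic rule (exact ties essentially never occur;
the fold-level activation penalties differ from the full-data one, so the
top of the curve is not flat).

**A caveat worth knowing.** Deviance-minimizing CV at p ≈ n admits at
least one spurious variable in roughly half of null-outcome realizations:
the CV curve dips slightly below its value at `lambda_max` by chance. We
verified this is a property of the criterion, not of this implementation,
by cross-checking against an independent penalized-regression
implementation on identical data (selected penalties agreeing within a few
percent and variable counts matching). Consequently the *in-sample* AUC of
a pipeline run on outcome-independent data has a median around 0.6--0.65
rather than 0.5: a single admitted noise variable yields an apparent AUC
near 0.65 however small its coefficient. In-sample evaluation of a
selected model is optimistic by construction; see "Evaluation" below.

## The iterated pipeline

`fit_iterated()` runs the three-stage procedure:

1. **Screening LASSO** (unit weights, CV-selected λ): variables with zero
   coefficients are eliminated; the survivors pass on *by name only*.
2. **Weight-generating LASSO** on the screened set (unit weights, fresh
   CV): its coefficients define the adaptive weights
   $w_j = 1/|\hat\beta_j|$ (standardized scale -- the penalty operates on
   the standardized problem).
3. **Adaptive LASSO** on the screened set with those weights (fresh CV):
   the final model.

Age and sex are eligible at every stage and are never forced in. Stage
seeds derive deterministically from the configured seed (`seed`,
`seed + 1`, `seed + 2`), making the whole pipeline bit-for-bit
reproducible given data, configuration and seed. Screening can be
disabled, which reduces the procedure to a single adaptive LASSO on the
full panel.

**Bootstrap intervals.** `bootstrap_cis()` draws outcome-stratified
resamples and refits *from the weight-generating stage*: the screened set
stays fixed, adaptive weights are recomputed per resample, and the
stage-2/adaptive penalties are held at their full-data CV selections.
Re-selecting λ inside every resample would multiply cost ~50-fold while
changing little beyond adding CV noise to the intervals; holding λ fixed
is the package's documented choice. Percentile 2.5%/97.5% intervals are
taken on the original measurement scale; a variable absent from a
resample's model contributes zero to that resample, so intervals for
weakly-selected variables naturally cover zero. The default B = 200 is a
compromise: percentile quantiles from fewer than ~100 resamples are
unstable (a 10-resample variant exists for strict procedure replication
but is not recommended). These are selection-conditional intervals: the
screening stage was chosen on the same data, so coverage for weak effects
is below nominal -- simulation with a strong generating effect shows
~90% empirical coverage of 95% intervals.

## Evaluation

`roc_analysis()` uses the classification rule *p ≥ threshold → case*, so
the smallest observed probability always yields 100% sensitivity, matching
how published operating tables are laid out. The AUC is the Mann--Whitney
statistic with ties counted ½ and its standard error comes from DeLong
placement values; reported 95% intervals are the normal approximation from
that SE (a bootstrap interval would also be defensible; the choice is
labelled in the output). `performance_table()` reports percentages as
`round(100 * count / n, 2)` together with the integer counts, the exact
arithmetic of published sensitivity/specificity tables.
`delong_test()` implements the paired test for correlated ROC areas via
the placement-value covariance, referring the squared standardized AUC
difference to χ²(1). `standardized_profile()` expresses patient-group
compound means in control-SD units, the construction behind published
profile figures.

Evaluation is **in-sample** (apparent performance), matching the published
tables this workflow reproduces; there is deliberately no nested
cross-validation layer, and apparent AUCs of selected models should be
read with the optimism caveat above. A seeded train/test split can be
built by the user with `build_design()` on subject subsets.

## The synthetic cohort generator

The generator emulates the study conditions the analysis assumes.

* **Distribution family.** Concentrations are positive and every published
  group summary but four shows mean > median (right skew), so compounds
  are log-normal: `lognormal_from_summary()` matches location and scale to
  a printed median/mean pair exactly via $\mu = \ln(\text{median})$,
  $\sigma = \sqrt{2\ln(\text{mean}/\text{median})}$. Printed ranges are
  used only as a sanity check, not fitted; for the four table cells where
  the printed mean sits marginally *below* the median (acetic acid and
  ammonia in the lung-adenocarcinoma cases, N2O in controls and in
  colon-adenocarcinoma cases) -- which no log-normal can reproduce -- the
  scale falls back to the printed min--max range through the expected
  extremes of n normal draws (Blom's approximation). The fallback is
  deterministic and fixed once.
* **Groups.** 45 controls, 36 lung adenocarcinoma, 25 lung squamous cell
  carcinoma, 52 colon adenocarcinoma (158 subjects); ages uniform over
  each group's printed range; sex Bernoulli with each group's published
  male proportion (only medians and ranges are published, so a uniform age
  model is as much structure as the sources support).
* **Panel.** 95 compounds: the 23 model-selected compounds named in the
  published summary tables carry the case/control differences; 11
  synthetic compounds (benzene, toluene and nine mass-only labels -- the
  published source does not name its excluded set) carry environmental
  background above alveolar levels (`env_factor` 3) so the QC stage
  re-derives the 95 − 11 = 84 arithmetic; the remaining 61 are null
  compounds with identical distributions in every group, on a fixed
  log-spaced ladder of medians (2--2000 ppb) with log-scale 0.6 (a
  mean/median ratio ≈ 1.2, typical of the printed tables).
* **Environmental air** is `env_factor · exp(log_mu)` with independent
  log-normal noise (σ = 0.3): one room-air record per subject,
  independent of that subject's breath, which is what a paired
  contamination test assumes under the null of no shared room effect.
* **CO2** is truncated-normal (mean 4.5%, SD 0.8%); a configurable
  `qc_fail_fraction` draws that share of samples below the 2% threshold
  (default 0 -- published cohort counts are post-QC).
* **Independence.** Compounds do not co-vary within a subject; the
  sources publish no covariance information, and inventing correlation
  structure would manufacture untestable claims. Real breath panels do
  co-vary (shared metabolic origins, instrument cross-talk between
  adjacent masses), so passing tests on these cohorts demonstrate
  correctness of the *procedure*, not expected field performance; no
  within-subject replicate variance or batch/room effects are simulated
  either, and the two exhalations collected per subject in the field
  collapse to the one record per subject that the published analyses use.

## Problem sizes used by the test suite

The packaged tests exercise: solver-vs-oracle equivalence on 50 random
instances (n ≤ 40, p ≤ 6, objective agreement 1e-6, KKT 1e-6); the full
pipeline on 20 seeded cohorts per contrast at the published group sizes
(in-sample AUC medians, selection-frequency rank tests); 20 seeded null
pipelines; DeLong-vs-permutation agreement on 20 instances of 40 subjects
(10^4 swaps); and bootstrap coverage over 50 repeats at n = 150, B = 200.
These sizes were chosen as the smallest at which each property is
statistically decisive.

## Known limitations

* In-sample AUC of a CV-selected model is optimistic; see the caveat
  above. The package reports it because that is the published convention
  it mirrors.
* Bootstrap intervals are selection-conditional (screened set fixed).
* The generator's independence and log-normality assumptions are
  idealizations; heavy upper tails in a few published ranges (e.g. a case
  maximum 17× the mean) are not reproduced, as no two-parameter family
  matches median, mean and such extremes simultaneously.
* The exclusion set of environmentally-dominated compounds, and therefore
  the exact identity of the 11 excluded labels, is a synthetic choice.
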