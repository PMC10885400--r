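---
title: "Building and evaluating a VTE risk score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating a VTE risk score: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vterisk)
```

# The problem

Ninety-day venous thromboembolism (VTE) after minimally invasive radical
prostatectomy is a rare event — on the order of 1% in prophylaxis-naive
men — so a cohort of several hundred patients yields only a handful of
cases. Two methodological problems follow. First, converting a flexible
risk model into a simple additive integer score requires reproducible
rules for which variables enter, how many points each carries, and where
its threshold sits. Second, choosing a high-/low-risk cut-point from
half a dozen positive cases by any single-sample rule is extremely
unstable. This package implements one complete answer to both problems
and the machinery to evaluate it.

# The score-construction procedure

1. **Model.** A gradient-boosted ensemble of shallow decision trees is
   fit to the binary outcome with binomial-deviance loss
   (`fit_brt()`). The outcome is binary, so deviance rather than
   squared error is the natural boosting loss. Defaults
   (`brt_hyperparams()`): 500 trees, interaction depth 3, learning rate
   0.05, row subsampling 0.75, fixed seed. These are conventional
   boosted-tree settings for tabular clinical data — enough trees for a
   small learning rate to converge, shallow trees because main effects
   plus low-order interactions are all a cohort with tens of events can
   support. All are overridable; none is tuned automatically.

2. **Relative influence.** Each variable's importance is its share of
   the total split gain across the ensemble, normalised to sum to 100
   (`relative_importance()`). This is the classical "relative
   influence" of boosted regression trees, not permutation importance:
   it is what the banding rule below is defined on.

3. **Banding.** Importances are mapped to points by a step function
   (`band_points()`): strictly above 30 → 5 points, above 20 → 4,
   above 10 → 3, above 1 → 2; variables not strictly above the lowest
   bound are omitted. "Above" is strict everywhere, so a variable at
   exactly the bound falls through to the next band (or to omission at
   the lowest bound). The reference system's Gleason rule illustrates
   the boundary: with importance exactly 1 it is not banded, and enters
   instead as a *forced* one-point rule motivated by external clinical
   evidence. Forced rules are first-class: they are appended after
   banding and override any banded rule on the same variable.

4. **Thresholds.** Each retained variable needs a cut value for its
   scoring condition `x > t`. Reading thresholds off partial-dependence
   plots by eye is not reproducible, so `select_threshold()` automates
   it: the threshold is the grid value at the left edge of the largest
   single-step increase of the partial-dependence curve, i.e. the last
   value *before* the modelled risk jumps — which matches the strict
   `>` form of the conditions. Ties are broken toward the smallest grid
   value (steps within a 1e-9-of-range sliver of the maximum count as
   tied, so exactly linear curves resolve deterministically rather than
   by floating-point noise). Thresholds are rounded to the variable's
   natural resolution (whole days, years, ng/mL, kg/m²) by default. A
   flat or decreasing curve carries no threshold signal: the function
   returns `NA` and `build_scoring_system()` falls back to a configured
   default (the pipeline uses the rounded training median) or fails
   naming the variable.

5. **Scoring.** A patient's score is the sum of points over satisfied
   conditions (`score_patient()`, `score_cohort()`); boundary values
   score zero for their rule. Missing covariates follow a configurable
   policy: `"strict"` (error; the default, since silent zeroing can
   mask data problems) or `"zero"` (condition unmet). Real cohorts of
   this kind contain "unknown" entries, and no universal convention
   exists for scoring them, hence the explicit switch.

The nine-rule reference system (`preset_scoring_system()`; maximum
total 24) is shipped as a preset so the downstream stages can be used
and tested independently of model fitting.

# The simulation-based cut-point

`simulation_cutoff()` draws B resamples of size m, with replacement,
from the positive patients' scores, computes the lower p-quantile of
each resample and averages. Defaults B = 10,000, m = 5, p = 0.025 —
10,000 resamples makes the Monte-Carlo standard error (reported as
`mc_se = sd/√B`) about 0.02 score points on the worked six-score
example, negligible at the one-decimal scale of a cut-off.

Numerical conventions worth stating:

* **Quantile interpolation.** The default is the Hyndman–Fan type-7
  linear order-statistic rule (R's `quantile()` default): with sorted
  resample x(1..m) and h = (m−1)p, q = x(⌊h⌋+1) + (h−⌊h⌋)(x(⌊h⌋+2) −
  x(⌊h⌋+1)). At m = 5, p = 0.025 this weights the two smallest order
  statistics 0.9/0.1. The inverse-CDF ("nearest") rule is exposed as an
  alternative (`quantile_spec(interpolation = "nearest")`), under which
  the estimator reduces to the expected minimum. On the worked example
  the exact expectations are 6.178 (linear) and 5.957 (nearest).
* **Exact oracle.** `exact_expected_quantile()` enumerates all n^m
  equally likely ordered resamples (chunked, with a 1e7 cap) and returns
  the exact expectation the simulation converges to. The test suite
  checks |simulation − exact| ≤ 3·mc_se across 20 seeds, and that mc_se
  halves when B quadruples.
* **Resampling is with replacement.** Size-5 subsets of six patients
  without replacement would be near-exhaustive (six of them), making
  10,000 resamples meaningless.
* **Degenerate inputs.** A single score, or all-equal scores, give the
  estimator exactly that score with zero Monte-Carlo error; an empty
  positive set is a domain error (the pipeline raises an explicit
  cannot-calibrate error rather than crashing).

**Calibration.** The simulated cut-off is then checked against the
observed positives (`calibrate_cutoff()`): if any positive scores below
it, the cut-off is lowered to the minimum positive score, so the final
rule classifies every observed case high-risk. The operation is
idempotent and never raises a cut-off. On the worked example the
simulated 6.2 is lowered to 5 because one positive scored 5.

**Comparators.** `youden_cutoff()` scans all distinct observed scores
(high-risk ⇔ score ≥ threshold) and maximises J = sensitivity +
specificity − 1, ties toward the smallest threshold (favouring
sensitivity, the clinically safer direction for a screening cut-off).
`bootstrap_cutoff()` averages the Youden threshold over stratified
(within-class) bootstrap resamples, preserving the tiny positive class
in every resample.

# Evaluation

`auc()` is the Mann–Whitney probability of correct pairwise ranking,
computed from mid-ranks (ties get half credit); `roc_points()` sweeps
the distinct thresholds and its trapezoidal area equals the
Mann–Whitney value identically, which the tests assert on random tied
instances. `auc_ci()` is a stratified bootstrap percentile interval
(default B = 2000) — stratification is what keeps the interval
well-defined with six positives, and the percentile method makes no
normality assumption a 24-point discrete score would violate.
`confusion_metrics()` uses the same score ≥ cut-off convention and
returns `NA`, not 0, for rates with empty denominators.
`compare_groups()` follows small-sample clinical-table convention:
Fisher's exact test for categorical variables (chi-square fallback for
large sparse tables), Wilcoxon rank-sum for continuous ones.

## Which ROC the pipeline reports

`run_pipeline()` reports two discrimination summaries on the held-out
split: the fitted boosted-tree model's predictions (`roc`, the primary
summary) and the integer score (`score_roc`). They answer different
questions — how well the *model* separates cases, and how much of that
survives discretisation into nine integer rules. On the synthetic
cohorts the model attains held-out AUC ≈ 0.96–0.98 while the
automatically built score sits lower (≈ 0.75–0.87): with a smooth,
convex risk signal the largest partial-dependence jump tends to sit in
the upper covariate tail, so automated thresholds are more extreme than
hand-picked ones would be. Reporting both makes that gap visible
instead of hiding it. Confusion metrics at the calibrated cut-off are
always computed from the score, which is the deliverable.

# The synthetic cohort generator

`generate_cohort()` exists so that every stage is testable on data with
known structure. It emulates a prophylaxis-naive minimally-invasive
prostatectomy population:

* **Marginals** (per-covariate, independently drawn): age from a
  discretised beta(3.5, 2) on [42, 79] (median ≈ 66); BMI drawn
  category-first (0.5% underweight / 25% normal / 45% overweight /
  29.5% obese) with uniform or shifted-exponential values inside each
  band, so category frequencies are exact in expectation; Gleason
  multinomial ≈ (8.4, 66, 9.6, 15, 1)% over grades 6–10; PSA and
  prostate volume lognormal; first-admission duration 1 + negative
  binomial(size 1.5, μ 2.2), giving P(stay ≥ 5 d) ≈ 0.22; counts
  Poisson; binary flags Bernoulli. All parameters are overridable and
  validated with the offending covariate named.
* **Outcome model**: logistic, `logit P(VTE) = β₀ + Σ βⱼ zⱼ`, with
  covariates standardised by *fixed* reference centres and scales
  (round-number summaries of the default marginals). Fixing the
  standardisation makes a record's event probability a pure function of
  its covariates (`event_probability()`), so monotonicity — raising a
  positively weighted covariate never lowers risk — holds exactly.
* **Default effects** put 1.4 / 1.2 / 1.0 log-odds per reference SD on
  duration of first admission, PSA and BMI, with small effects (0.2–0.4)
  on age, clotting and neurological disease, comorbidity count and METS
  score. The top-three concentration mirrors the importance ordering the
  score construction is meant to recover, and the implied generative
  discrimination (AUC of the true linear predictor ≈ Φ(σ/√2) ≈ 0.94)
  matches the strong-discrimination regime reported for scores of this
  kind.
* **Intercept calibration** (`calibrate_intercept()`): with all effects
  zero the closed form `qlogis(target)` (≈ −4.499 at 1.1%); otherwise
  bisection on a fixed-seed 200,000-draw Monte-Carlo estimate of mean
  event probability, to tolerance 1e-5, with a calibration error when
  the target is unreachable. Bisection is distribution-free and, with
  the frozen internal sample, fully deterministic.
* **Prophylaxis** is drawn as an independent Bernoulli (default
  118/640) and deliberately *excluded* from the outcome model; the
  pipeline by default restricts analysis to prophylaxis-naive patients,
  matching the subgroup in which the headline incidence is defined. The
  generator itself takes no stance on which denominator a modeller
  should use.

**What the generator does not emulate** — and hence what passing tests
do and do not show. Covariates are independent (real BMI, comorbidity
and stay durations are correlated); there is no time-to-event structure
and no competing mortality (vital status is an independent Bernoulli);
the outcome is exactly logistic-linear in standardised covariates, with
no interactions or threshold effects unless a test constructs them.
Green tests therefore demonstrate that the machinery recovers known
structure under clean conditions — parameter recovery, calibration,
oracle agreement — not that the reference score generalises to any real
population; that question needs real cohorts.

# Problem sizes used in the test suite

Stochastic properties are checked at sizes chosen to give the relevant
checks comfortable power while keeping the suite quick: importance
recovery and held-out discrimination at n = 5000 over 20 seeded fits
(about 50 events per cohort); the permutation-null contrast at n = 2500
over 10 paired fits; prevalence calibration over 50 cohorts of n = 5000;
AUC-CI coverage over 50 replicates of n = 500 with B = 1000. The full
suite runs in under two minutes on one CPU.

# Known limitations

* Importance banding depends on the influence *scale*, which shifts
  with hyperparameters; the bands are fixed constants, so rebanding
  after aggressive hyperparameter changes deserves inspection.
* The automated threshold rule is faithful to "largest jump" but, on
  smooth convex risk signals, selects more extreme thresholds than
  manual curve reading would (see the ROC discussion above).
* The simulation cut-point's m is a free parameter; as m grows the
  lower quantile of a resample drifts toward the minimum positive
  score, so m should be read as part of the estimator's definition, not
  tuned.
* `exact_expected_quantile()` is exponential in m (n^m enumeration) and
  capped at 1e7 tuples; beyond that, only the Monte-Carlo estimator is
  available.
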