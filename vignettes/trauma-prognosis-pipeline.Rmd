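---
title: "Methods: trauma prognosis from diagnostic text, composite AIS and tabular learners"
author: "traumaprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trauma prognosis from diagnostic text, composite AIS and tabular learners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In-hospital prognosis of severe trauma is a three-class problem (cure /
improvement / poor prognosis) over heterogeneous admission data: free-text
diagnoses, per-region Abbreviated Injury Scale (AIS) grades, vitals,
laboratory panels and categorical symptoms/treatments. `traumaprog`
implements a complete, seeded analysis pipeline for this setting — scoring
the text, compressing the regional AIS grades into composite severity
scores, screening candidate predictors, and fitting both an interpretable
stepwise logistic model (with a nomogram) and a benchmarked panel of
machine-learning classifiers. A synthetic-cohort generator stands in for
registry data, so every stage is exercised and tested end to end without
access to patient records.

## Diagnostic-text scoring

Each diagnosis field (main diagnosis, other diagnoses) has its own keyword
library of $J = 7$ modules (head/brain, neck, thorax, abdomen, limb/pelvic
fracture, spine/spinal cord, multiple injuries for the main field; a
complication-oriented set for the other field). For patient $i$ the score is

$$F_i = \sum_{j=1}^{7} \delta_j\, N_{ij},$$

where $N_{ij}$ counts occurrences of module-$j$ keywords in the normalized
text and $\delta_j \in [0,5]$ is the module weight. Matching is plain
codepoint substring search after lowercasing and punctuation stripping:
every occurrence counts, distinct keywords count independently (so
overlapping matches of different keywords both count), and no stemming,
negation handling or embedding is attempted. Substring matching keeps the
method script-agnostic (it works unchanged on non-space-delimited text).

Weights are solved by maximizing the population variance of the score
series,

$$\max_{\delta \in [0,5]^J} \; \sigma^2 = \frac{1}{n}\sum_i (F_i - \bar F)^2,$$

on the information-theoretic rationale that a more dispersed score carries
more discriminative information. The solver is a genetic algorithm
(tournament selection of size 3, uniform crossover at rate 0.8, per-gene
mutation at rate 0.1, elitism 2, population 60, 100 generations — standing
defaults of this package, configurable via `ga_config()`). Because the
objective's maximizers sit at vertices of the weight box (see below), the
landscape is deceptive for a vanilla GA — escaping a locally optimal
vertex requires several coordinated gene flips — so the engine includes
two stock diversity operators for box-constrained problems: boundary
mutation (a mutated gene jumps to a box bound half the time) and random
immigrants (10% of each generation is drawn fresh). With them the solver
recovers the exhaustive-grid optimum on well over 95% of adversarial
negatively-correlated count matrices at the default budget; without them
it plateaus near 90% and a doubled generation budget barely helps. Weights are
encoded as **integers 0–5** by default: reference weight sets in this
setting are integer-valued, and the integer grid admits an exhaustive
oracle ($6^7 = 279{,}936$ candidates, `exhaustive_weight_search()`) against
which the GA is verified. A continuous encoding over $[0,5]^J$ is available
as a configuration option.

Two structural facts are worth recording. First, $\sigma^2$ is a convex
quadratic form in $\delta$, so its maximum over the box lies at a vertex of
$\{0,5\}^J$; the test suite asserts that the full-grid optimum always
coincides with the best vertex. Second, as a consequence, interior optimal
weights (values 1–4) can only arise from additional constraints or from a
solver stopped before convergence; the bundled library ships a reference
weight set containing interior values for use as fixed scoring weights
(`optimize = FALSE`), but the solver itself, run to convergence, reports
grid optima. When the match-count columns are positively correlated — the
typical case when modules are sampled independently — the optimum saturates
at $\delta_j = 5$ for every informative module; interior vertices appear
only under negative inter-module correlation. Ties between equally optimal
weight vectors resolve to the lexicographically smallest vector, so reported
weights are deterministic. A degenerate (all-constant) count matrix makes
the objective flat; the fit is then flagged and zero weights returned rather
than an arbitrary vector.

## Composite AIS severity

Six body regions are scored 0–6 (head/neck, face, chest, limbs+pelvis,
abdomen+pelvis, body surface). Three composites are computed and compared:

* **CRITIC weights** (`critic_weights()`): each column is min–max
  normalized; variability $S_j$ is the sample standard deviation of the
  normalized column, conflict $R_j = \sum_k (1 - r_{jk})$ over Pearson
  correlations (the self term contributes 0), information $C_j = S_j R_j$,
  and $w_j = C_j / \sum C$. The sample ($n-1$) standard deviation is used;
  the choice rescales every $S_j$ identically, so the weights are invariant
  to it. A constant column is flagged and assigned zero weight, with its
  undefined correlations treated as zero association. Min–max normalization
  plus Pearson correlation make the whole table invariant to positive-affine
  rescaling of any column.
* **Equal weights**: the regional mean (1/6 ≈ 0.167 each).
* **ISS**: the sum of squares of the three highest regional grades, with
  the standard convention that any region graded 6 sets ISS = 75. ISS is
  not a weighted sum; when a per-region "weight" is reported for it, it is
  the average share each region contributes to the ISS total.

Schemes are compared on the dichotomized outcome by discrimination (rank
AUC of the raw composite), calibration (Hosmer–Lemeshow on a univariate
logistic recalibration of the composite, $g = 10$ risk deciles, $\chi^2$
with $g-2$ df) and decision-curve net benefit
$NB(p_t) = TP/n - (FP/n)\, p_t/(1-p_t)$ over thresholds 0.01–0.99 in steps
of 0.01, with treat-all and treat-none reference policies. RTS and TRISS
baselines use the standard published coefficient sets, shipped as
configuration data (`inst/extdata/trauma_score_coefficients.json`) rather
than in-code constants.

## Missing values and univariate screening

Missingness below 5% per column is handled by *simulated imputation
selection* (`impute_select()`): four candidates (mean, mode, median, and a
compact chained-equations multiple imputation with $m = 5$ chains,
aggregated by mean/mode) are each scored by how much they perturb the
column distributions relative to the complete cases. The change score —
deliberately simple and recorded verbatim in the audit output — is the mean
over affected columns of $|\Delta\text{mean}|/s + |\Delta\text{var}|/s^2$
for numeric columns and the total-variation distance of level frequencies
for categorical ones; the smallest score wins, with ties resolved in the
fixed order mode, mean, median, multiple. The multiple-imputation candidate
regresses each incomplete numeric column on the numeric design (linear
model plus Gaussian residual noise; aliased columns drop out) and draws
categorical cells from observed level frequencies.

Univariate screening follows the conventional decision tree: continuous
variables pass a per-group Shapiro–Wilk gate at $\alpha = 0.05$ — one-way
ANOVA when every group looks normal, Kruskal–Wallis (standard tie
correction) otherwise; categorical variables use the chi-square test. The
gate is applied per group, not pooled. No multiple-testing correction is
applied at this stage; the screen is a coarse filter, not an inferential
claim. Zero-variance features are flagged and not tested. Variables that
cannot reliably be collected at admission (rescue counts, surgery) are
removed from the significant set by `timeliness_filter()` before modelling.

## Class rebalancing and feature selection

The binary task (good = cure+improved vs poor) is imbalanced at roughly
4.4:1. `rebalance()` implements SMOTE (k = 5 minority neighbours; every
synthetic point is a convex combination of two original minority points)
followed by ENN cleaning (k = 3 majority vote; rows are deleted, never
edited). Neighbour counts are package defaults, configurable.

`importance_screen()` fits a random forest (impurity importance) and a
gradient-boosted tree model (gain importance), normalizes each algorithm's
importances to sum to one, and retains features at or above the 5% share
threshold. The two retained sets D1 and D2, their union and intersection
are evaluated with a boosted-tree learner under a stratified 8:2 split plus
5-fold CV on the training part; the best set is flagged by held-out AUC.
An events-per-variable gate warns when the retained set exceeds one
variable per 10 positive events. SHAP attributions (exact TreeSHAP
contributions of the boosted model) are computed on the held-out split only,
to avoid optimism; the direction label (risk vs protective) is the sign of
the correlation between feature value and attribution.

## Stepwise logistic model and nomogram

`stepwise_logistic()` performs backward elimination from the full binomial
GLM: at each step the variable with the largest likelihood-ratio p-value is
removed while that p-value exceeds $\alpha_{exit} = 0.10$ (ties break
toward the removal with the lowest AIC); $\alpha_{entry} = 0.05$ is
recorded for completeness. The final table reports $B$, SE, Wald
$=(B/SE)^2$, p, $\exp(B)$ and the 95% CI $\exp(B \pm 1.96\,SE)$, all
recomputed from full-precision estimates. Perfect separation is detected
and flagged with a suggestion to switch to a penalized fit. A structural
caveat, verified by simulation in the test suite: with $\alpha_{exit} =
0.10$, each pure-noise variable survives elimination with probability
≈ 0.10, so on a design with 10 noise variables the chance that *all* are
dropped in one run is only $0.9^{10} \approx 0.35$ — per-run perfect
support recovery is not a property backward elimination at this threshold
can deliver, and the package documents rather than hides this.

The nomogram maps each retained variable onto a 0–100 point scale
proportional to $|B_j| \times$ its observed range (the largest such product
spans the full scale) and carries a monotone total-points-to-probability
map. Internal validation reports the C-index (rank AUC of the linear
predictor) with a stratified-bootstrap CI, and a bootstrap calibration MAE:
each of 1,000 replicates refits the model on a resample, predicts the
original data, and the mean absolute difference between decile-binned
predicted and observed event rates is averaged across replicates.

## Benchmark design

`run_benchmark()` evaluates every configured model on identical stratified
5-fold outer splits (each held-out fold plays the 20% role of an 8:2
split). All preprocessing that learns from data — rebalancing, tuning — is
fit inside the training folds only. Out-of-fold predictions are pooled into
the test metric panel (ACC, PRE, TPR, TNR, F1, AUC with stratified
bootstrap CI; macro-averaged one-vs-rest for the three-class task, with the
micro-average AUC also reported for pooled ROC display). Undefined
precision (no predicted positives) is reported as 0 and flagged.

Backends: L1/L2-penalized logistic regression (`glmnet`, regularization
strength by internal CV), RBF-kernel SVM (C = 1.0, γ = 0.1, balanced class
weights, tolerance 1e-3; Platt probabilities are orientation-checked
against the training labels because the underlying library can emit them
label-flipped), random forest (500 trees), and gradient-boosted trees with
the fixed settings max_depth = 6, min_child_weight = 3, learning rate 0.05,
200 rounds, gamma = 0.1, subsample = 0.8. The inner tuner is `"none"`
(fixed settings) by default; `"ga"` runs the genetic tuner over learning
rate (log-uniform 0.01–0.3), depth (3–8) and rounds (100–400), seeded at
the fixed settings, with a deliberately small default budget (population 8,
5 generations) so that a demo-scale benchmark completes interactively —
both knobs are configurable for larger studies. Model names without an
installed backend (`lightgbm`, the attention-based tabular hybrids) are
skipped with an explicit log entry, never silently. The overfit-gap report
flags models whose train–test AUC difference exceeds 0.15 as candidates for
early stopping and stronger regularization.

## The synthetic cohort

`generate_cohort()` draws seeded cohorts with the structure the analysis
assumes; the defaults **are** the study conditions and are not adjusted per
experiment:

* exact class counts 108 / 130 / 54 (total 292);
* ~43 admission variables with per-class marginal targets shipped in
  `inst/extdata/feature_targets.csv`: continuous variables are log-normal
  (right-skewed, as admission labs are), parameterized in closed form from
  per-class median and IQR targets ($\mu = \log m$, $\sigma =
  \operatorname{asinh}(IQR/2m)/z_{0.75}$), so empirical medians converge to
  their targets (verified at $n = 10{,}000$ within 5% relative error);
  count variables are Poisson; categorical variables follow per-class level
  frequencies;
* six AIS regions drawn from per-class severity profiles chosen once so
  the cohort's ISS medians sit near the 20 / 22 / 29 gradient across the
  outcome classes;
* diagnosis texts assembled from the keyword library with class-dependent
  module propensities (poor-prognosis records sample high-weight modules at
  2.5× odds) plus neutral filler tokens chosen to be collision-free with
  every keyword, so match counts are exactly recoverable;
* MCAR missingness per eligible column at rate 0.03, with the realized
  per-column proportion capped strictly below 5%;
* outcome assigned first, features sampled conditionally — the simplest
  structure consistent with per-class marginal contrasts.

What the generator does **not** emulate: the joint correlation structure of
real admission panels (features are conditionally independent given the
outcome), real clinical text (no negation, abbreviation or misspelling),
time-to-event structure, and informative missingness. Passing tests
therefore demonstrate the correctness and stability of the *pipeline
machinery* under realistic marginals and class imbalance — not clinical
validity on registry data.

## Numerical choices and degenerate inputs

* Population variance (divisor $n$) for the text-score objective; sample
  SD for CRITIC variability.
* Lexicographic tie-break for equal-objective weight vectors.
* Constant columns: flagged (CRITIC weight 0, univariate test skipped,
  degenerate weight fit).
* Likelihood-ratio p-values that are undefined (aliased or constant terms)
  are treated as 1, so uninformative terms are removed first.
* Hosmer–Lemeshow bins with zero-variance expectation are dropped from the
  statistic; degrees of freedom floor at 1.
* Seeds: one global seed fans out to stage seeds via a fixed hash
  (`derive_seed()`), so stages are independently reproducible and two runs
  under one seed produce byte-identical artifacts (asserted on manifest
  fingerprints, which hash config and output-file checksums but not
  wall-clock fields).

## Problem sizes used by the test suite

The suite favours many small, seeded instances over few large ones: GA
verification on 50 instances of 30 patients × 7 modules against the full
$6^7$ grid; stepwise support-recovery on 50 designs of $n = 2000$ with 5
signal and 10 noise variables; univariate type-I calibration on 2,000 null
replicates of the 292-patient group structure; pipeline determinism on the
full 292-patient demo run twice. These sizes are the package's standing
verification choices and are stated here so they can be scaled up
deliberately rather than accidentally.

## Known limitations

* The text scorer is exact substring matching only — no clinical NLP.
* The variance objective rewards dispersion, not outcome association;
  weights are unsupervised with respect to prognosis.
* SMOTE interpolates in the numeric encoding of categorical codes, which
  can produce fractional category values for synthetic points; the
  boosted-tree and forest learners are insensitive to this, but linear
  models read such values literally.
* The nomogram's bootstrap calibration refits the *final* selected model;
  it does not re-run the stepwise selection inside each replicate, so the
  MAE does not account for selection uncertainty.
* The attention-based tabular hybrids named in benchmark configurations
  have no backend in this package and are reported as skipped.
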