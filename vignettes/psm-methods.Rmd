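---
title: "Forest-proximity patient similarity and personalized mortality models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forest-proximity patient similarity and personalized mortality models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional ICU mortality models are one-size-fits-all: a single model is
fitted to the whole training cohort and applied to every new patient. When
the cohort mixes subpopulations whose feature-risk relationships differ,
training data from dissimilar patients can actively mislead the model for a
given index patient. Personalized (patient-specific) prediction instead
trains a custom model for each index patient, using only - or preferentially -
the training patients most similar to them.

`psmforest` implements that workflow with a *random-forest proximity* patient
similarity metric (PSM), four personalized model families swept over the
neighborhood size M, a case-specific random forest that replaces neighborhood
selection with similarity-weighted bootstrapping, and a cross-validated
AUROC/AUPRC harness. Because the large ICU databases this method targets are
credential-restricted, the package ships a synthetic cohort generator that
emulates their feature schema and lets every stage be exercised and tested
end to end.

## The similarity metric

An unsupervised random forest is grown on a two-class contrast problem:
the observed patients (class 1) against an equal number of synthetic rows
whose features are drawn independently from each feature's empirical
marginal (class 2). The synthetic class preserves all marginals but destroys
the dependence structure, so the forest's splits encode where the observed
data concentrate jointly. Following the convention for proximity forests,
the forest uses `mtry` equal to the total number of predictors, a minimum
node size of 5, and 500 trees by default.

For patients $i$ and $j$, the proximity count
$\mathrm{Prox}_{ij} \in [0, T]$ is the number of the $T$ trees in which both
fall into the same terminal node. One row of proximities is normalized into
similarity weights

$$ w_{ij} = \frac{\mathrm{Prox}_{ij}}{\sum_{j'} \mathrm{Prox}_{ij'}}, $$

a probability vector over the training patients. Dividing by $T$ instead of
the row sum is an equivalent choice for any ranking purpose (the two differ
by a positive scalar); the row-sum form is the default because the weights
double as a bootstrap sampling distribution in the case-specific forest, and
the alternative is available via `normalize_psm(denominator = "ntree")`. A
unit test asserts the rank-invariance explicitly.

Two degenerate contracts are fixed by design: an all-zero proximity row
falls back to uniform weights (with a warning), and ties in the similarity
ranking are broken by ascending patient index so neighbor selection is
deterministic.

By default the per-fold forest is grown on the union of that fold's training
and test *features* (outcome labels are never used by the unsupervised
forest), which matches growing one proximity forest on all available data; a
strict `scope = "train_only"` mode is provided for a leakage-free variant.
Since labels never enter the forest, the default leaks no outcome
information, only feature geometry.

## Personalized model families

For an index patient, the $M$ most similar training patients form the local
training set (*hard thresholding*). Four families are supported:

* **DC (death counting)** - the predicted risk is the neighborhood death
  fraction; with $M$ equal to the full training set this degenerates to the
  overall training mortality rate.
* **LR** - maximum-likelihood logistic regression (`stats::glm` defaults).
* **DT** - a recursive-partitioning classification tree (`rpart` defaults,
  cost-complexity pruning as shipped).
* **RF** - a random forest with the conventional defaults
  (`mtry = floor(sqrt(p))`, node size 1, 500 trees; tree count reducible for
  desk-scale runs).

Small, homogeneous neighborhoods raise two practical degeneracies. First,
predictors that are constant across the $M$ rows (an all-male neighborhood,
say) are dropped before fitting and ignored at prediction
(`drop_degenerate_predictors()`). Second, a single-class outcome vector
short-circuits to a constant-risk model (0 or 1) without fitting. Logistic
fits that separate or fail to converge fall back to the neighborhood death
rate; base R's `glm` would warn and keep the diverged fit, and the constant
fallback is the deliberate, documented difference. Categorical predictors
are one-hot encoded with the first declared level as reference for all
families, trading R's factor-handling idiosyncrasies for a single uniform
encoding.

## Case-specific random forest

The CSRF drops the hard threshold: every tree of the index patient's forest
is grown on a bootstrap sample of size $n_{\text{train}}$ drawn *with
probabilities equal to the similarity weights* over the whole training set.
Defaults are 500 trees, node size 1 and `mtry = floor(sqrt(p))`. The
prediction is the fraction of trees voting death. Per-tree RNG streams are
derived from `(seed, tree index)`, and each tree is fitted by the same CART
machinery as the RF family; with uniform weights the procedure *is* a
standard random forest built through explicit bootstrap samples, which the
tests exploit as an exact equivalence check (and separately as a
distributional comparison against `randomForest` itself). The bootstrap
sample size equals the training size, the standard forest convention. Trees
whose weighted sample happens to be single-class cast a constant vote.

## Evaluation harness

`run_sweep()` reproduces the experimental design: k-fold cross-validation
(default 10, unstratified by default with a stratified option), per-fold
PSM computation between the fold's test and training patients, per-patient
model training at each neighborhood size on the grid, and fold-level AUROC
and AUPRC. AUROC uses the Mann-Whitney formulation (ties credited 0.5);
AUPRC is average precision with tie blocks collapsed to a single threshold.
Fold summaries are $\bar{x} \pm t_{0.975,k-1}\, s/\sqrt{k}$.

The full-scale grids (M from 10 to 15,000 in steps of 10 for DC; 4,000 to
15,000 for LR/RF; 5,000 to 15,000 for DT, each against roughly 15,500
training patients) assume a cohort of about 17,000; `default_sweep_grid()`
preserves their proportions at any cohort size, and any grid value above
the training-fold size is rejected as infeasible. "Best performance" is the
grid point with the maximum mean metric; `find_peak()` tests it against the
largest grid M and against the all-training-data condition with a paired,
two-sided t test on per-fold differences (pairing is natural because both
conditions share folds; an exact sign test covers the zero-variance edge).
Because CSRF is soft thresholding, it has no M grid and runs once per fold.

## The synthetic cohort generator

The generator emulates the 75-predictor first-day ICU schema: age truncated
normal on 18-100 years (mean 64.5, sd 17); admission type drawn at the
18.0/3.7/78.3% elective/urgent/emergency mix; six vital signs as
patient-level Gaussians with four 6-hour windows and min <= max enforced by
construction within every window; eight labs log-normal (positive,
right-skewed); an integer worst Glasgow Coma Scale in 3-15; nonnegative
urinary output per window. Means and spreads are ordinary adult-ICU
magnitudes and are documented in the source (`.vital_params()`,
`.lab_params()`).

Heterogeneity is a latent mixture: each patient belongs to one of
`n_clusters` (default 4) hidden subpopulations. A cluster shifts the
feature means (scale `cluster_sep`, default 0.8 between-patient sd) and
owns a logistic risk coefficient vector
$\beta_c = \texttt{effect\_scale} \times (\beta_{\text{base}} + \delta_c)$,
where $\beta_{\text{base}}$ points in the usual clinical directions (older
age, lower GCS, vasopressor use, lower blood pressure, higher BUN increase
risk) and $\delta_c$ is a cluster-specific deviation of comparable spread.
This makes `effect_scale` a single dial from "nothing to personalize"
(`effect_scale = 0`: every cluster shares the same flat risk, so no
similarity metric can help) to strong exploitable heterogeneity; it was
fixed once so that the true-risk ranking discriminates the simulated
outcome at AUROC about 0.85 under the defaults, the performance regime of a
good ICU mortality model. The mean-shift and coefficient structure is the
minimal one under which feature-driven similarity correlates with
risk-model membership - the mechanism personalization needs.

The marginal mortality is calibrated by Monte-Carlo bisection of a shared
intercept shift until the mean true risk is within 0.002 of the 15.1%
target (`calibrate_intercepts()`); unreachable targets fail with a
diagnostic. Everything is driven by one integer seed: the same
configuration reproduces a cohort bit for bit.

What the generator does **not** emulate: real feature correlation
structure, unit pathologies of real lab data, repeated admissions of the
same patient, missingness (the generator emits complete cases; the reader
enforces the complete-case rule on external files), or temporal waveforms
beyond windowed min/max summaries. Passing tests therefore demonstrate the
machinery and the qualitative personalization phenomenology, not clinical
performance on any real ICU population.

## What the tests establish, and at what scale

The package's end-to-end checks run at desk scale, chosen to finish on one
CPU in minutes: cohorts of n = 2,000 with 10-fold cross-validation, 100-tree
proximity forests, 50-tree local RFs scored on a 25-patient stratified
subsample per fold, DC on the full M grid (10 to 1,740 by 10, keeping the
largest M near but below the training size, as in the full-scale design).
At that scale the central qualitative finding reproduces: on a heterogeneous
cohort, death counting attains a significant interior best-M (paired
p < 0.01 against the all-data model), the RF family is statistically flat in
M, and on a homogeneous cohort the DC peak disappears. A "peak" is claimed
only when the paired test is significant at the same level used to report
the positive finding (alpha = 0.01); with 174 correlated grid points, the
maximum of the mean curve is upward-biased by selection, which is why the
negative control is asserted at the claim alpha rather than 0.05. The
subsampled RF arm has wide fold CIs - a deliberate power trade-off; it makes
the no-difference finding easier to state but also matches the visibly flat
mean curve.

Numerical conventions collected in one place: similarity weights sum to 1
within 1e-12; all probability outputs are clamped to [0, 1]; AUROC requires
both classes and AUPRC at least one positive (explicit errors otherwise);
constant scores give AUROC 0.5 and AUPRC equal to prevalence; fold sizes
differ by at most one; all stochastic stages derive their streams from the
stage seed, and sweep records are bit-reproducible under a fixed seed.

## Limitations

* Proximities are counted over all trees, matching the default of the
  reference forest implementation, not the out-of-bag variant.
* No per-patient optimal-M selection and no PSM-threshold (absolute cutoff)
  neighborhood rule; the sweep characterizes performance as a function of M
  for the cohort as a whole.
* No hyperparameter tuning of the model families beyond the stated
  defaults.
* The synthetic cohort is a stand-in with documented distributional
  choices; quantitative metric values on it are not comparable to values
  reported on any real ICU cohort.
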