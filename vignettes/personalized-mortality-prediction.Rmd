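---
title: "Personalized mortality prediction with a patient similarity metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized mortality prediction with a patient similarity metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simpredict)
```

## The idea

Severity-of-illness (SOI) scores such as SAPS and SOFA are one-size-fits-all:
a single model, fitted to a large heterogeneous population, scores every
patient. `simpredict` implements the opposite, instance-based strategy for
binary outcomes such as 30-day mortality after an ICU stay. For each *index
patient* whose outcome is to be predicted, it

1. computes a similarity value between the index patient and every past
   patient in the training data,
2. sorts past patients by descending similarity,
3. trains a predictive model on only the *N* most similar patients, and
4. applies that custom model to the index patient, yielding a risk in [0, 1].

The interesting scientific quantity is not one model but the curve of
predictive performance as a function of *N*: too large an *N* dilutes the
training data with irrelevant (dissimilar) patients, too small an *N*
starves the model of data. The package's sweep machinery maps this
homogeneity-versus-sample-size trade-off under stratified cross-validation.

## The patient similarity metric

Each patient is a vector in feature space. Similarity is the cosine of the
angle between two patient vectors,

$$\mathrm{PSM}(P_1, P_2) = \frac{P_1 \cdot P_2}{\lVert P_1\rVert\,\lVert P_2\rVert} \in [-1, 1],$$

with two conventions for mixed-type clinical data:

* **Continuous features** are rescaled to $[-1, 1]$ by a min–max map fitted
  on training data, so that every predictor can contribute equally. Values
  outside the fitted range (possible for test patients) are clipped to
  $\pm 1$ rather than extrapolated, preserving the equal-contribution
  rationale. A feature that is constant in the fitting data carries no
  similarity information and is mapped to 0, with a warning.
* **Categorical features** are compared all-or-none: a dimension
  contributes $+1$ to the dot product when the two categories agree and
  $-1$ when they differ. Each categorical dimension also contributes
  exactly 1 to each vector's squared magnitude. This is the unique
  magnitude convention consistent with the $\pm 1$ numerator: a lone
  matching categorical gives $\mathrm{PSM} = 1$, a lone mismatch $-1$.

Ties in the resulting ranking are broken by ascending patient id, so every
downstream computation is deterministic.

### Normalization scope

Fitting the min–max scaler on the *whole* dataset lets information about
test patients leak into training-fold computations. The default is
therefore `normalization_mode = "per_fold"`: the scaler is fitted on each
training fold and applied, with clipping, to that fold's test patients.
Whole-dataset fitting remains available (`"global"`) because the
alternative convention is common and the difference is worth measuring; on
cohorts of a few thousand patients we observe it is negligible, since fold
min/max values nearly coincide.

## The local models

Three model families can be trained on the *N*-most-similar subset:

* **Death counting** (`death_count`) — the mortality rate among the *N*
  neighbors. No parameters; works at very small *N* (conventional grid
  10–500 by 10).
* **Logistic regression** (`logistic`) — maximum likelihood on all schema
  features, categoricals dummy-coded against the first sorted level. Local
  subsets are routinely near-separated, so the default fit adds a tiny L2
  ridge ($10^{-6}$, excluded from the intercept) that keeps the IRLS
  solve finite while moving coefficients by far less than their standard
  errors; `ridge = 0` gives the strict unpenalized fit (and matches
  `glm()` to $10^{-6}$ on well-behaved data, which the test suite checks).
  The fit sorts the subset by patient id first, so the result does not
  depend on neighbor order.
* **Classification tree** (`tree`) — CART with Gini impurity via
  \pkg{rpart}. Defaults: minimum leaf size 20, maximum depth 8, no
  surrogate splits. These mirror common CART practice at the
  2000–15000-patient subsets trees are used on here; no claim of
  optimality is made. Leaf risks are Laplace-smoothed,
  $(\text{deaths}+1)/(\text{leaf size}+2)$, so no patient receives risk
  exactly 0 or 1.

A logistic fit needs every categorical level represented and a tree needs
outcome variability, which is why each model kind carries a minimum
admissible *N* (defaults 10 / 5000 / 2000). These floors are configuration,
not constants: they shrink with the dataset, and `sweep_config()` accepts
`minimum_n` explicitly.

Two prediction-time edge cases are defined rather than fatal: a categorical
level never seen by a model maps to the reference level (logistic) or is
routed down the majority child (tree), with a warning; and if an individual
index patient's model cannot be fitted at all (e.g. an all-survivor
neighborhood at the low end of a grid), the prediction falls back to death
counting on the same neighborhood, flagged in the output — configurable to
a hard error. A library must define this behavior because per-index subsets
routinely miss rare diagnosis codes.

### Benchmarks

SOI scores are consumed as plain numeric columns and *logit-customized*:
the outcome is regressed on the raw score in a univariable logistic model
fitted on the entire training fold (not on *N* neighbors). Customization
re-anchors calibration to the local population; because a positive-slope
logit refit is strictly monotone, it provably leaves AUROC unchanged — a
property the test suite asserts exactly.

## Evaluation

* **Folds** are stratified: the expired and the survived are permuted
  independently and dealt round-robin, the deal continuing across the two
  strata, so per-class fold sizes *and* total fold sizes each differ by at
  most one.
* **AUROC** uses the rank-based (Mann–Whitney) estimator with ties counted
  one half — exactly the mean over all positive–negative pairs.
* **AUPRC** is average precision with tie blocks: positives contribute the
  precision at the end of their tie block; no interpolation between
  precision–recall points is performed (PR areas are not linearly
  interpolable the way ROC areas are). Under this convention a constant
  classifier scores exactly the prevalence, the correct "random" baseline
  on skewed data.
* **Summaries** are fold means with 95% confidence intervals from the t
  distribution on $k-1$ degrees of freedom; the interval construction over
  cross-validation folds is a convention choice, stated here once.
* **Comparisons** (peak vs. largest *N*, peak vs. each benchmark) are
  two-sided two-sample t-tests at $\alpha = 0.05$, Welch's form by default
  since equal fold variances are not guaranteed; the pooled-variance form
  is available. Unpaired tests are used even though fold values are
  paired — the conservative reading of the convention this package
  follows; no multiplicity correction is applied.

`run_sweep()` computes each index patient's neighbor ordering once per fold
and reuses it across the whole *N* grid; for death counting the entire grid
then costs one cumulative sum per index patient. This makes a 50-point grid
on a 4,000-patient cohort a matter of seconds rather than hours.

## The synthetic cohort generator

Real first-day ICU data of the kind this method targets are
access-restricted, so the package ships a generator
(`generate_cohort()`) that emulates the *statistical structure* the method
assumes, with known ground truth:

* latent patient subgroups (default 6, mildly imbalanced) standing in for
  service lines / presenting syndromes;
* ~70 continuous features in correlated min/max pairs (max = min +
  positive gap), mimicking first-24-hour vital-sign and lab extractions
  and deliberately exercising near-collinearity in local logistic fits;
* categoricals with per-subgroup multinomials, including a 40-level,
  Zipf-tailed primary-diagnosis stand-in;
* true risk $\operatorname{logit}^{-1}(\alpha_c + \beta_c^\top x)$ with
  *subgroup-specific coefficient vectors* — identical across subgroups
  under `cluster_effect = "none"`, mutually orthogonal under `"high"`.
  Subgroup-specific directions (not merely shifted intercepts) are what
  make a local model class genuinely beat a global one, which is the
  hypothesis the framework exists to test;
* a global intercept shift found by bisection so the mean true risk hits
  the prevalence target (default 15.1%) within 0.002;
* severity-score stand-ins: affine transforms of true risk plus Gaussian
  noise, the noise scale bisected so each score's in-sample AUROC hits its
  target (defaults 0.66 SAPS-like, 0.63 SOFA-like), then mapped to
  familiar display scales (mean 14.5/6.3, sd 5.1/3.9).

Effect-size scales (mean separation 1.5 SD under `"high"`, 0.6 under
`"moderate"`; coefficient-vector mixing 1 / 0.5 / 0) were chosen once as a
plausible range from "clearly clustered" to "homogeneous" and are not
tuned. Everything is driven by one integer seed through a Mersenne–Twister
stream that is restored afterwards, so generation is reproducible and
side-effect free.

What the generator does **not** emulate: clinically realistic physiologic
joint distributions, time series, informative missingness (it produces
complete cases by construction), or the actual correlation structure of any
real ICU database. Tests that pass on these cohorts therefore demonstrate
that the machinery is correct and that the locality effect is recoverable
*when present* — not that any particular performance level will be attained
on real data.

## Problem sizes and numerical choices

The shipped verification suite exercises the full pipeline at sizes chosen
to make the statistical claims testable at desk scale: trade-off and
null-control checks use 20 replicate cohorts of 4,000 patients with 5-fold
cross-validation and the 10–500 death-counting grid; parameter-recovery
checks use 5,000–10,000 observations; the degenerate-limit check compares
per-index and global logistic fits to within $10^{-8}$ on a 4,000-patient
cohort. Larger cohorts change runtimes, not conclusions.

Other numerical conventions, collected: PSM values are clamped to
$[-1, 1]$ to absorb floating-point drift; a PSM between two zero-magnitude
vectors is an error (impossible once any categorical feature exists);
bisections run 60 halvings of a fixed bracket; IRLS iterates to a
$10^{-10}$ coefficient change with weights floored at $10^{-10}$; all
ranking and fitting tie-breaks are by ascending patient id.

## Limitations

* The cosine PSM weights all features equally; no learned metric,
  diagnosis-code hierarchy, or feature selection is attempted.
* Each ICU admission is treated as an independent patient; repeat
  admissions of one person are neither linked nor de-duplicated.
* Complete-case analysis only; rows with any missing declared value are
  dropped at load.
* Per-index model fitting is embarrassingly parallel but implemented
  serially; index patients are independent work units and any execution
  order yields identical results.
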