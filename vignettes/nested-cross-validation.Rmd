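---
title: "Nested cross-validation with embedded feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested cross-validation with embedded feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomedical prediction problems are routinely in the \(P \gg n\) regime:
tens of thousands of candidate predictors (genes, probes, metabolites)
measured on tens to low hundreds of samples. Two practices that look
innocuous are then catastrophic for performance estimation:

1. **Filtering predictors on the whole dataset** (e.g. keeping the 100
   genes with the smallest t-test p-values) before splitting into
   training and test sets. The filter has seen the test labels, so the
   selected predictors carry information about the test set, and the
   apparent accuracy is inflated — on pure noise it can approach an AUC
   of 1.
2. **Reporting accuracy on the CV folds used to tune hyperparameters.**
   The tuning loop optimises performance on those folds, so their
   accuracy is "learnt" and optimistic.

`nestfold` implements fully nested \(k \times l\)-fold cross-validation:
an **outer** loop of \(k\) folds measures performance on data never
touched by any model-building step, and an **inner** loop of \(l\) folds
inside each outer training fold tunes hyperparameters. Feature
filtering, class rebalancing and tuning are all embedded strictly inside
the outer training folds. Pooling the out-of-fold predictions across
outer folds uses every sample for testing exactly once, which is what
makes nested CV attractive for small cohorts compared with a single
held-out partition.

## The procedure

For each outer fold \(i = 1, \dots, k\), in this exact order:

1. take the outer training rows (the other \(k - 1\) folds);
2. **balance** classes on those rows only (optional);
3. **filter** predictors on the (balanced) training rows, keeping the
   top \(N\);
4. **tune** hyperparameters by \(l\)-fold inner CV on the balanced,
   filtered training rows;
5. **fit** the tuned model on the whole outer training fold;
6. **predict** the untouched, unbalanced outer test rows, restricted to
   the selected predictors.

The pooled out-of-fold score vector (one score per sample) is the basis
for all headline metrics: ROC AUC, accuracy and balanced accuracy for
classification, RMSE and \(R^2\) for regression. Per-fold metrics are
reported for dispersion only. The inner-CV left-out-fold performance at
each fold's chosen hyperparameters is also computed and reported, but
clearly labelled as optimistically biased — it is the quantity people
mistake for honest performance.

A **final model** for deployment is fitted by applying the same recipe
to the whole dataset: whole-data filter, optional balancing, fresh
seeded \(l\)-fold CV for tuning, fit on everything. Its filter sees all
rows by design — it is the model you ship, not the performance estimate.
The tuning folds are fresh seeded folds rather than a reuse of the outer
folds; the final fit is a new model-building exercise, and tying it to
the evaluation partition would serve no inferential purpose.

## Tunable parameters

* `k_outer`, `l_inner` (default 10 × 10): more outer folds mean larger
  training fractions and smaller test folds; 10 × 10 is the
  conventional compromise.
* Filter `n_keep` (default 100): the number of predictors retained.
  Top-\(N\) selection is used rather than p-value thresholds; \(N\) is
  what practitioners actually fix in biomarker work.
* Elastic net: `alpha` grid (default \(\{0, 0.25, 0.5, 0.75, 1\}\),
  ridge to lasso), `n_lambda` (default 100 path points per alpha),
  `lambda_min_ratio` (default \(10^{-3}\) when \(n > P\), else
  \(10^{-2}\)). The tuning metric is binomial deviance by default — it
  is smooth along the regularization path, whereas AUC is piecewise
  constant; AUC tuning is available by configuration.
* Balancing: `method` (`oversample`, `undersample`, `both`, `smote`),
  `target` minority:majority ratio (default 1), SMOTE `k_neighbors`
  (default 5, truncated to minority size − 1).
* ReliefF: `n_neighbors` (default 10) nearest hits/misses,
  `n_samples_used` (default: all samples), exhaustive neighbor search,
  Manhattan distance on min-max-scaled features, class-prior-weighted
  misses.

## Design choices

Several points are genuinely open in the literature; the package's
positions, chosen once:

* **Welch t-test** (unequal variances) rather than the pooled form: a
  robust default for expression-like data. Ties in every filter ranking
  break by ascending predictor index, so results are exactly
  reproducible.
* **Zero-variance predictors** are excluded and reported
  (`dropped_degenerate`) rather than raising an error: \(P \gg n\)
  matrices routinely contain constants after subsetting. For the t
  filter this applies to predictors with zero variance in *both*
  groups, whose statistic is undefined.
* **Stratified folds by default.** Within each class, indices are
  shuffled with the seeded RNG and dealt round-robin across folds;
  remainders go to the smallest folds. Per-class counts then differ by
  at most one between folds. Continuous outcomes are stratified by
  quantile bins (deciles, fewer when \(n < 20\)) to stabilise regression
  folds. Stratification can be switched off.
* **Ridge lambda path**: \(\alpha = 0\) has no finite lambda that nulls
  all coefficients, so its path maximum is set to 1000 × the
  \(\alpha = 0.001\) path maximum. One shared lambda path per alpha is
  computed on the full outer-training fold, mirroring standard
  regularization-path CV practice.
* **Tuning tie-breaks** go to larger lambda, then larger alpha — the
  sparser model.
* **Balancing and inner folds.** Balancing happens on the outer
  training fold *before* inner folds are populated. When balancing
  changes the row set, the plan's precomputed inner folds no longer
  apply and inner folds are re-stratified on the balanced outcome with
  the fold-derived seed. Duplicated minority rows can therefore appear
  in different inner folds (train on one copy, validate on another);
  this inner-level optimism affects tuning only, never the outer
  performance estimate, and is the price of balancing before tuning. We
  document it rather than de-duplicating across inner folds.
* **Fit after tuning uses the balanced fold** — the same data the tuner
  saw — for downstream consistency.
* **Balancing is refused for regression** outcomes, where rebalancing
  is known to be deleterious.
* **Positive class** is the second level of the sorted label set,
  stated in every report.
* **Fail-fast error policy**: a failing fold aborts the run with its
  fold index and stage, rather than being dropped silently — dropped
  folds would bias pooled metrics.
* **Indices** are 1-based inside the package (the natural R
  convention); the JSON fold-plan serialization is 0-based so plans can
  be replayed from any language, and all report files carry sample ids
  rather than indices.
* **Seeds.** The plan seed deterministically derives per-outer-fold
  seeds (`seed + fold index`), which drive balancing, stochastic
  filters and stochastic learners in that fold. Results are therefore
  invariant to execution order and to the number of parallel workers;
  parallelization is applied to the outer CV loop only.

## The outer-only mode

`outercv()` measures performance without the inner tuning loop, for
learners whose parameters are fixed or learned internally — a random
forest with a fixed tree count is the canonical example, since the tree
count does not require tuning against test performance. Feature
filtering and balancing remain nested inside the outer loop: unnested
filtering is usually a larger source of bias than unnested tuning. With
a degenerate one-point tuning grid, `nestcv()` and `outercv()` produce
identical results — a structural identity the test suite asserts.

## The null simulation

`run_bias_experiment()` reproduces the optimism-bias demonstration on
data with no signal at all: features i.i.d. standard normal, outcome a
random balanced binary label independent of the features. Three schemes
are compared over repeated fresh datasets:

* **filter-then-partition** (biased): t-test top-\(N\) filter on the
  whole data, then a stratified 2/3–1/3 split, tune and fit on the
  training part, AUC on the test part;
* **partition-then-filter** (unbiased): the split happens first and the
  filter sees training rows only;
* **nested CV** (unbiased): the full engine.

Since the data are noise, the true AUC is 0.5. The biased scheme
reports dramatically inflated AUCs; both unbiased schemes are centred
at 0.5, with nested CV showing smaller spread across repeats because
all \(n\) samples contribute to each estimate rather than \(n/3\).

Default conditions: \(n = 100\) samples, \(p = 5000\) predictors,
top-100 t-test filter, 2/3 training fraction, 50 repeats, 10 × 10
folds. \(p = 5000\) is the package's working scale for this
demonstration — the bias is driven by the selection pressure
\(p / N\), which at \(5000/100 = 50\) is already far beyond what any
honest estimator could absorb, and larger \(p\) is available by
configuration. \(n = 100\) is a typical small-cohort size for this
design. The acceptance machinery runs 10–20 repeats of these
conditions; the bias and variance orderings it checks are properties of
the scheme, not of a particular repeat count.

What the generator deliberately does **not** emulate: correlated
predictors (gene co-expression), heavy-tailed or count-distributed
features, batch effects, and label noise. Passing the null calibration
therefore shows the estimator does not manufacture signal from
selection pressure; it does not certify behaviour under correlated
designs, where filters select correlated surrogates and effective
dimensionality is lower.

## Numerical notes and degenerate inputs

* AUC is computed by the Mann–Whitney rank identity, `(concordant +
  0.5 × tied) / (n_pos × n_neg)`; the trapezoidal area of the ROC curve
  equals it to numerical identity, which the tests assert at 1e-12.
* Probabilities are clamped to \([10^{-10}, 1 - 10^{-10}]\) before
  deviance computation.
* A predictor constant within a training fold is dropped by the filter
  for that fold only; a class with fewer members than ReliefF's
  `n_neighbors` uses all available members with a warning; SMOTE with a
  singleton minority falls back to random oversampling with a warning.
* Missing values are rejected at dataset construction by default. With
  `impute = "median"` the engine imputes per outer fold using medians
  of the *training* rows only — the same leakage logic as filtering.
* An inner fold whose training rows contain a single class cannot fit a
  binomial model and raises a degenerate-outcome error asking for
  re-stratification; stratified folds make this practically
  unreachable.

## Problem sizes used in the checks

The packaged tests run the full study conditions (\(n = 100\),
\(p = 5000\), 10 × 10 folds) for the calibration, bias and variance
checks with 20 repeats shared across the three, and smaller instances
(tens of samples, tens to hundreds of predictors, 3–5 outer folds) for
structural and oracle checks, where the properties under test are
exact identities independent of scale.

## Known limitations

* Binary classification and gaussian regression only; multiclass
  outcomes are accepted by the ANOVA and ReliefF filters but not by the
  engine.
* No repeated nested CV (repetition across fresh fold plans is the
  simulation harness's job), no grouped or leave-one-out folds, no
  survival outcomes.
* The filter catalogue covers the univariate statistics plus random
  forest importance and ReliefF; anything else plugs in through the
  custom-filter contract, which the engine treats identically.
* Inner-CV metrics are reported for didactic contrast only; any use of
  them as a performance claim reintroduces exactly the bias this
  package exists to remove.
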