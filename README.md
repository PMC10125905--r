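# nestfold

Fully nested *k* × *l*-fold cross-validation with embedded feature
selection and class balancing, for classifiers and regression models in
the *P* ≫ *n* regime typical of transcriptomics and other omics data.

## Why

When a dataset has far more predictors than samples, two common
shortcuts wreck performance estimation:

* **filtering predictors on the whole dataset** (e.g. keeping the top
  100 genes by t-test) before splitting into training and test data —
  the filter has seen the test labels, so the test set is no longer
  unseen;
* **reporting accuracy on the same CV folds used to tune
  hyperparameters** — tuning optimises those folds, so their accuracy
  is inflated.

On pure noise, whole-data filtering followed by a train/test split can
report an AUC above 0.9. `nestfold` removes both biases by nesting
every model-building step — balancing, filtering, hyperparameter
tuning — strictly inside the outer training folds, and measuring
performance on pooled out-of-fold predictions: every sample is tested
exactly once by a model that never saw it.

Per outer fold the engine runs, in order: outer training rows → class
balancing (optional) → feature filter (top-*N*) → inner *l*-fold CV
tuning → fit → predict the untouched held-out fold. A final model is
then fitted on the whole dataset by the same recipe for deployment.

Built-in filters: Welch t-test, Wilcoxon rank-sum, one-way ANOVA,
Pearson/Spearman correlation, random forest importance, ReliefF, plus a
custom-filter contract. Balancers: random over/undersampling, their
combination, SMOTE. Learners: an elastic net whose **alpha and lambda
are both tuned on inner folds** (via glmnet), a fixed-parameter random
forest for the outer-only mode (`outercv()`, for tuning-free learners),
and a custom-learner contract.

## Worked example

One hundred samples, 1000 gaussian predictors of which the first five
carry a modest class shift; 10 × 10 nested CV with a top-50 t-test
filter and an elastic net tuned over alpha and lambda:

```r
library(nestfold)

ds <- gen_noise_dataset(100, 1000, seed = 42)
ds$X[, 1:5] <- ds$X[, 1:5] + ifelse(ds$y == "b", 0.6, -0.6)
df <- as.data.frame(ds$X); df$status <- ds$y

res <- nestcv(df, outcome = "status", k_outer = 10, l_inner = 10,
              filter = filter_spec("ttest", n_keep = 50),
              learner = elastic_net_learner(), seed = 7)
res
#> <nestcv_result> elastic_net, 10 outer folds, 100 samples
#> Pooled out-of-fold metrics (unbiased):
#>     auc accuracy balanced_accuracy
#>  0.9016     0.83              0.83
#> Inner-CV metrics (optimistically biased; comparison only):
#>        auc  accuracy balanced_accuracy
#>  0.9975407 0.9722222         0.9722222
#> Positive class: b
```

The pooled out-of-fold AUC (0.90) is the honest estimate; the inner-CV
AUC (0.9975) is reported only to show how misleading tuning-fold
accuracy is. `augment()` gives the per-fold view — all ten folds keep
50 predictors and choose their own (alpha, lambda):

```r
head(augment(res), 3)
#> # A tibble: 3 × 5
#>    fold n_selected alpha  lambda fold_metric
#>   <int>      <int> <dbl>   <dbl>       <dbl>
#> 1     1         50  0.25 0.00130        0.96
#> 2     2         50  0.25 0.00206        1
#> 3     3         50  0.25 0.00133        0.76

head(variable_importance(res$final$model), 5)
#> # A tibble: 5 × 2
#>   predictor importance
#>   <chr>          <dbl>
#> 1 V4             1.49
#> 2 V3             1.34
#> 3 V1             1.22
#> 4 V5             1.05
#> 5 V2             0.784
```

The final model correctly ranks the five planted predictors (V1–V5)
top. `tidy(res)` returns the pooled predictions,
`autoplot(res)` the pooled ROC curve, and `predict(res, newdata)`
scores new samples with name-based column alignment.

The null demonstration — why nesting matters — is one call:

```r
exp <- run_bias_experiment(null_sim_config(n_repeats = 20))
glance(exp)   # filter-then-partition mean AUC far above 0.5;
              # nested CV and partition-then-filter centred on 0.5
autoplot(exp)
```

A command-line interface (`inst/cli/nestfold`) exposes `nestcv`,
`outercv`, `simulate-bias` and `predict` subcommands driven by
YAML/JSON configs; see `?run_cli`.

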