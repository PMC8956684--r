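# sparsewrap

Sparse wrapper model *sets* for binary biomarker panels.

Expression studies that discriminate two tissue states (tumor versus normal,
say) from continuous features usually report one selected model. In sparse,
correlated designs, however, many small feature combinations predict equally
well, and which one a selector returns is close to arbitrary. `sparsewrap`
returns the whole set of near-equivalent sparse logistic models and then
treats that set as the object of analysis: which features recur, which
co-occur, which are interchangeable, and — centrally — whether a feature's
estimated direction of effect flips between its marginal (single-feature) fit
and its fits inside the retained multivariate models. Features with such
discordant signs are flagged *antagonistic*: the operational signature of a
Yule–Simpson reversal driven by correlated partners, and a statistical reason
why different studies can assign opposite roles to the same biomarker.

## What it computes

* **Search** (`run_swag`): a screening step scores all *p* one-feature
  logistic models by repeated class-stratified k-fold cross-validated
  misclassification; features at or below the inclusive empirical
  α-quantile survive. Each growing step extends retained models of the
  previous dimension with one screened feature, rescore, retain the best α
  proportion again, up to `p_max`. The result is a per-dimension set of
  "strong" models, fully reproducible from a seed.
* **Evaluation**: stratified train/test splits with largest-remainder
  rounding, confusion metrics at the 0.5 cutoff, ROC curves / AUC, the ROC
  *region* (pointwise envelopes over all model curves), events-per-variable,
  and an L1-penalized (lasso) single-model baseline with percentile-bootstrap
  confidence intervals via `glmnet`.
* **Effects** (`effect_table`): for each feature, the single coefficient
  β from its one-feature fit, the median and range of its associative
  coefficients across all retained models containing it, its occurrence
  rate, and the resulting class — oncogenic (both signs positive),
  protective (both negative), antagonistic (signs disagree, occurrence
  ≥ 10%), or unstable.
* **Networks** (`build_network`, `focal_subnetwork`): co-occurrence graphs
  with node size = occurrence %, node sign from the median associative (or
  single) coefficient, edge weight = co-occurrence %, edge color sign from
  bootstrap-supported Spearman correlations; exported as GraphML, TSV edge
  lists, or DOT.
* **Synthetic cohorts** (`generate_cohort`, `simpson_config`): correlated
  Gaussian features with planted conditional effects and a numerically solved
  intercept matching a target prevalence, including configurations guaranteed
  (via the sign condition β_a(β_a + β_u ρ) < 0) to produce marginal/conditional
  sign reversals — so every claim the package makes can be tested against
  generative truth.
* **Pipeline** (`run_pipeline`, `validate_frozen`): one call from cohort to
  model set, metrics, effect table, networks, and frozen models (coefficients
  plus training standardization) that can be applied unchanged to an external
  validation cohort, with a manifest for reproducibility. A thin command-line
  wrapper with `simulate` / `run` / `validate` subcommands is in
  `inst/cli/sparsewrap-cli.R`.

## Worked example

A 125-sample synthetic cohort at 44% case prevalence with three planted
effects (+3, −3, +1.5 on features `f001`, `f002`, `f003`) among 12 features:

```r
library(sparsewrap)

cfg <- cohort_config(n_samples = 125, n_features = 12, prevalence = 0.44,
                     effects = c(`1` = 3, `2` = -3, `3` = 1.5), seed = 5)
cohort <- generate_cohort(cfg)

res <- run_pipeline(cohort, test_size = 25,
                    swag = swag_config(p_max = 3, alpha = 0.25, m_models = 30,
                                       k_folds = 10, n_repeats = 2),
                    n_boot = 500, seed = 17)

res$selected
#> <swag_model_set> 5 models (dim 1: 3, dim 2: 1, dim 3: 1); 3 screened features

head(res$metrics[order(-res$metrics$accuracy),
                 c("model", "accuracy", "sensitivity", "specificity", "auc")], 3)
#>            model accuracy sensitivity specificity       auc
#> 1 f002|f003|f001     0.88   0.9166667   0.8461538 0.9358974
#> 2      f002|f003     0.80   0.7500000   0.8461538 0.9102564
#> 3           f002     0.80   0.9166667   0.6923077 0.9230769

res$effects[, c("feature", "single_beta", "median_associative",
                "occurrence_pct", "effect_class")]
#>   feature single_beta median_associative occurrence_pct effect_class
#> 1    f002  -2.1954572          -2.511358             60   protective
#> 2    f003   0.7259203           1.085973             60    oncogenic
#> 3    f001   1.1324075           1.891048             40    oncogenic
```

The search recovers exactly the three planted features (screening kept only
`f001`, `f002`, `f003`) and the three-feature panel classifies the held-out
25 samples at 0.88 accuracy / 0.936 AUC. The effect table recovers the
planted signs: negative single and associative coefficients for `f002`
(protective), positive for `f001` and `f003` (oncogenic); with independent
covariates no antagonistic call appears. `res$epv` reports the
events-per-variable of each panel size (47 events in this training split: 15.7
at size 3), `res$lasso` the baseline (3 features selected, 0.92 test
accuracy, bootstrap CIs per metric), `res$network` the co-occurrence graph,
and `res$frozen` the frozen models for external validation via
`validate_frozen()`.

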