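---
title: "Model-set analysis of binary expression cohorts with sparsewrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-set analysis of binary expression cohorts with sparsewrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Expression studies that classify two tissue states (say, invasive carcinoma
versus normal breast tissue) from a few hundred continuous features usually
report a single selected model. But in sparse, highly correlated designs many
small feature combinations are statistically indistinguishable in predictive
terms, and the choice among them is close to arbitrary. `sparsewrap` takes the
opposite stance: it returns the *set* of near-equivalent sparse models and
then analyses that set as an object in its own right — which features recur,
which co-occur, and whether a feature's estimated direction of effect depends
on the company it keeps.

The base learner is logistic regression. For a feature subset
$S = \{j_1, \dots, j_d\}$,

$$\operatorname{logit} P(y_i = 1 \mid x_i) = \beta_0 + \sum_{j \in S} \beta_j x_{ij},$$

with all columns standardized so that the $\beta_j$ are comparable across
features and models. Positive $\beta_j$ means the feature raises the odds of
the positive class (an "oncogenic" direction in the tumor/normal setting),
negative means the opposite.

## The sparse wrapper search

`run_swag()` implements a greedy wrapper in two phases:

1. **Screening.** All $p$ one-feature models are scored by repeated,
   class-stratified $k$-fold cross-validated misclassification at the 0.5
   cutoff. Features whose error is at or below the empirical
   $\alpha$-quantile of the $p$ errors survive; only survivors may appear in
   any larger model.
2. **Growing.** For each dimension $d = 2, \dots, p_{\max}$: up to $m$
   candidate models are formed by sampling a retained $(d-1)$-model uniformly
   and adding one screened feature it does not contain; duplicates are removed
   after formation, and when the number of distinct achievable combinations is
   at most $m$ the exhaustive set is used instead of sampling. Candidates are
   scored by the same cross-validation and the $\alpha$-quantile retention is
   applied again within the dimension.

Two deliberate clarifications relative to common informal descriptions of
such wrappers:

* The roles of "number of CV repetitions" and "number of candidate models per
  step" are held by two separate parameters (`n_repeats`, `m_models`); they
  are conceptually unrelated even though both are conventionally called *m*.
* "Retaining the best $\alpha$ proportion" is implemented as *error
  $\le$ the inclusive empirical $\alpha$-quantile* (the
  $\lceil \alpha n \rceil$-th smallest error), with all ties at the threshold
  retained. This makes retention reproducible and well-defined under the
  heavy ties that misclassification counts produce.

A consequence of the greedy chain worth stating explicitly: the candidate
space at dimension $d$ is the set of extensions of the *retained* $(d-1)$
models, not all $\binom{p'}{d}$ subsets of the $p'$ screened features. At
$d = 2$ the two coincide (every screened singleton is retained at dimension
1). At $d \ge 3$ they can differ, both because a strong subset may extend
only unretained models and because the $\alpha$-quantile denominator is the
candidate count. The package's correctness tests therefore compare
`run_swag()` under exhaustive candidate generation against an independent
enumeration of the same greedy-reachable space (built by `combn()` plus
subset filtering), not against the unconstrained enumeration, and they verify
the unconstrained claim exactly at $d = 2$.

### Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `p_max` | 5 | largest model size; small panels keep models interpretable and keep events-per-variable high (44 events give EPV 8.8 at size 5, 11 at size 4) |
| `alpha` | 0.05 | retention proportion per step; typical useful range 0.01–0.1 — small enough that only clearly strong models survive |
| `m_models` | 100 | candidates per dimension; `Inf` requests exhaustive generation |
| `k_folds`, `n_repeats` | 10, 10 | repeated stratified CV; 10×10 is the conventional compromise between variance and cost |
| `ridge` | 1e-6 | stabilization penalty on slopes (see below) |

The defaults `p_max = 5` and `alpha = 0.05` are assumptions chosen for the
4–5-feature panel regime this package targets; both should be revisited for
data with many more informative features.

## Numerical choices

**Separation.** Small models on highly discriminative features routinely
separate the classes completely, where the logistic likelihood has no finite
maximizer. The fitter (`fit_logit()`) is penalized IRLS with a fixed tiny
ridge (default $10^{-6}$) on slopes only, never on the intercept, with
step-halving and an iteration cap; separation is detected and flagged. On
standardized inputs the penalty is orders of magnitude below the sampling
noise of any reported coefficient and cannot change a 0.5-cutoff
classification, but it guarantees the finite coefficients that the effect
analysis needs. On well-conditioned data the fit agrees with `stats::glm` to
at least four decimals (tested).

**Folds.** Cross-validation folds are stratified by class: within each
repeat, each class's indices are shuffled and dealt cyclically, the second
class continuing the deal where the first stopped, so fold sizes differ by at
most one and `k_folds = n` is exact leave-one-out. With ~44% prevalence and
$k = 10$, unstratified folds can produce single-class training sets; if that
still happens the stratification is redrawn with a perturbed seed (and
reported). Standardization parameters are always computed on the training
folds only. All models scored in one search share the same folds, which makes
their errors directly comparable and the search deterministic given its seed.

**Cutoff.** A predicted probability exactly equal to the cutoff counts as a
positive call (`>=`). Some convention must be fixed; this one is tested.

**Quantile ties.** See the inclusive-retention rule above; duplicated
columns receive identical errors and are retained or dropped together.

## Single versus associative effects

For every feature in the retained set the package reports:

* the **single** coefficient — the slope of the one-feature logistic fit;
* the **associative** coefficients — the feature's slope inside *each*
  retained model containing it, summarized by median and (min, max) range;
* the **occurrence rate** — the fraction of retained models containing it.

The classification rule (`classify_effect()`): *oncogenic* when single and
median associative coefficients are both positive, *protective* when both
negative, *antagonistic* when the signs disagree and the feature occurs in at
least 10% of the models (the default `min_occurrence`), *unstable* otherwise.
Two notes on that rule:

* The decision uses the sign of the **median** associative value; the range
  may straddle zero without triggering the antagonistic call. This keeps the
  call robust to a single unstable context.
* The 10% occurrence filter suppresses sign flips estimated from one or two
  models, where the discordance is as likely noise as structure.

Antagonism is exactly the Yule–Simpson situation: a marginal association of
one sign coexisting with a conditional association of the opposite sign,
driven by correlated covariates. In the Gaussian linear approximation the
marginal slope of a focal feature $a$ with conditional effect $\beta_a$,
confounder effect $\beta_u$ and correlation $\rho$ is proportional to
$\beta_a + \beta_u \rho$, so `simpson_config()` accepts exactly the parameter
triples with $\beta_a(\beta_a + \beta_u \rho) < 0$ and refuses the rest.

One asymmetry is intentional and documented: *predictive* evaluation always
standardizes with training-set parameters only, while the *effect* analysis
(single and associative fits) standardizes the full analysis cohort, since it
is a descriptive re-estimation on all available samples rather than an
out-of-sample claim. Whether single coefficients should instead be restricted
to the training subset is genuinely underdetermined; the package exposes the
cohort argument so either choice is one line.

## Synonyms and networks

Two features are *synonyms* when two retained models differ exactly by
swapping one for the other with test AUC differing by at most `tolerance`
(default 0, an exact tie — substitutability in the strictest sense; loosen it
deliberately). This is the substitution ("paradigmatic") axis of the model
set, complementing the combination ("syntagmatic") axis captured by
co-occurrence.

`build_network()` renders the combination axis: nodes are features sized by
occurrence percentage and signed by the median associative coefficient; edges
join features that appear together in at least one model, weighted by
co-occurrence percentage and annotated with the Spearman correlation of the
two features on the standardized design (computed there for internal
consistency with the effect analysis). `focal_subnetwork()` restricts the
model set to the models containing one focal feature, rescales all
percentages to that restricted set, and signs partner nodes by their *single*
coefficient — the view used to ask why a feature's overall direction is
stabilized by specific partners. The focal feature itself is omitted from the
graph, since it would connect to every partner at 100% by construction.

Correlation uncertainty (`bootstrap_correlation()`) uses the nonparametric
pairs bootstrap: percentile 95% intervals, two-sided p-value
$2\min(\hat F(0), 1 - \hat F(0^-))$ floored at $2/n_{\text{boot}}$ so that a
resampling p-value is never reported as exactly zero, degenerate resamples
skipped and counted. The default `n_boot = 5000` is a convention, not an
estimate.

## The synthetic cohort generator

`generate_cohort()` draws features from a correlated Gaussian — unit marginal
variance, equicorrelated blocks as configured, scaled by `noise_sd` — and
labels from the logistic model with the configured conditional effects. The
intercept is **solved** (1-D root finding on the population prevalence under
the Gaussian design), not sampled, so prevalence is decoupled from effect
sizes; labels are then per-sample Bernoulli, matching a sequentially
collected cohort, so realized class counts vary binomially around the target
(the default prevalence 0.44 mirrors a 55-case / 70-control design).

What the generator emulates: continuous standardized features, a binary
outcome at case/control proportions, a few informative features with either
sign, correlated blocks that induce marginal sign flips, and arbitrarily many
pure-noise features. What it does not emulate: heavy tails or skew of real
log-intensities (features are Gaussian by assumption — the real intensity
distribution is not characterized, and this assumption is flagged, not
defended), probe-level artifacts, batch effects, normalization, or label
noise. Passing tests on these cohorts therefore demonstrate algorithmic
correctness and statistical behaviour under the stated generative model, not
robustness to array artifacts.

## What the checks compute, at which sizes

The package's acceptance checks (in `tests/testthat/test-acceptance.R` and
recomputed by `scripts/acceptance.R`) use problem sizes chosen as the
smallest at which each property is statistically unambiguous:

* split arithmetic on a 125-sample, 70/55 cohort (exact);
* wrapper-versus-enumeration agreement on 20 cohorts of $n = 200$, $p = 8$,
  $p_{\max} = 3$, exhaustive candidates, $\alpha = 0.4$ — a retention broad
  enough that every dimension keeps several models, so the comparison
  exercises ties and thresholds rather than a single winner;
* conditional-effect recovery at $n = 20000$, reported as the deviation of
  the mean estimate over 10 generation seeds (a single draw's standard error
  at $\beta = 3$ is itself near the 0.1 mark being verified);
* antagonism detection on `simpson_config(1, 3, -0.8)` cohorts at
  $n = 2000$, 100 seeds, against a model set containing the deconfounded
  contexts, with the false-positive rate measured on matched
  independent-covariate nulls;
* bootstrap interval coverage for a null Spearman correlation at $n = 200$,
  200 replicates of 400 resamples.

## Known limitations

* The greedy chain can miss strong high-dimensional models whose
  sub-models are weak (inherent to wrappers of this family).
* Misclassification error at a fixed cutoff is a coarse, tie-heavy score;
  near-equivalent models are distinguished only up to its resolution.
* Only the logistic learner ships; the learner abstraction exists but no
  other learner is implemented.
* Effect classes are statistical statements about sign stability across
  contexts in one cohort; they carry no mechanistic or causal claim.
* Exact reproduction of any specific published split depends on that split's
  seed; with an unknown seed only the structural properties (class counts,
  error levels, sign patterns) are reproducible.
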