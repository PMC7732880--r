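---
title: "Iterative thematic categorization of regularized-model features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative thematic categorization of regularized-model features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Large household surveys describe each respondent with thousands of mostly
categorical variables. When the goal is hypothesis generation — *which
constructs are associated with a binary outcome such as child marriage?* —
a single fitted model is a blunt instrument: a handful of strong,
well-known correlates (marital duration, fertility, poverty) dominate the
coefficient ranking, and anything correlated with them is absorbed into
their coefficients and never surfaces. `themescan` implements a pipeline
built around that observation:

1. **Encode.** One-hot encode every categorical variable (one binary column
   per observed level, no reference level dropped) and z-score the
   continuous variables with training-split statistics. Keeping all levels
   preserves interpretability — "first child: female" and "first child:
   male" are separate predictors — and the collinearity this creates is
   tolerated because every downstream model is regularized.
2. **Select and refit.** Fit an L1-penalized (lasso) logistic regression to
   discard features with no detectable association, then refit the surviving
   features with an L2-penalized (ridge) logistic regression, whose dense
   coefficients are the interpretable ranking. A feed-forward neural network
   on the same lasso-selected features provides a non-linear benchmark, and
   an unpenalized logistic fit on all features provides the cautionary
   baseline.
3. **Cut at the knee.** Sort the ridge coefficients from high to low and
   keep the features above the knee — the point of maximum curvature of the
   sorted coefficient curve, where the coefficients level off. These are the
   "meaningful features" of the round.
4. **Categorize and iterate.** Domain experts code features into themes
   (the codebook). A theme qualifies in a round when enough of its features
   are above the knee. The dominant theme's features are then removed and
   the whole fit-select-cut cycle repeats on the reduced pool, letting
   weaker themes that were masked by the dominant one rise above the knee.
   Iteration stops when the test ROC AUC falls below a floor, when a round
   selects no new features, or when several consecutive rounds produce no
   new theme.

Evaluation throughout uses the fixed test split (20% of rows, stratified),
ROC AUC, and the balanced error rate `BER = 1 − 0.5·(TPR + TNR)` at the 0.5
decision threshold, which stays interpretable under the ≈41% outcome
prevalence.

## Models and their assumptions

All three classifiers model `P(y = 1 | x) = logistic(f(x))`.

* **Traditional logistic regression** (`fit_traditional_logistic`): maximum
  likelihood, no penalty, all features. With thousands of collinear one-hot
  columns and p comparable to n this fit is deliberately vulnerable —
  rank-deficient, overfit, miscalibrated — and serves as the baseline the
  regularized pipeline is compared against. Non-convergence and aliased
  coefficients are recorded, not raised.
* **Lasso → ridge** (`fit_lasso`, `select_nonzero`, `fit_ridge`): the L1
  penalty can zero coefficients exactly, so the lasso acts as the feature
  selector; the ridge refit on the nonzero set shrinks without zeroing and
  yields the coefficient profile used for knee selection. Both penalties
  are chosen by 5-fold cross-validated ROC AUC on the training split, refit
  on the full training split at the chosen penalty.
* **Lasso → neural network** (`fit_neural_network`): a fully connected
  feed-forward network on the lasso-selected features — 4 hidden layers,
  tanh activations, batch normalization before each activation, sigmoid
  output — trained with binary cross-entropy for 100 epochs in mini-batches
  of 100. Width (64 units), optimizer (Adam) and learning rate (1e-3) are
  conventional defaults for tabular inputs of this size; depth, activation,
  normalization, epochs and batch size are the method's stated
  architecture. Training is plain seeded matrix algebra, so runs are
  bit-reproducible.

## Numerical choices that matter

**Penalty grid and tie-breaking.** The λ grid is 50 values log-spaced over
[1e-4, 1e4]; features are not re-standardized inside the solver (one-hot
columns are left on their natural scale, continuous columns are already
z-scored). Because ROC AUC is rank-based, the cross-validated AUC curve is
frequently *exactly tied* over a wide λ range. The tie direction matters
and is resolved by the role of each stage: the lasso breaks ties toward the
largest tied λ (the sparsest model — it is a selection step), the ridge
toward the smallest (the least-biased coefficients — it is an estimation
step, and heavy shrinkage would push every predicted probability below the
0.5 threshold, destroying the fixed-threshold metrics while leaving AUC
untouched).

**Knee detection** (`find_knee`). Both axes of the sorted coefficient curve
are min-max rescaled to [0, 1] (curvature is not scale-invariant), the curve
is smoothed with a centered moving average, and the discrete curvature
`|y''|/(1 + y'²)^{3/2}` (central differences) is evaluated at every interior
index; the knee is the curvature argmax, ties to the smallest index. The
smoothing window default is 3. We measured the window's effect on curves
with a planted corner (steep linear descent, then a near-flat tail): a
window of `w` displaces the detected knee by `+(w−1)/2` indices, because
within the smoothed arc the slope magnitude falls from left to right and
the curvature formula rewards the flatter side. Window 3 localizes a clean
planted bend within ±1 index in 100% of 500 random corner curves; window 5
is systematically two indices late. Larger windows are available via
`smooth_window` for long noisy curves. Two degenerate cases are handled
explicitly: a straight or constant curve has no knee (flagged `flat`, all
features selected with a warning), and curves shorter than 4 points skip
knee detection the same way.

The knee estimator's known weakness is flat-region noise: on a monotone
curve whose tail has irregular small gaps, the curvature at a small kink in
a near-flat region can exceed the curvature at the true bend, because the
`(1 + y'²)^{3/2}` denominator suppresses points on steep slopes. Smoothing
mitigates but does not remove this. Consumers should treat the knee as a
levelling-off heuristic, not a changepoint estimator.

**Theme qualification.** A theme qualifies in a round when its members
among the above-knee features number at least
`max(ceil(0.05 × |selected|), 2)`. The 5% fraction is the method's rule; the
absolute floor of 2 encodes that a theme is by definition a *group* of
features for one concept, so a single feature can never qualify a theme.
At the scale the rule was designed for (36+ selected features) the fraction
term is binding and the floor is invisible; at desk-scale selections
(5–20 features) the fraction alone would degenerate to a threshold of 1.
`min_theme_size = 1` restores the pure fraction rule; `min_theme_fraction`
and `min_theme_size` are both engine options.

**Dominant theme and removal.** The dominant theme is the qualified theme
holding the largest above-knee coefficient (ties: larger summed member
coefficient, then lexicographic); a variance-based alternative is available
(`dominant_metric = "coefficient_variance"`). When a theme is removed, a
feature leaves the pool only if *every* theme it is coded to has been
removed; features with no codebook entry collect under the reserved
`uncoded` label, are reported each round for human coding, and are never
removed.

**Stopping rules**, checked after qualification in this order: test ROC AUC
below the floor (default 0.75) — this outranks the others because a
below-floor round is no longer interpretable; no feature above the knee
that was not selected in an earlier round; no new theme for 3 consecutive
rounds. A safety cap (`max_rounds = 25`) guarantees termination; reaching
it is reported as its own stop reason and treated as a failure in the
package's own validation.

**Splits.** One fixed train/test split (default 20% test) is drawn once,
stratified on the outcome, and reused by every model and every iteration
round; cross-validation folds (default k = 5, the round-robin assignment
keeping folds size-balanced within one row and class-balanced) live inside
the training split only. Normalization constants are computed on training
rows only and applied unchanged to test rows.

## The synthetic survey generator

Real individual-level survey data of this kind is access-restricted, so the
package ships a generator (`generate_schema`, `generate_survey`) with known
ground truth, and three frozen study presets used by the test suite and the
reproduction script:

* `sim_masked_themes(seed)` — the headline design. Two themed blocks of
  4 three-level categorical variables; the dominant theme's variables carry
  graded log-odds effects +1.2/+1.5/+1.8/+2.1 on their first level (real
  coefficient tables decay gradually, and a graded block gives the sorted
  curve a single unambiguous levelling-off point); the weak theme's
  variables carry only +0.10/+0.13/+0.17/+0.20 but are linked to the
  dominant theme's variables through a one-factor Gaussian copula
  (pairwise latent correlation ρ = 0.4). Conditional on the dominant
  features the weak theme contributes almost nothing, so its features sit
  in the noise band of the round-1 coefficient curve; after the dominant
  theme's removal they inherit its signal through the correlation and
  surface as a *new* theme. 25 uncoded noise categoricals (2–4 levels) and
  3 continuous variables (random location and scale, so normalization is
  genuinely exercised) complete the table; n = 4000, outcome prevalence
  calibrated to 0.41.
* `sim_support_recovery(seed)` — 250 binary variables (500 one-hot
  features), 20 informative with effects drawn from U(0.75, 1.5);
  n = 5000. Used to check that the lasso retains the planted support and
  the ridge refit discriminates.
* `sim_wide_collinear(seed)` — 100 three-level categoricals plus 20
  continuous variables (320 features) against n = 350, with a 10-variable
  collinear signal block (ρ = 0.5, effects +1.2). Used to check that the
  regularized pipeline beats the traditional fit when p ≈ n.

Shared generator mechanics: per-variable category probabilities are drawn
from a symmetric Dirichlet (concentration 1); for *themed* variables the
draw is rejection-sampled so no category is rarer than 0.15 — planted
effect levels mimic the common survey categories (education, wealth
quintiles) that carry signal in real data, and rarer levels would make the
planted truth unobservable at these sample sizes. The outcome is drawn from
a logistic model over the planted one-hot effects; the intercept is
calibrated by bisection against the Monte-Carlo prevalence on the realized
covariates (tolerance 0.005, at most 50 steps — no closed form exists under
mixed designs). The masking copula threads a shared standard-normal factor
through the latent uniforms of both themes' variables.

**What the generator does not emulate:** survey weights and multi-stage
sampling design, skip patterns and structured missingness, the scale of the
real data (tens of thousands of rows, thousands of variables), and real
codebooks in which human coders disagree. Passing tests on these synthetic
designs therefore demonstrate that the *machinery* behaves as specified
(recovery, masking, bookkeeping, determinism), not that any particular
substantive finding about child marriage would replicate.

## Problem sizes used in validation

The package's own test suite and the reproduction script run at deliberate
desk scale: metric oracles on 1000 random instances of up to 200
observations; knee localization on 500 random and 500 corner curves;
support recovery over 5 seeds at n = 5000 × 500 features; model ordering
over 5 seeds at n = 350 × 320 features; masked-theme recovery over 20 seeds
at n = 4000; and reproducibility of the full pipeline (including the neural
network) at n = 1200. Expected behavior at these sizes was measured before
the expectations were frozen; the masked-theme recovery rate, for example,
is required to reach 80% of seeds, and the suite measures ~85%.

## Known limitations

* The knee rule inherits the curvature estimator's noise sensitivity
  described above; on real coefficient curves with no clean cliff it can
  select very small or very large prefixes. The per-round
  `features_by_round.csv` output exists so analysts can inspect the curve
  rather than trust the cut blindly.
* With a fixed codebook, "new theme" necessarily means "a known theme that
  newly qualified". The interactive mode of real use — human coders writing
  new codebook entries between rounds — is supported by editing the
  codebook and re-running with the same seed and split, but no interactive
  prompt is built in.
* The qualification floor means runs whose knee selects a single feature
  stop with `no_qualified_themes` rather than removing that feature's
  theme; this is intentional (one feature is not a theme) but differs from
  the pure 5% rule.
* The neural network reports no coefficient curve, so it never drives knee
  selection or iteration; it is an evaluation benchmark only, consistent
  with its role as a black-box comparator.
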