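---
title: "Shortening polytomous PROM scales: adaptive testing vs regression trees"
author: "promcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shortening polytomous PROM scales: adaptive testing vs regression trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promcat)
```

## The problem

Patient-reported outcome measures (PROMs) such as the cleft-specific
quality-of-life scales this package emulates are short batteries of ordered
polytomous items (3 or 4 response options each). Administering every item of
every scale burdens respondents, so two families of methods shorten the
assessment:

* **Computerized adaptive testing (CAT)** under an item response theory
  model: after each response the respondent's latent-trait posterior is
  updated and the next most informative item is chosen, until a stopping
  rule fires.
* **Binary regression trees** built by recursive partitioning: a tree maps
  item responses — and, unlike CAT, clinician-reported variables such as age,
  gender or cleft type, available at no cost to the respondent — to a
  predicted scale score. The tree is built once, in advance, so no scoring
  happens between items.

`promcat` implements both, plus a seeded synthetic-cohort generator and a
matched-length evaluation harness, so that the accuracy trade-off between
the two can be studied end to end under controlled conditions.

## Measurement model

Items follow the **partial credit model** (PCM), the Rasch-family model for
ordered polytomous responses. For an item with step thresholds
$\delta_1, \dots, \delta_K$ (so $K+1$ categories) the probability of
category $k \in \{0,\dots,K\}$ at person location $\theta$ (logits) is

$$
P(X = k \mid \theta) \;=\;
\frac{\exp\!\sum_{j \le k} (\theta - \delta_j)}
     {\sum_{m=0}^{K} \exp\!\sum_{j \le m} (\theta - \delta_j)},
$$

with the empty sum for $k = 0$ equal to zero. Discrimination is fixed at 1
(the Rasch constraint), which buys *sum-score sufficiency*: persons
answering the same items with the same raw sum get the same estimated
score. That property is load-bearing later.

**Calibration** (`pcm_calibrate()`) maximizes the marginal likelihood under
a standard-normal latent-trait prior with a fixed-quadrature
expectation–maximization algorithm: the E-step computes each person's
posterior over the quadrature nodes, the M-step refits each item's
thresholds by BFGS with an analytic gradient. The prior is never updated;
anchoring the latent scale to N(0, 1) is what makes scores reportable as
person-location logits.

**Scoring** (`eap_score()`) is expected a posteriori (EAP): the posterior
mean over the same grid, with the posterior SD as the standard error. Any
subset of items may be scored, including none (the prior mean, 0).

### Numerical choices

* Quadrature: 61 equally spaced nodes on $[-6, 6]$, standard-normal weights
  renormalized to sum to 1. Equally spaced rules on smooth, rapidly
  decaying integrands are effectively trapezoidal and converge very fast;
  the test suite holds the default grid to within $10^{-3}$ logits of a
  $10^5$-point reference integration, so the node count is not a tuning
  knob that matters.
* EM convergence: maximum absolute threshold change below $10^{-4}$ logits,
  at most 500 cycles. Non-convergence sets a flag and warns — never silent.
* Categories are 0-based consecutive integers everywhere (files and
  memory).
* Calibration refuses items with unobserved categories (the parameter would
  not be identified) and names the item and category in the error.

## The adaptive test

`run_cat_session()` implements fixed-length CAT with **minimum expected
posterior variance** (MEPV) item selection: for each candidate item $i$ the
engine computes

$$
\mathrm{EPV}(i) \;=\; \sum_k \hat P(X_i = k)\;
\mathrm{Var}(\theta \mid \text{data}, X_i = k),
$$

where $\hat P$ is the posterior-predictive category probability under the
*current posterior* (not a point estimate), and administers the candidate
minimizing it. Applied to the fresh prior this same rule picks the first
item, i.e. the item most informative in a general population. Ties break to
the lexicographically smallest item id so sessions are reproducible.
Stopping is purely fixed-length — no standard-error or content rule — and
simulated respondents answer from their pre-recorded full-length response
vectors, so no response resampling occurs.

Two consequences worth noting. First, with the full bank administered, CAT
scoring coincides exactly with full-scale EAP (likelihoods are
order-invariant); the suite asserts this per person. Second, MEPV does not
depend on how many items remain, so a session of length $m$ is a prefix of
the same person's session of length $m' > m$ — the harness exploits this to
evaluate several matched lengths from one simulated session per person.

## The regression tree

`reg_tree()` grows a binary least-squares tree (`grow_tree()`) on a
training table of item responses (ordered; threshold splits), an
out-of-scale "overall appearance" rating (ordered, counted as an item), and
clinician-reported covariates (categorical ones use exhaustive subset
search, capped at 12 levels). The outcome is the ground-truth
person-location logit. Growth follows the comparison design: limited
*only* by a prespecified maximum depth, with a minimum of 2 observations
per node and no complexity threshold during growth.

Branches that do not generalize are removed afterwards by **cost-complexity
pruning**: the nested weakest-link sequence of subtrees is computed from
the per-leaf SSE improvement $g(t) = (R(t) - R(T_t))/(|T_t| - 1)$ scaled by
the root SSE, and the complexity parameter is chosen to minimize squared
prediction error in a seeded 10-fold cross-validation
(`cv_select_cp()`) — the plain CV minimum, not the 1-SE rule. Ties go to
the larger cp (the simpler tree). Fold assignment is recorded on the fit.

Prediction (`predict()`, `predict_with_accounting()`) routes a person to a
leaf and reports the leaf's mean training logit, plus the number of
*items* the path consumed: splits on scale items and on the
overall-appearance item count, clinician-reported splits are free, and
repeated splits on the same item along a path count **once** by default — a
respondent answers an item a single time and the answer can be reused
(`count_repeated_items = "per_split"` implements the other reading).

## The synthetic cohort generator

`generate_item_bank()` / `generate_cohort()` define the study conditions;
they emulate the statistical structure of a cleft-related PROM field test,
not any particular dataset:

* **Scale**: 8 items by default, 3 or 4 ordered categories (4 by default).
  Item locations are N(0, spread²) with centered, ordered category-step
  offsets also scaled by the spread; the default spread of 1 logit gives
  realistic threshold ranges (roughly ±3 logits) while keeping every
  category observed in cohorts of a couple of thousand. Spread 0 collapses
  every threshold to 0, a useful degenerate case for tests.
* **Latent trait**: standard normal, shifted additively on the logit scale
  by covariate effects — the simplest structure consistent with clinical
  variables being weak predictors of the measured construct.
* **Covariates** (defaults in `default_covariates()`): age (uniform 8–29),
  gender, cleft type (4 levels), laterality (3 levels), planned treatment.
  Effects are deliberately small (0.1–0.3, at most 0.4 logits): the
  literature this design follows reports clinical variables as weak
  predictors relative to item responses, and no printed effect sizes exist
  to calibrate against, so the defaults are chosen once to reproduce that
  qualitative regime and are not revisited per experiment.
* **Overall-appearance item**: a 4-category PCM response driven by
  $\lambda\theta + \sqrt{1-\lambda^2}\,\varepsilon$ with loading
  $\lambda = 0.7$. In a unit-discrimination PCM the thresholds cannot set a
  correlation, so the loading enters through this attenuated latent input;
  the item is available to trees but excluded from the CAT bank, which may
  only use the calibrated scale.
* **Determinism**: the config seed fully determines the bank (seed) and the
  cohort (seed + 500000), and all generator randomness is scoped so global
  RNG state is untouched.

Synthetic data are *complete by construction*; real field-test missingness
patterns, multi-scale batteries and differential item functioning are out
of scope. Passing tests therefore demonstrate correctness of the machinery
and the qualitative behaviour of the two methods under a clean
unidimensional Rasch world — not performance on any real cohort.

## The comparison experiment

`run_experiment()` reproduces the comparison protocol end to end:

1. calibrate the PCM on the whole cohort and EAP-score everyone on the full
   scale — these scores are the **ground truth** both methods try to
   recover;
2. split persons 2:1 into training and test sets (seeded);
3. recalibrate on the training set only; the CAT uses these parameters;
4. grow and CV-prune the tree on the training rows (outcome: the
   whole-sample ground-truth logits — the quantity the design says trees
   predict — with items, the overall-appearance rating and covariates as
   predictors);
5. per matched length $L$ (defaults: 75% and 50% of the scale, i.e. 6 and
   4 items for an 8-item scale, with tree `max_depth` set equal to the CAT
   fixed length), simulate CAT sessions and tree predictions for every
   test person;
6. report per-person paired predictions and the aggregate metrics: mean
   items per arm, Pearson's r, MAE, RMSE, the count of unique attainable
   scores, and a two-sided Wilcoxon signed-rank test on paired squared
   errors (exact distribution — via a generating-function convolution that
   stays exact under midrank ties — for up to 25 nonzero differences,
   tie-corrected normal approximation above).

### Problem sizes

The packaged experiments and tests use cohorts of n = 1800 (1200 train /
600 test), the scale of the per-scale samples in the field-test literature
this design emulates, and 10 replicate seeds for the qualitative claims;
smaller fixtures (n = 120–1000) exercise individual components. A full
n = 1800 experiment runs in well under a minute on one core.

### What replicates, and one caveat

Across replicate seeds, the adaptive test is consistently more accurate
than the matched-depth tree at both lengths, the tree's first split is an
item response rather than a clinician-reported variable (the weak-covariate
regime), and trees pose fewer questions than their CAT comparators (pruning
and free clinician splits shorten paths). At the half-length limit the tree
also attains far fewer unique scores than the CAT — the polytomous
underfitting phenomenon: a depth-$d$ binary tree can output at most $2^d$
values, while the adaptive test distinguishes many more response patterns.

The caveat: at the 75% limit on a *short* scale, the unique-score ordering
can invert. Rasch sum-score sufficiency caps the CAT's distinct scores near
(number of administered item sets) × (distinct raw sums), only a few dozen
on an 8-item scale, while a depth-6 tree predicting a noiseless
deterministic function of its predictors legitimately retains most of its
64 possible leaves under honest cross-validation. Underfitting comparisons
are therefore assessed at the half-length limit, where the phenomenon is
unambiguous; the longer-scale, lower-category settings in the motivating
literature do not hit this ceiling.

## Known limitations

* Unidimensional PCM only: no 2PL/graded-response discrimination, no
  multidimensional traits, no item-fit machinery.
* The tree learner is CART-style binary splitting; multiway (e.g.
  chi-square-based) splits, surrogate splits and forests are out of scope.
* The Wilcoxon exact path enumerates up to 25 nonzero differences;
  degenerate all-zero comparisons return p = 1 with a flag rather than an
  error.
* The generator produces complete responses; conclusions about missing-data
  behaviour cannot be drawn from it.
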