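---
title: "Methods: PLS regression for fitness task-time prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLS regression for fitness task-time prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firefit)
```

## The model and its assumptions

`firefit` models p task completion times jointly as linear functions of m
physical fitness predictors through a small number of latent components.
Both blocks are autoscaled (centered, unit variance) before extraction: the
predictors span incomparable units — kilograms, percent, watts, mL/kg/min —
so covariance-scale PLS would let the watt-scale power variables dominate
the weights, and correlation-scale (autoscaled) PLS is the defensible
default. The responses are autoscaled too, so tasks measured in thousands
of seconds (a 5 km run) and tens of seconds (a rope climb) contribute
comparably to component extraction and to PRESS.

Each component takes the unit predictor weight vector `w` as the dominant
left singular vector of `E'F`; the score `t = E w` is the predictor
combination with maximal covariance with a response combination. The
classical chemometrics literature describes this as making the predictor
score "maximally correlated" with the response score; covariance and
correlation are not distinguished there, and the package implements the
standard maximal-covariance criterion, which is what the singular-vector
construction delivers.

The loadings are least-squares projections of each block on the score
(`alpha = E't/||t||^2`, `beta = F't/||t||^2`), and both blocks are deflated
by the score's rank-one reconstruction: `E - t alpha'`, `F - t beta'`.
Deflating the response block by `t beta'` (rather than by the response
score `u`) is the regression-mode convention: `beta` was estimated by
regressing `F` on `t`, so `t beta'` is the part of `F` the component
actually explains, and the residual enters the next extraction. The two
textbook presentations of the decomposition (one writes the response block
expansion in `u`, one estimates `beta` from `t`) disagree on this point;
the package follows the estimate.

Assumptions inherited from the model class: linearity of the
predictor-response map, exchangeable subjects, and responses whose
conditional mean is captured by at most `min(n - 1, m)` latent directions.
Nothing in the solver assumes the predictors are full rank — PLS is the
tool of choice precisely when they are collinear — but with exactly
rank-deficient predictors the coefficient matrix is not identified (only
predictions are), which matters for how parameter-recovery checks must be
posed (see below).

## Numerical choices

* Weight vectors come from `svd(E'F)` rather than the iterative NIPALS
  inner loop; the two agree at convergence, and the direct decomposition
  has no tolerance to tune at these sizes (m = 5, p = 7). The sign is fixed
  so the largest-magnitude entry of `w` is positive, removing the
  sign indeterminacy of singular vectors and making serialized models
  byte-reproducible.
* Extraction refuses to proceed when `E'F` is numerically zero (Frobenius
  norm below 1e-12 relative to the block norms): there is no
  predictor-response association left to model.
* Coefficients are accumulated through the basis-correction vectors
  `r_a = w_a - sum_{b<a} r_b (alpha_b' w_a)`, giving `B_std = R beta'` in
  one pass; the identity "prediction via components equals prediction via
  `(B, b0)`" is asserted in the test suite at 1e-10 relative.
* Zero-variance columns are rejected by name during standardization rather
  than silently producing NaN.
* The component cap is `min(n - 1, m)`; leave-one-out selection further
  caps at `min(n - 2, m)` because each fold loses a row.

## Component selection

`PRESS(h)` refits the h-component model n times, each time excluding one
subject, with centering and scaling re-estimated inside the fold so no
information leaks from the held-out row. Errors are accumulated on a
standardized response scale (the full-data response standard deviations by
default, configurable) so high-variance tasks do not dominate. `SS(h)` is
the in-sample residual sum on the same scale, and `SS(0)` — needed by the
Q² of the first component — is the centered total sum of squares, the
standard cross-validity baseline (the h = 0 "model" predicts each task's
mean). On that scale `SS(0) = p (n - 1)` exactly.

Components are retained while `Q²_h = 1 - PRESS(h)/SS(h-1)` stays at or
above `1 - 0.95² = 0.0975`, and extraction stops at the first violation
(the SIMCA-style reading of "stop once cross-validity drops below the
limit"). Extraction also stops early when the residual response sum falls
below 1e-10 of the baseline — the model is already exact and further Q²
ratios would divide by numerical zero. If even the first component fails
the threshold, the selection still returns a one-component model flagged
`significant = FALSE`: downstream stages need a model, and the flag
preserves honesty. Whether the original study ran leave-one-out on all 20
subjects or on its 16-subject training split is not recorded anywhere; the
package exposes both (selection runs on whatever rows it is handed, and
the pipeline's `all` stage hands it the training split).

## Sensitivity analysis

The perturbation grid steps each predictor through
`x_min + c (x_max - x_min)` for `c = -0.2, 0, 0.2, ..., 1.2` — eight
levels from 20% of the range below the observed minimum to 20% above the
maximum — while every other predictor sits at its cohort mean. The two
outermost levels deliberately extrapolate beyond the observed range; the
package emits a notice rather than refusing, since that extrapolation is
part of the protocol being reproduced. Because the fitted model is linear,
every curve is exactly affine with per-step increment
`0.2 · x_dif_j · B[j, ]`, which the tests assert to 1e-9 relative.

Trend classification labels a (predictor, task) curve `negligible` when
its total excursion is below `flat_tol` times the all-means prediction,
else by slope sign. The source protocol never quantifies "little change";
the default `flat_tol = 0.02` (2% of the baseline prediction) is this
package's operationalization, chosen once and configurable.

## Evaluation

The headline metric is `100 · (1 - mean |ŷ - y| / y)` per task — one
hundred minus the mean absolute relative error in percent — floored at
zero, with the overall figure the unweighted mean over tasks. Published
accuracy percentages in this literature rarely state their formula; mean
absolute relative error is the most common reading for strictly positive
task times, and `1 - NRMSE` and `R²` variants are available behind the
`metric` argument for comparison. The 80/20 split takes
`round(n · 0.2)` (at least 1) subjects at random into the test set,
seeded; training accuracy is computed by leave-one-out within the training
split, test accuracy by refitting on the whole training split and
predicting the held-out subjects.

## The synthetic generator

No subject-level data were ever published for the motivating cohort — only
per-predictor means, minima and maxima — so the generator emulates the
statistical structure the analysis assumes rather than any real records:

* `n = 20` subjects, matching the cohort size;
* latent rank 2 by default, with spherical standard-normal latent scores —
  the minimal exchangeable latent structure implicit in a PLS analysis.
  The two default traits encode the qualitative pattern the literature
  reports: a fitness trait (high VO₂max and muscular power, low body fat)
  that shortens all task times, and a body-mass trait that lengthens
  climbing tasks while mildly shortening load-carry sprints;
* Gaussian column noise at 0.3 standardized units on both blocks — chosen
  once so that Q² selection typically retains the two generating
  components at n = 20, documented as a default rather than an empirical
  claim;
* each predictor column affinely mapped so its empirical minimum and
  maximum equal the published cohort extremes exactly. Exact pinning
  (rather than distributional matching) makes cohort-summary
  reconstructions deterministic;
* each response column affinely mapped onto ±30% around a baseline task
  time. The baselines (25, 210, 15, 95, 240, 1500, 20 seconds for the
  seven tasks) are invented: no response summaries were ever published.

What passing tests on this generator do show: the solver, selection rule,
sensitivity procedure and evaluation metrics are internally correct and
recover known structure (rank, coefficient signs, near-perfect prediction
in the noise-free limit). What they cannot show: that any particular
accuracy figure from real cohorts is reproducible — real fitness data have
non-Gaussian marginals, heteroscedastic measurement error and
subject-level dependence that the generator deliberately omits, and the
cohort's raw records remain unpublished. The pinned evaluation band in the
test suite (leave-one-out accuracy between 90 and 100 on the default
configuration) is a regression guard for this generator, not a claim about
firefighters.

Parameter-recovery checks are posed with care around two identifiability
traps. First, predictor-side measurement noise attenuates any estimated
least-squares map below the generating map (classical errors-in-variables
bias), so the coefficient-convergence check runs with response-side noise
only. Second, with rank-deficient predictors the coefficient matrix is
non-identified — the minimum-norm solution depends on the metric, and an
autoscaled fit and an unscaled pseudo-inverse legitimately disagree while
producing identical predictions — so that check runs at full latent rank
(5), where the map is unique. The suite checks it at n = 2000 draws to
0.05 elementwise; other solver identities are asserted on small randomized
instances (n ≤ 30), and the large-sample oracle for the generator's true
map uses 10⁵ noise-free draws.

## Pipeline and reproducibility

`run_pipeline("all", cfg)` chains read → summary → 80/20 split → component
selection on the training rows → fit → sensitivity → evaluation, writing
every intermediate artifact as CSV (plus a plain-text model serialization)
with a configuration fingerprint in a comment line. All randomness flows
from the single master seed through independent per-stage derived streams,
so outputs are byte-identical across reruns and changing one stage's draws
cannot shift another's.

## Known limitations

* Coefficients on exactly collinear predictors are reported in the
  autoscaled minimum-norm convention; compare predictions, not
  coefficients, across conventions.
* No missing-data handling, no nonlinear or kernel PLS, no k-fold or
  Monte-Carlo cross-validation variants, no permutation significance of
  Q² — all out of scope by design.
* The accuracy metric floors at zero; models worse than "always predict
  the observed value doubled" are indistinguishable at 0%.
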