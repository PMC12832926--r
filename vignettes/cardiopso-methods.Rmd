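---
title: "Methods: swarm-tuned diagnostic classification for tabular cardiac cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swarm-tuned diagnostic classification for tabular cardiac cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiopso)
```

# Overview

`cardiopso` implements a complete diagnostic-classification workflow for
tabular cardiac cohorts in the 14-attribute heart-disease schema (age, sex,
chest-pain type, resting blood pressure, cholesterol, resting ECG, fasting
blood sugar, maximum heart rate, exercise angina, ST depression, ST slope,
vessel count, thalassemia status, and a binary disease target):

1. a **data-refinement pipeline** — forward-fill imputation, exact-duplicate
   removal, interquartile-range (IQR) fence-outlier median imputation, and
   robust scaling;
2. an **improved particle swarm optimizer (IPSO)** — a continuous PSO with a
   linearly decaying inertia weight and Gaussian mutation — that jointly
   searches a binary feature mask and a classifier's hyperparameters;
3. a **clinical metric panel** — accuracy, balanced accuracy, sensitivity,
   specificity, precision, F1, NPV, MCC, informedness, markedness, the
   likelihood ratios LR+ and LR−, and the diagnostic odds ratio (DOR);
4. a **synthetic cohort generator** with a planted logistic signal and a
   ledgered corruption model, so everything is testable offline;
5. an **experiment harness** for split grids, ablations, repeated-split
   paired *t*-tests, and feature-selection frequency analysis.

# The refinement pipeline

`run_pipeline()` applies four stages in a fixed order. The order matters:
duplicates are compared on raw forward-filled values, and fences are
estimated on the deduplicated table.

* **Forward-fill ("padding") imputation.** Each missing cell takes the
  nearest preceding observed value in its column. A leading missing value
  has no predecessor, so it is an error naming the column rather than a
  silent guess.
* **Exact-duplicate removal** keeps first occurrences in order.
* **Fence-outlier median imputation.** Quartiles use linear interpolation
  between order statistics (`stats::quantile` type 7 — R's default, stated
  here explicitly because quartile conventions change fence positions).
  Values strictly outside `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` are replaced by
  the column median, computed once before any replacement. This is a
  **single detect-and-replace pass**: replacing extremes shifts the
  quartiles, so re-detection on the output can in principle flag new
  points. The operation is idempotent *given the detection-time fences*,
  which `impute_outliers_median()` returns and the test suite asserts; it
  is deliberately not a fixed-point loop, which could erode genuine tail
  mass. Only the continuous columns (age, trestbps, chol, thalach,
  oldpeak) are fenced by default — fences on categorical codes are
  meaningless.
* **Robust scaling**, `(x − median)/IQR`. Two fit modes exist.
  `scale_fit = "paper"` (the default) estimates the parameters on all rows
  before any split — the protocol of the composite-cohort study this
  package reproduces, kept as the default so its headline numbers
  regenerate verbatim. `scale_fit = "safe"` freezes the parameters on a
  supplied training subset and applies them to held-out rows, which is the
  leakage-free choice for new studies; the experiment harness audits its
  splits either way. Columns with zero IQR on the fit subset cannot be
  scaled and pass through flagged as degenerate.

# The IPSO engine

`ipso_optimize()` maximises a black-box fitness over the unit hypercube.
Each particle holds a position `x` and velocity `v` in `[0,1]^d`; per
iteration, for every dimension independently (`r1`, `r2` drawn per
dimension, which avoids the rank-one step bias of per-particle draws):

```
v ← w·v + c1·r1·(pbest − x) + c2·r2·(gbest − x)
x ← clip(x + v, 0, 1)
```

* **Inertia schedule**: `w` decays linearly from `w_max = 0.9` to
  `w_min = 0.4` across iterations — exploration first, exploitation last.
  `inertia_at(cfg, 0)` is exactly 0.9 and `inertia_at(cfg, max_iter)`
  exactly 0.4.
* **Gaussian mutation**: with probability `p_mutation = 0.1` per particle
  per iteration, *every* coordinate of that particle is perturbed by an
  independent draw from Normal(0, σ = 0.1), then clipped. Mutating the
  whole particle (rather than single coordinates) gives the escape jump a
  meaningful step length in high dimension at the same trigger rate.
* **Boundary handling** is clipping, and velocities are clamped to
  `±v_max_fraction = 0.25` of the unit range; both are least-surprise
  choices where the method description is silent.
* **Elitism**: `gbest` is updated asynchronously (within the evaluation
  sweep) and can only improve; the recorded history — length
  `max_iterations + 1`, one entry after the initial evaluation and one per
  iteration — is non-decreasing by construction and is asserted so in
  tests.
* **Budget**: exactly `n_particles × (max_iterations + 1)` fitness
  evaluations. The defaults (50 particles, 100 iterations, c1 = c2 = 2)
  follow the published configuration. `standard_pso_config()` degenerates
  the engine to fixed inertia and no mutation, giving a plain PSO baseline
  with the identical code path.

## Joint feature and hyperparameter search

`build_space()` maps the hypercube onto 13 mask dimensions (≥ 0.5 means
the feature is selected; an all-off mask is repaired to the single highest
coordinate, since an empty feature set is unlearnable) plus per-family
hyperparameter dimensions — e.g. a log10-scaled regularisation strength
for logistic regression, or tree count / depth / learning rate /
subsampling for gradient boosting. Integer dimensions round half-up.
Fitness is the mean positive-class F1 across stratified k-fold
cross-validation on the *training* portion only, memoised by decoded
specification, so re-visited positions cost nothing.

# Model families

Five families share one interface (`fit_final()`, `predict()`): ridge
logistic regression (glmnet), Gaussian LDA with covariance shrinkage
toward the average diagonal (implemented in-package because the standard
LDA implementation exposes no shrinkage; it matches `MASS::lda` at
shrinkage 0), Gaussian naive Bayes with variance smoothing (e1071, with
the smoothing applied post-fit as `sqrt(sd² + vs · max var)`), an RBF
support-vector classifier (e1071), and gradient-boosted trees (xgboost,
single-threaded and seeded for determinism).

# The metric panel

`metric_panel()` and `likelihood_ratios()` compute the full clinical panel
from a confusion tally. Division-by-zero policy is explicit: proportion
metrics either error (default) or return 0 (`zero_division = "zero"`);
likelihood ratios with empty cells return flagged infinities unless the
Haldane–Anscombe +0.5 correction is requested. Printed tables round
**half-up** (`round_half_up()`), not banker's rounding, because that is
the convention of the published result tables the package reproduces:

```{r}
counts <- confusion_counts(tp = 38, tn = 46, fp = 3, fn = 5)
panel <- metric_panel(counts)
round_half_up(100 * as.numeric(panel$accuracy), 2)   # 91.30
likelihood_ratios(counts)$dor                        # 116.53...
```

# The synthetic cohort generator

`generate_cohort()` emulates the composite cohort's *schema and marginal
shape*, not its joint distribution: continuous attributes are truncated
normals centred mid-range with sd = range/6; categorical codes are uniform
except sex (76% male, matching the published cohort); the binary target
follows a logistic model over a chosen set of standardized informative
features, with the intercept calibrated by root-finding so the expected
prevalence equals the configured value (52.86% by default). The returned
`truth` object records the planted signal, enabling recovery tests.

`corrupt_cohort()` injects pathologies against a ledger: per-attribute
missing counts mirroring the published cohort's missingness profile
proportionally, 22.69% duplicate rows, and fence outliers placed at
fence ± 3·IQR. Duplicates are inserted before cell corruption, and
corrupted cells avoid rows involved in duplicate pairs, so the pipeline's
log counts provably equal the ledger (a blanked duplicate would no longer
match its twin exactly). This is an emulation for testing, not a
generative model of real patients — correlations between attributes are
absent by design, and results on it quantify the machinery, not clinical
performance.

# Numerical and testing choices

* Quartiles: type 7 everywhere (fences, robust scaling); stated once,
  used consistently.
* Rounding for printed comparisons: half-up at the printed precision.
* All stochastic components draw from explicit seeds; sub-seeds derive
  affinely and stay below 2³¹.
* The stochastic test problems are sized as the package's own choices:
  selection recovery uses a 1,000-row cohort with 3 planted and 10 decoy
  features over 20 independent 15-particle × 20-iteration runs; the
  improvement property compares tuned and default gradient boosting over
  10 seeded 90:10 splits of a 600-row cohort with a 6 × 8 swarm and
  3-fold fitness. These are desk-scale budgets chosen to separate signal
  from noise within minutes on one CPU, not the published full-scale
  configuration.

# Limitations

* The generator's independence assumption means feature-interaction
  effects (and any metric sensitive to them) are untested against realism.
* Forward-fill imputation is order-dependent; it reproduces the studied
  protocol but is not recommended for cohorts where row order is
  meaningless — consider model-based imputation there.
* `scale_fit = "paper"` leaks test-row location/scale information into
  preprocessing; use `"safe"` for honest generalisation estimates.
* DOR and the likelihood ratios are unstable at small or zero cell
  counts; the flagged-infinity/Haldane policy makes this explicit rather
  than solving it.
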