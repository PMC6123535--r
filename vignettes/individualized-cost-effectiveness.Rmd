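---
title: "Individualized cost-effectiveness analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized cost-effectiveness analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`indicer` implements an individualized cost-effectiveness analysis for a
two-arm depression trial comparing treatment as usual (TAU) with blended
treatment (BT, integrated face-to-face plus internet-based therapy). Instead
of the classical population-level incremental cost-effectiveness ratio
(ICER), the package predicts each patient's six-month quality-adjusted life
years (QALYs) and societal costs under *both* arms from baseline
characteristics alone, places the predicted differences on the
cost-effectiveness plane, and recommends an arm per patient at a
willingness-to-pay (WTP) threshold. This vignette explains the statistical
machinery, the assumptions behind it, and the design decisions that were
genuinely open.

## The model

For outcome $o$ (QALY), cost $c$, baseline features $b$ and treatment type
$tt \in \{\mathrm{TAU}, \mathrm{BT}\}$, the joint conditional distribution
is factorized as

$$p(o, c \mid b, tt) = p(o \mid b, tt)\, p(c \mid b, tt),$$

i.e. outcome and cost are modelled independently given baseline and arm — a
deliberate simplification justified by the small per-arm sample sizes. Each
of the four (arm, target) pairs gets its own regression fitted only on that
arm's patients; predicting a patient under the arm they did not receive is
then an ordinary model evaluation. Cross-arm leakage is structurally
impossible and is verified by a perturbation test in the suite.

### Outcomes and costs

* **QALYs.** EQ-5D-5L response profiles are valued into utility weights by a
  pluggable value set; utilities at months 0, 3 and 6 are linearly
  interpolated and integrated over the 0.5-year horizon (trapezoidal rule).
  The horizon makes 0.5 the attainable maximum. Worse-than-death states are
  admitted down to utility $-0.5$, so QALYs live in $[-0.25, 0.5]$.
  A patient whose trajectory stops short of the horizon has the last
  utility carried forward; patients missing the six-month endpoint are
  excluded at the merge stage rather than extrapolated.
* **Costs.** Societal perspective: resource quantities times unit costs,
  plus productivity losses valued at an hourly rate, plus a fixed platform
  cost for every BT participant (hosting, maintenance, therapist feedback
  on the online modules). No discounting: at six months it would be
  vacuous.

### Learners and evaluation

Six learners are registered: the intercept-only *mean reference*, OLS,
ridge, lasso, a CART regression tree and $\varepsilon$-insensitive support
vector regression. The mean reference is the yardstick — a method that
cannot beat the training mean of the target has no business influencing
allocation decisions.

Evaluation is leave-one-out cross-validation (LOOCV), pooled over both
arms, scored by MAE and RMSE, with a two-sided Wilcoxon signed-rank test on
the paired absolute errors against the reference. Two tuning modes exist:

* `tuning = "pretuned"` (pipeline default): one k-fold grid search per
  (arm, target) fixes the hyperparameters, then LOOCV refits with them.
  This mirrors the common grid-search-then-LOOCV workflow. Its selection
  leakage is mild (hyperparameters, not coefficients, see the discussion of
  imputation leakage below) and it is roughly `k × grid` times cheaper.
* `tuning = "nested"`: a full inner 5-fold grid search inside every LOOCV
  training fold — no leakage, at substantial cost. Available everywhere.

Default grids: ridge $\lambda \in 10^{\{-2,\dots,4\}}$ (13 log-spaced
points); lasso along its own penalty path from $\lambda_{max}$; tree depth
$\{2,3,4,5\}$ × min-leaf $\{5,10,20\}$; SVR $\varepsilon \in \{0.01, 0.1\}
\cdot \mathrm{SD}(y)$ with RBF kernel at $C \in \{0.1,1,10,100\}$ and
linear kernel at $C \in \{0.1,1\}$. The linear kernel's $C$ range is
deliberately short: beyond $C=1$ the linear SVR converges toward an
unregularized linear fit (already represented by OLS/ridge) while the
underlying QP solver slows by two to three orders of magnitude. Grid-search
ties break to the earliest (simplest) grid entry.

Ridge is solved in closed form on internally standardized features with an
unpenalized intercept, so $\lambda = 0$ is *exactly* OLS and the solution
can be checked against a hand-written normal-equation oracle. The lasso
minimizes $\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2 +
\lambda\lVert\beta\rVert_1$ by coordinate descent along a warm-started
path; its published description as a penalty on "the absolute value of the
sum" of coefficients is read as the standard $\ell_1$ penalty (sum of
absolute values) — the only convex reading that produces the sparsity the
method is used for. Standardization constants always come from the
training fold only.

### Feature selection

With a few hundred mixed-type baseline features and ~175 patients per arm,
all-feature fits overfit and OLS is not even defined ($p \ge n$), so OLS is
only ever fitted after selection. `select_features_lasso()` runs
cross-validation along the lasso path, takes $\lambda^\*$ at the minimum
mean CV error, and keeps the features with nonzero coefficients —
separately for each of the four (arm, target) pairs. An empty selection
falls back to intercept-only models (the reference measure), with a
warning.

### Recommendation rule

With predicted $\Delta q = \hat q_{BT} - \hat q_{TAU}$ and
$\Delta c = \hat c_{BT} - \hat c_{TAU}$, the ICER $\Delta c / \Delta q$ is
reported where it is decision-relevant (NE and SW quadrants of the
cost-effectiveness plane) and replaced by a dominance flag in the SE
(BT dominates) and NW (TAU dominates) interiors. The *decision*, however,
is taken by net monetary benefit:

$$\mathrm{NMB} = \mathrm{WTP} \cdot \Delta q - \Delta c, \qquad
  \text{recommend BT iff } \mathrm{NMB} > 0.$$

This was a genuinely open design point: the threshold rule is only ever
stated for the NE quadrant ("above the threshold, too expensive") and says
nothing about the SW quadrant or the $\Delta q = 0$ ray. The NMB form was
adopted because it (a) reproduces the stated NE rule exactly
(ICER < WTP $\Leftrightarrow$ NMB > 0 when $\Delta q > 0$), (b) reproduces
dominance in SE/NW, (c) extends coherently to SW (recommend BT iff the
savings per QALY forgone exceed WTP) and to $\Delta q = 0$, and (d) has no
division by zero. Ties (NMB exactly 0) go to TAU as the status-quo arm — a
conservative, configurable choice. The default WTP is 25,000 €/QALY, the
conservative end of the commonly cited 25,000–35,000 €/QALY band.

### Counterfactual policy evaluation

The recommended allocation is valued by substitution: concordant patients
(received what the model recommends) keep their observed outcome and cost;
discordant patients contribute the model's prediction under the
recommended arm. Percent changes compare recommended-allocation totals to
observed totals (totals and means move identically at fixed N). Because
fitting is per-arm, the recommended-arm model never trained on a
discordant patient, so the substituted predictions are out-of-sample by
construction; a separate held-out variant would change nothing and the
`counterfactual` flag in `experiment_config()` documents this.

One behavior deserves emphasis: under a *null* trial (no effects, no
signal) this plug-in evaluation is not exactly zero-biased. The rule
routes patients toward whichever arm looks cheaper/better on noisy
predictions, and replacing skewed observed costs with near-mean
predictions trims the substituted tail — a regression-to-the-mean optimism
of a few percent. The null-preset test bounds this rather than pretending
it away; on real decisions the remedy is external validation, not a
different substitution.

## The synthetic trial generator

The real trial data are not redistributable, so the package ships a
generator that emulates their *structure* — not their content — and, more
importantly for testing, records ground-truth potential outcomes under
both arms for every patient.

A latent severity $z_i \sim N(0,1)$ drives a block of informative numeric
features ($x_{ij} = 0.8 z_i + N(0,1)$ for the first four of thirty, pure
noise otherwise), a severity-linked categorical item among ten
three-level questionnaire items, baseline PHQ-9
($\approx 15.4 + 3.5\,s_i$, the published baseline mean), baseline EQ-5D
utility ($0.62 - 0.08\,s_i$ plus noise) and baseline consultation counts.
Utilities at months 3 and 6 add a natural recovery ramp; BT adds a
per-patient effect $\delta_i$ (mean 0.03 by default) ramped 0/½/1 across
the three measurements, so the ground-truth QALY gain is
$0.25\,\delta_i$ — the closed form the generator tests verify at n = 2000.
Utilities are clamped to $[-0.5, 1]$; the default location and noise keep
clamping rare so the closed form stays sharp. EQ-5D profiles are attached
by nearest-profile inversion of the bundled synthetic value set.

Costs arise from six-month consultations (Poisson around a linear
intensity in severity and baseline use), productivity hours (linear in
severity, scaled by a lognormal factor — the `cost_lognormal_params`
dial), and rare hospital admissions (Bernoulli × admissions ×
`hospital_unit_cost`, 8% × €4,000 by default) which produce the
characteristic right-skewed societal cost tail with occasional extreme
patients. All of this randomness is drawn *once per patient* and shared
between the two potential arms; BT differs deterministically (effect ramp,
non-hospital cost multiplier, platform cost). Observed outcomes therefore
equal the assigned arm's potential outcome exactly, which is what makes
oracle-based testing of the recommendation machinery possible. At
`noise_scale = 0` (and the feature-independent dials off) the potential
outcomes are exactly linear in the observed features, so correctly
specified linear models must recover them to solver tolerance — the
strongest end-to-end check in the suite.

Missingness is MCAR by default (the source data's mechanism is
uncharacterized; only its magnitude — on the order of a quarter of
baseline cells — is known, hence `missing_rate = 0.25` as an order-of-
magnitude emulation, not a claim). A missing-at-random hook that masks
severe patients more often exists behind `mar_missingness = TRUE`.

Three presets fix study conditions: `default` (heterogeneous effect
independent of features), `informative` (effects and costs partially
predictable from features: effect modifiers on two features, feature-
driven admission risk and BT cost multiplier, slightly tamer cost noise),
and `null` (no effects, no signal, no platform cost, no admissions). The
informative preset's signal strength was calibrated once, by pilot
simulation, to the regime the analysis assumes — baseline features that
genuinely predict outcome and cost strongly enough that every learner
(including the regression tree, the weakest here) beats the mean
reference at n = 350 — and then frozen. What passing tests on this preset
shows is that the *pipeline* extracts signal where signal exists; it does
not show that any real trial's baselines carry that much signal.

## Preprocessing

The order is fixed and mirrors the analysis it reproduces: merge keyed
sources (patients missing either dependent variable are dropped; colliding
column names get source prefixes) → remove degenerate features (fewer than
two observed values, overall or within either arm — per-arm modelling
makes within-arm constants unusable) → single imputation → one-hot
encoding against the modal reference level.

Two imputation methods are provided, matching the two evaluated upstream:
median (numeric) / mode (categorical), and distribution sampling
(Normal(observed mean, observed SD) for numerics, observed frequencies for
categoricals; seeded). Median ties at even counts take the mean of the two
central values; mode ties take the lexicographically smallest level — both
logged conventions, since the upstream choice is unstated. Imputation
statistics are computed on the full dataset before CV splitting, exactly
as the reproduced workflow implies; this leaks a small amount of held-out
information into every training fold. It is documented rather than
silently "fixed" because changing it would change the thing being
reproduced; recomputing imputation inside each LOOCV fold is a
straightforward strict variant a user can build from the exported stage
functions.

The PHQ-9 improvement summary uses the unequal-variance (Welch) t-test on
the six-month scores; the source says only "a t test", and Welch is the
safer default under arm-wise variance differences.

## Numerical choices and degenerate inputs

* Ridge/OLS: QR; rank-deficient designs fall back to the minimum-norm
  (SVD) solution with a warning.
* Lasso: glmnet coordinate descent, convergence threshold $10^{-12}$,
  warm-started path into the requested $\lambda$; $\lambda \ge
  \lambda_{max}$ returns the exact all-zero solution (KKT).
* SVR: features and target standardized internally; $\varepsilon$ is in
  raw target units; a constant target degenerates to a constant predictor.
* LOOCV folds with a constant training target fall back to the mean
  prediction, with one warning per call.
* QALY clipping of predictions to $[-0.25, 0.5]$ and cost flooring at 0
  happen at prediction time, not training time.
* All randomness is routed through per-stage sub-seeds derived from one
  master seed by hashing the stage name (31-bit arithmetic, exact in
  doubles), so inserting a stage never perturbs the others and identical
  configurations produce byte-identical report bundles.

## Problem sizes used by the test suite

Unit tests run at n = 30–400. The qualitative-reproduction check runs the
full benchmark at the trial's size (n = 350, ~46 design columns) over five
seeds; support recovery uses 100 replicates of n = 300, p = 50; the
noiseless-recovery check uses n = 240. These sizes were chosen so the
whole suite completes in a few minutes on one core while keeping every
assertion at the scale its property is stated for.

## Known limitations

* The bundled value set is synthetic. Real analyses must load a country
  tariff (`load_value_set()`); the package deliberately does not ship one.
* The generator emulates structure, not the real feature catalogue; its
  212-item questionnaire battery is represented by a few dozen generic
  features. Country-level clustering (the real trial spans nine countries)
  is not modelled.
* Point predictions only: the recommendation rule consumes no uncertainty.
  Patients near the WTP ray flip arms under small prediction changes; a
  probabilistic extension (e.g. CE-acceptability curves per patient) is a
  natural next step but out of scope.
* The WTP rule is linear. Nonlinear valuations of QALY gains (diminishing
  value at high baseline health, severity-dependent thresholds) are a
  documented extension point, not implemented.
* The counterfactual policy value inherits plug-in optimism under weak
  signal, as discussed above.
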