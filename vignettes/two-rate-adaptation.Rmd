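---
title: "Methods: state-space and rate-of-change models of trial-by-trial adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-space and rate-of-change models of trial-by-trial adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tworate)
```

This vignette documents the models the package implements, the conventions
and numerical choices behind them, and what the synthetic-data tests do and
do not establish about real data.

## The paradigm

The default schedule (`build_schedule()`) is 288 reach-training trials: 64
with cursor aligned to the hand, 160 with the cursor rotated so that full
compensation is +30°, 16 with the opposite rotation (−30°), and 48
error-clamp trials in which the cursor travels straight to the target and no
performance error exists. Four target directions (60°, 80°, 100°, 120°)
cycle within blocks of four trials. In the experiments this paradigm models,
each training trial is followed by one test trial — a no-cursor reach, an
active or passive hand-localization judgement, or a pause — so every test
channel lives on the same 1–288 trial axis as training.

All angles are in degrees throughout, in *compensation space*: a positive
deviation is one that counters the rotation, so adapted behaviour tracks the
sign of the perturbation column.

Standard analysis windows (`trial_windows()`): R1 = trials 65–68, R1_Late =
221–224, R2 = 237–240, and EC = 273–288 (the last 16 clamp trials, kept
short for a less noisy estimate even though the clamp phase has 48 trials).
Values are baseline-normalized by subtracting each participant's mean over
trials 33–64 — the second half of the aligned phase — computed separately
per channel, since test channels can carry channel-specific biases; whether
to normalize test channels by their own or the training baseline is not
settled by the paradigm itself, and per-channel is this package's default.
Cross-participant outliers beyond 3 SDs within a (channel, trial) cell are
marked missing; the population SD is used and the rule is applied once, not
iterated (re-running would recompute the SD on the censored data and could
cascade). Zero-variance cells remove nothing.

## The two-rate state-space model

Behaviour on trial $t$ is the sum of a slow and a fast latent process,

$$x_t = x_{s,t} + x_{f,t}, \qquad
  x_{s,t+1} = L_s e_t + R_s x_{s,t}, \qquad
  x_{f,t+1} = L_f e_t + R_f x_{f,t},$$

with error $e_t = p_t - x_t$ forced to zero on error-clamp trials (the
model, like the participant, experiences no error there). All four
parameters are unitless rates in $[0,1]$ *inclusive* — boundary estimates
such as $R_s = 1$ (no forgetting of the slow state) are legitimate — with
the orderings $L_s < L_f$ and $R_s > R_f$ that give the processes their
identity. The closed-loop error uses the model's own output, not the data:
this is what makes the clamp phase meaningful, since the model's error can
be clamped while the data cannot.

**State-reporting convention.** The trajectory value at trial $t$ is the
model's motor output *on* that trial: the state accumulated from errors on
trials $1..t-1$, before learning from trial $t$'s own error. With zero
initial state the output on the first rotated trial is therefore 0, and the
first nonzero output appears one trial after the first error. This is the
alignment under which the model's MSE against per-trial data is computed.

Under a constant perturbation $P$ (with $R_s, R_f < 1$) the recurrence has
the fixed point
$x^\* = P\,G/(1+G)$ with $G = L_s/(1-R_s) + L_f/(1-R_f)$
(`two_rate_steady_state()`), which the test suite uses as a closed-form
oracle for the simulator.

### Fitting

`fit_state_space()` minimizes the MSE between model output and data
(missing trials ignored):

* **Grid search.** 6 points per dimension over the box, with the endpoints
  nudged to [0.001, 0.999] so log-smooth objectives stay well behaved;
  nodes violating $L_s < L_f$ or $R_s > R_f$ are skipped. The six best
  feasible nodes seed local refinement (`grid_search_starts()` is exported
  as a generic utility).
* **Refinement.** `L-BFGS-B` within the inclusive $[0,1]$ box. The
  orderings are enforced by a quadratic penalty ($10^6 \times$ squared
  violation) that vanishes on the feasible side, so the objective stays
  smooth for the quasi-Newton updates; finite-difference steps of $10^{-7}$
  are used because the default coarse steps stall the optimizer well short
  of the least-squares solution (with them, noiseless self-generated data
  are recovered only to ~$10^{-4}$; with fine steps, to ~$10^{-10}$).
  Proposals that survive at an ordering boundary are nudged strictly
  feasible by $10^{-9}$ before the fit object is built.
* **Fit target.** By default the model's total output is fit to the data;
  `fit_target = "slow"` fits the slow process instead, supporting the
  question of whether a measured implicit time course behaves like the slow
  process.

Fitting is intended for group-mean series (the paradigm's usual practice)
but works unchanged on single participants.

### Model comparison

The one-rate comparator ($x_{t+1} = L e_t + R x_t$, $k = 2$) is fit with
the same machinery. `compare_models()` computes AIC per fit and relative
likelihoods $\exp((\mathrm{AIC}_{\min}-\mathrm{AIC})/2)$. The AIC formula
is `n·log(MSE) + 2k` by default — the Gaussian-likelihood form up to a
shared constant — but is a configurable argument, because published AIC
values for this paradigm are not reproducible from published MSEs under any
single standard formula; relative likelihoods from given AICs, which *are*
internally consistent, are the quantity the package treats as primary. A
zero MSE makes the log-based AIC undefined and is reported as `NA` with a
warning rather than $-\infty$.

## The rate-of-change (exponential decay) model

Implicit measures saturate too fast for the state-space machinery to be the
natural summary, so any per-trial process can be reduced to two numbers by

$$P_{t+1} = P_t + L\,(A - P_t),$$

the per-trial fractional closure $L \in [0,1]$ of the gap to asymptote $A
\in [0, 2\max|data|]$. (Written with a minus sign this recurrence would
move *away* from the asymptote; the package implements the convergent
form, which is the only one consistent with a saturating process and with
any reported fit.) The gap decays exactly geometrically,
$|A - P_t| = |A - p_0|(1-L)^t$, and the closed form is used everywhere.
Rates are reported as percentages ($100L$) in summaries.

**Axis convention.** `simulate_decay()` returns $P_1, P_2, \dots$ — the
states after 1, 2, … updates, starting from $p_0$ (default 0, the
normalized baseline). `fit_decay()` aligns data index $j$ with $P_j$: the
$j$-th fitted value reflects $j$ learning updates. Two consequences:

* *Prepended zero.* Test-trial responses have already changed through the
  training trial that precedes them, so for test channels a zero is
  prepended (`prepend_zero = TRUE`): it occupies index 0 of the fitted
  axis, where the model's starting state $P_0 = p_0 = 0$ sits, anchoring
  the curve at the pre-training value. Index 0 can never be returned as a
  saturation trial.
* *First-rotation window.* For fits to the reach data or the model's slow
  process, the 160-trial window holds the states *produced by* the 160
  first-rotation errors — schedule trials 66–225
  (`first_rotation_window()`, the `"post_error"` alignment) — because the
  state on rotation-onset trial 65 is still the baseline zero, i.e. the
  decay model's $p_0$, not its first fitted value. Test channels instead
  sit on the rotation trials themselves (`"on_trial"`, trials 65–224): the
  test following training trial 65 already reflects one update. Both
  windows are user-selectable; this choice is what makes the decay axis
  and the state-space axis count learning updates identically.

Fitting is multi-start bounded least squares (15 `L-BFGS-B` starts over the
box by default). An all-zero series makes the asymptote bound degenerate;
$A$ is fixed to 0 with a warning. The fit is validated in the test suite
against an exhaustive 2-D grid oracle (steps 0.001 in $L$, 0.01° in $A$).

**Bootstrap.** `bootstrap_decay()` resamples participants with replacement
(default 1000 resamples), refits each resample's mean series (seeding the
optimizer with the full-sample estimate plus a reduced start grid), and
forms percentile 2.5/97.5% CIs — the plain percentile interval is used
since nothing more specific is implied by "95% CI" in this literature. The
point estimate always comes from the full-cohort mean. Everything is
deterministic given the seed.

**Saturation trial.** The first trial $t \geq 1$ at which the modelled
curve $P_t$ (from the group-average fit) lies inside the bootstrapped CI of
the asymptote. A modelled process that never enters the CI within the
horizon returns `NA` with a warning naming the horizon.

## Proportional localization model

The visual–proprioceptive discrepancy is the perturbation on ordinary
trials and the participant's own reach deviation on clamp trials
(`build_discrepancy()`). The localization shift on the test trial after
training trial $t$ is modelled as $b \cdot d_{t-1}$ (lag 1 on the
interleaved axis; trials whose lag predates the experiment use 0). The
no-intercept least-squares slope is the closed-form projection
$b = \sum xy / \sum x^2$; an intercept variant exists but is off by
default, keeping the model one-parameter. `regress_localization()` provides
the companion window-mean regressions (slope, intercept, CI, correlation)
via `lm()`. Test-trial target locations (±5° around training targets) play
no role in any model. Whether proportional fits should use group-mean
series or pooled participants is not dictated by anything in the paradigm;
both work, and group-mean is the pipeline default.

## The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure the analyses assume:

* Per-participant parameters: group means (defaults:
  `reference_group_params()`, group-level estimates typical of this
  paradigm) jittered on a logit scale (SD 0.2) and projected back onto the
  feasible region, so the slow/fast orderings always hold. The logit scale
  keeps jitter proportionate near the boundaries, where retention rates
  live.
* Training channel: the participant's two-rate trajectory plus i.i.d.
  Gaussian motor noise, SD 4° per trial. Localization channels:
  $\beta_i d_{t-1}$ plus noise with SD 3°, with $\beta_i$ uniform on
  [0.20, 0.30] — the range in which hand-localization shifts are typically
  reported. No-cursor channels: 0.7 of the slow process plus a 0.2
  proportional component (so aftereffects are present from the first test
  trial) plus motor noise. The noise SDs are calibration choices, set so
  group-mean residuals are commensurate with the few-deg² MSEs seen in
  group fits of cohorts of 32–47; they are not measured quantities.
* Determinism: participant $i$'s draw depends only on (seed, $i$), so
  cohorts are reproducible and extendable. The generating truth (per
  participant parameters and betas) is serialized beside the data, and all
  recovery tests compare against stored truth.

What the generator does *not* emulate: trial-level error corrections,
target-direction effects, explicit strategies or their instruction effects,
attrition, drifts in baseline, or any raw kinematics. Passing recovery
tests therefore establishes that the estimators invert the package's own
generative assumptions at realistic noise — not that those assumptions hold
in any particular data set.

## Problem sizes and budgets used by the test suite

Recovery experiments use 100 cohorts of 32 participants (the size at which
a 4° motor noise SD leaves ~0.7° noise on the group mean), at which the
median absolute error of the recovered slow learning rate is well below
0.02. Steady-state oracles run 20 random parameter sets to a 4000-trial
horizon; exhaustive-grid oracles use steps 0.001/0.01° (decay) and 0.005
(one-rate). Bootstrap tests use reduced resample counts (15–400) since they
test mechanics, not CI coverage; the pipeline default remains 1000.

## Known limitations

* The state-space fit is least squares on the mean series: no trial-level
  likelihood, no estimated noise parameter, no hierarchical pooling across
  participants — so standard errors on the two-rate parameters come only
  from resampling outside the fitter.
* The decay model summarizes monotone saturating processes; applied to a
  non-monotone process (e.g. a channel spanning the rotation reversal) its
  parameters are not interpretable. The pipeline therefore fits it within
  the first rotation only, with the window exposed.
* AIC values depend on the configurable formula; only relative likelihoods
  within one comparison, computed under one formula, are meaningful.
* With 2 participants the bootstrap's resample space is tiny and percentile
  CIs are coarse; the implementation warns only through the width of the
  resulting intervals.
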