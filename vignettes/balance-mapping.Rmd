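---
title: "Mapping clinical evaluations to gait balance control: methods"
author: "gaitbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping clinical evaluations to gait balance control: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the balance-control
measures and how they are computed from trajectories, the network model and
its training algorithm, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## 1. Balance-control measures

Balance control during gait is described by the interaction of the
centre of mass (CoM) with the base of support (BoS), evaluated at heel
strikes. All geometry lives in the ground plane: the vertical CoM
coordinate is carried but ignored for distances, because the BoS is a
ground-plane construct. Internally everything is in metres; the reporting
boundary converts to cm and cm², the units in which these measures are
conventionally published.

* **BoS polygon** (`build_bos`). In single support the BoS is the
  in-contact foot's outline polygon; in double support it is the convex
  hull of both outlines' vertices, which includes the region between the
  feet. Contact comes from per-frame boolean flags (in a laboratory these
  would be derived from force plates; here they are part of the trial
  format). Whether the original laboratory convention for double support
  was exactly a convex hull is not documented for this protocol; the hull
  is declared, not inferred, and is the standard choice.
* **CoM–BoS distance** (`com_bos_distance`): minimum Euclidean distance
  from the CoM projection to the polygon boundary, computed against every
  edge segment (not just vertices). Always reported non-negative; an
  `inside` flag from an even-odd crossing test records which side the CoM
  is on, since no sign convention is established for the outside case.
* **CoMv–BoS displacement** (`comv_bos_displacement`): the first
  intersection of the ray from the CoM along the unit horizontal velocity
  with the boundary. For an interior CoM this always exists and is never
  smaller than the CoM–BoS distance (the distance along any ray dominates
  the minimum distance — a property the tests check on every random
  instance). For an exterior CoM the measure is defined only if the ray
  re-enters; speeds below `velocity_eps` (default 1e-4 m/s) are flagged
  undefined with a reason code rather than returning a junk direction.
* **BoS area** (`polygon_area`): shoelace area of the validated simple
  polygon.

`evaluate_trial` applies a fourth-order low-pass Butterworth filter with
an 8 Hz cutoff to the CoM trajectory first — the standard treatment of
marker trajectories — implemented zero-phase (forward–backward), so the
effective magnitude response is squared and no lag is introduced at the
events. Edge transients are controlled by odd-reflection padding (up to
100 samples per end); a single-pass causal mode is available by flag.
Velocity, when not supplied, is obtained by central differences of the
*filtered* positions, one-sided at the ends. The per-trial summary is the
arithmetic mean over heel-strike events with defined values, with the
count of undefined dynamic-measure events reported alongside.

## 2. The network and its training

`lmnet()` fits the three-layer feed-forward regression network

$$\hat y = W_2 \tanh(W_1 x + b_1) + b_2$$

with a hyperbolic-tangent (tansig) hidden layer and pure linear output
layer. Inputs and targets are affinely mapped column-wise onto $[-1, 1]$
by their training min/max (`minmax_fit`); the error goals 0.1 / 0.01 /
0.001 are defined as the mean over samples and output dimensions of the
squared error on that normalized scale — the only scale on which those
three numbers are mutually meaningful. Constant columns are a hard error
naming the column. Predictions are always denormalized back to real
units.

Training is Levenberg–Marquardt: each epoch computes the analytic
residual Jacobian by backpropagation (one row per sample × output, one
column per parameter) and solves

$$(J^\top J + \mu I)\,\delta = -J^\top e .$$

A step is accepted only if it lowers the MSE, whereupon $\mu$ is divided
by 10; otherwise $\mu$ is multiplied by 10 and the step retried. Training
stops at the goal, at the epoch cap (default 500), or when $\mu$ exceeds
$10^{10}$. Defaults $\mu_0 = 10^{-3}$, factor 10 both ways, are standard
LM practice. The accepted-step MSE trace is therefore monotone
non-increasing by construction, and the tests assert it. There is no
validation split or early stopping inside training: the procedure stops
on goal or cap only, which is the protocol this experiment grid assumes.

Weights are initialized Nguyen–Widrow style (random hidden directions
scaled to magnitude $0.7\,h^{1/p}$ with evenly spread biases — the
customary default for tansig layers operating on $[-1,1]$ inputs), with a
plain uniform fallback behind `init = "uniform"`. Initialization is the
only stochastic ingredient; it is driven by a per-call seed through a
private RNG stream that never touches the global RNG state, so a fit is
bit-reproducible from `(data, config, seed)`.

Numerical guards: the tanh pre-activation is clamped to ±40 (tanh is ±1
to machine precision far earlier; the clamp only prevents overflow in
intermediate expressions), and a singular damped system is treated as a
rejected step (raising $\mu$) rather than an abort.

`input_importance` scores each input by the sum over hidden units of the
absolute hidden-layer weight — the customary first look at what a trained
network leans on. Ties keep input order. Because an interpolating,
overparameterized network leaves irrelevant weights near their
initialization scale, support recovery by this score is only reliable for
students of roughly matched capacity, ideally taking the best of a few
restarts; the tests exercise exactly that setting.

## 3. The synthetic cohort generator

The generator exists so the full analysis can run end to end without the
(unavailable) original cohort. It emulates a 56-subject elderly cohort at
two levels.

**Tabular level** (`generate_cohort`). Each of the 16 clinical features
and 3 balance outcomes has a marginal family calibrated to the published
cohort mean (SD):

* Normal for age, BMI, TUG and the three outcomes;
* Gamma for positive skewed measures (TMT B−A, the three normalized
  torques, visual acuity), matched by moments;
* scaled Beta for bounded ABC (percent);
* *discretized* Beta for integer-valued bounded instruments (BBS /56,
  GDS /15, SLUMS /30): naive rounding of a moment-matched Beta biases the
  mean of a boundary-piled score like the GDS by about −2%, so the raw
  Beta parameters are solved (deterministically, at configuration time)
  such that the **rounded** variable hits the target mean and SD;
* negative binomial for counts (falls/year, medications), which matches
  both moments since the published variances exceed the means;
* Bernoulli for sex (22/56 male) and hearing impairment (14/56).

Dependence comes from a 3-latent-factor Gaussian copula: latent balance
ability, strength and cognition load onto every variable's Gaussian score
with clinically signed defaults (better balance ⇒ higher BBS/ABC, lower
TUG and fall count; larger Snellen denominator ⇒ worse vision ⇒ worse
balance), score noise making every score unit-variance, and each score
mapped through its marginal's quantile function — so the marginals are
exact by construction while the outcomes remain learnable from the
features. The outcomes' latent score is passed through a tanh link
(standardized to unit variance by quadrature) so the clinical-to-balance
map is nonlinear, which is the regime a tansig network is for. Squared
row norms of the loading matrix are the explained-variance budget; the
defaults put roughly 55–65% of outcome score variance on the shared
latents. These loadings are a modelling stand-in, not an estimate of any
real population — the source study published only marginals — and every
analysis-level number obtained on synthetic cohorts must be read as a
property of this simulation.

Degenerate configurations are honored: zero loadings and zero noise give
a cohort constant at the configured means; loadings with row norm > 1
(an impossible dependence structure) are a configuration error.

**Trajectory level** (`generate_trial`). Given a requested outcome, the
generator solves for a double-support geometry that reproduces it: step
length, step width and the CoM offset inside the support hull are
optimized (Nelder–Mead on relative misfit, multiple starts, acceptance at
1% combined misfit) against the *same* geometric definitions used for
evaluation. The periodic CoM path is then threaded through that
configuration at every heel strike: forward velocity constant, lateral
sway cosine-phased so it is extremal — hence laterally stationary — at
heel strikes, feet alternating with the solved step geometry. Footprints
are rectangles with a rounded toe, scaled from body height by the
standard anthropometric ratio (foot length = 0.152 × height, width 0.40 ×
length); the full anthropometric BoS model of the laboratory protocol is
deliberately not reproduced. Because a double-support hull can never be
smaller than one footprint, small-area outcomes (lower tail of the
cohort) rescale the footprint template down — physically, small-BoS
subjects have small feet.

White noise of 0.3 mm (typical optical marker noise) is added to the CoM
path, and 2 mm jitter to each foot placement. The dynamic measure is by
far the most noise-sensitive quantity: the velocity direction obtained by
central differences meets the curved toe arc at shallow angles, so
millimetre-scale marker noise is already visible in per-event
displacements. With these defaults the round trip
`generate_trial → evaluate_trial` recovers requested outcomes with median
relative error of a few percent (the module's contract is 10%), and
noise-free trials recover them to better than 2%.

What the generator does **not** emulate: real marker sets and segmental
CoM estimation, force-plate signals, gait-event detection (events are
exact by construction), pathological gait (no asymmetry, no stumbles),
and real inter-feature correlation structure beyond the three-factor
model. Passing tests on these cohorts therefore demonstrates the
*pipeline's* correctness and the qualitative behaviour of the method, not
clinical performance on real elderly adults.

## 4. The experiment pipeline

`make_folds` partitions the subject ids into 4 disjoint test sets of
equal size (56 → 4 × 14, training on the complementary 42), so the
rotation tests every subject exactly once; whether the original protocol
used a partition or 4 independent draws is ambiguous, so a partition is
the default and `mode = "independent"` is available. `run_config` fits
the network per fold; normalization is part of the fit and therefore
fitted on training rows only — an audit attribute on the result verifies
the normalizer ranges are reproducible from the training rows alone.
Correlation (Pearson, with constant vectors flagged as missing rather
than silent NaN) and mean absolute error are computed on denormalized
test predictions in real units. Fold failures are recorded and never
abort a grid. `run_grid` enumerates the full factorial (default 6 × 4 ×
3 = 72 configurations), expanding one master seed deterministically into
per-configuration and fold seeds. `summarize_grid` reports the best
configuration per grouping by argmax of the mean fold correlation across
the three outputs (how the original "selected combinations" table was
assembled is not fully specified; argmax is declared), the epochs-to-goal
table by hidden size, and an input-importance ranking for the best
all-inputs configuration averaged over refits.

The routine three-way ANOVA of the original analysis is out of scope and
replaced by these descriptive tables.

## 5. Problem sizes and tolerances used in the checks

The test suite verifies geometry against brute-force oracles (dense
boundary sampling at 10⁵ points, ray marching at 10⁻⁵ m steps, O(n³)
hulls, fan triangulation) on ≥10³ random instances at 10⁻³ cm / 10⁻⁶
relative-area agreement; LM training against a normal-equations
least-squares oracle on linear data (10⁻⁶), finite-difference Jacobians
(10⁻⁴), multi-seed XOR and teacher–student recovery; generator
calibration at n = 10⁵ within 1% (means) and 2% (SDs) of the configured
values, with a 4-standard-error floor so binomial sampling noise on the
binary traits cannot masquerade as miscalibration; and the two
qualitative grid patterns (all-domain grouping best; small hidden layers
slowest and most often capped at tight goals) on a full 72-configuration
run with a 56-subject cohort. That full grid takes well under a minute on
one CPU, the whole suite a few minutes. `scripts/acceptance.R` re-runs
the pipeline from scratch under a single command-line seed.

## 6. Known limitations

* The published headline correlations were obtained on 56 real subjects;
  with 14-subject test folds and an overparameterized network, fold
  correlations on synthetic cohorts are lower and noisy. Only qualitative
  orderings are stable at this size, and only those are asserted.
* The |W1| importance score is initialization-contaminated for
  interpolating networks (Section 2); rankings from a single 403-parameter
  fit on 42 subjects are descriptive, not inferential.
* The BoS model is a footprint-polygon convention, not the full
  anthropometric model of the laboratory protocol; absolute areas are
  comparable only within this convention.
* `signal::filtfilt` applies no edge treatment, so the package wraps the
  two filter passes with odd-reflection padding itself; very short series
  (under ~3 filter lengths) are rejected rather than filtered badly.
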