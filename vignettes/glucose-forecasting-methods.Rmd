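---
title: "Methods: dilated recurrent networks for 30-minute glucose forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dilated recurrent networks for 30-minute glucose forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The forecasting problem

People with type-1 diabetes carry continuous glucose monitors (CGMs) that
report interstitial glucose every 5 minutes. A forecast of the glucose
concentration 30 minutes ahead (6 sampling slots) gives a patient — or a
closed-loop insulin-delivery controller — enough time to prevent an
impending hypo- or hyperglycaemic excursion. The predictors available at
time $t$ are the recent glucose trace $G$, the insulin boluses $I$ (units),
the meal carbohydrate entries $M$ (grams), and the time of day $T$.

`glucodrnn` implements this forecasting pipeline end to end: a synthetic
cohort generator, CGM preprocessing, sliding-window construction, a dilated
vanilla-RNN forecaster with two-phase transfer learning, three classical
baselines, and the evaluation statistics (RMSE, MARD, cross-correlation
time lag, paired $t$-tests).

# The dilated recurrent forecaster

Each layer is a single-gate tanh ("vanilla") recurrent cell,

$$h_t = \tanh(W_{rec}\, h_{t-1} + W_{in}\, x_t + b),$$

with parameter count $n^2 + mn + n$ per state for hidden size $n$ and input
size $m$ — a quarter of an LSTM's and a third of a GRU's
(`drnn_param_count()` evaluates all three). In a *dilated* stack, layer $l$
keeps the same cell but its recurrent edge skips backwards $d_l$ steps:

$$h^l_t = \tanh(W_{rec}\, h^l_{t-d_l} + W_{in}\, h^{l-1}_t + b^l),$$

so with dilations $(1, 2, 4)$ the top layer's receptive field covers the
whole 12-step (one-hour) window at an average recurrence path length far
shorter than a plain RNN's. Dilation affects only the recurrent edge; the
feed-forward edge always consumes the layer below at the same timestep.
Setting all dilations to 1 recovers an ordinary stacked RNN — this identity
is enforced by an oracle-equivalence test against an independently written
stacked-RNN loop.

The network is many-to-one: only the top layer's final state $h^L_T$ feeds
an affine head with no activation,

$$\hat{y}_T = (W_{FC}\, h^L_T + b_{FC}) + x_T,$$

so the head estimates the glucose *change* over the horizon ($\Delta$BG)
and the forecast adds it to the current (unnormalized) reading. Regressing
the change rather than the level removes the dominant persistence component
from the target and is what lets a zero-initialized head start exactly at
the persistence forecast.

Design points the architecture leaves open, and the choices made here:

* **Pre-window states.** All states with $t - d_l < 1$ are zero vectors;
  outputs are invariant to anything "before" the window by construction.
* **Initialization.** Uniform on $\pm 1/\sqrt{\text{fan-in}}$ for both
  input and recurrent matrices (treated uniformly across layers), zero
  biases, seeded. This keeps tanh pre-activations in the linear regime at
  the start of training.
* **Channel scaling.** Raw mg/dL magnitudes saturate tanh units, so the
  glucose, insulin and meal channels are standardized with means/SDs
  fitted on training windows only; the time-of-day index is already in
  $[0,1)$ and passes through; labels stay in mg/dL.

# Training

Mini-batch RMSprop (learning rate $10^{-3}$, decay 0.9, batch 512,
$\epsilon = 10^{-8}$, no momentum) minimizes the mean squared
$\Delta$BG error. Gradients come from backpropagation through time written
out analytically for the dilated topology; they are verified against
central finite differences to $10^{-4}$ relative error in the test suite.
Choices not fixed by the architecture:

* **Gradient clipping** at global norm 5 — dilation alleviates but does not
  eliminate the exploding-gradient failure mode of tanh recurrences.
* **Early stopping** on validation RMSE with patience 10 under a default
  budget of 200 epochs; the returned model is the best-validation one, never
  a later epoch. Validation is the chronologically last 10% of the training
  windows (time-series data; no k-fold shuffling), giving the 81/9/10
  train/validation/test split when the outer test partition is 10%.
* **Shuffling.** Windows are reshuffled each epoch with a seed derived from
  `(seed, epoch)`, so runs are bit-reproducible; shuffling can be disabled.

## Two-phase transfer learning

CGM records are short, so a per-subject model benefits from other
subjects' data. Phase 1 trains on a corpus of twice the target's length:
the whole target record plus five donor blocks of 10% of the corpus each
(20% of the target length per donor). Each donor contributes its *final*
contiguous block — a fixed, deterministic rule chosen over random sampling
so reruns are identical; windows never cross the subject boundaries.
Phase 2 fine-tunes **all** weights on the target alone (no layer freezing,
the simplest defensible default) for up to 50 epochs with the same
optimizer and early stopping. `phase2_epochs = 0` returns the phase-1
model unchanged.

The "10% each" share is measured against the combined corpus, not the
donor's own length: that is the only reading under which the corpus is
exactly double the target.

# Synthetic cohort generator

Real CGM datasets sit behind licenses and data-use agreements, so the
package ships a generator whose output has the statistical structure the
pipeline assumes. It is first-class, tested code — the entire test suite
and the acceptance experiments run on it.

**Event statistics** (per day, defaults): 3 meals anchored at 8:00, 13:00
and 19:00 with timing SD 20 min and size 60 g at CV 10%; 1–5 boluses at a
mean dose of 6 U (CV 20%), anchored to a uniformly chosen meal time with
30-min jitter — boluses are deliberately *not* forced to coincide with
meals. The 60 g / 6 U defaults follow the common clinical
10 g-per-unit carbohydrate ratio for an adult; timing anchors are ordinary
adult meal hours.

**Dynamics.** A Bergman-style minimal model with a two-compartment gut
chain for meals and a two-compartment subcutaneous chain for boluses:

$$\frac{dG}{dt} = -p_1 (G - G_b) - X G + \frac{f\, k_{gut} Q_2}{V_g},
\qquad \frac{dX}{dt} = -p_2 X + p_3 I_p,$$

with $Q_1 \to Q_2$ (rate $k_{gut}$) receiving meal carbohydrate and
$S_1 \to S_2$ (time constant $t_{max,I}$) receiving boluses,
$I_p = S_2 / (t_{max,I} V_i)$. Defaults
($p_1 = p_2 = 0.02\,\mathrm{min}^{-1}$, $p_3 = 4\times 10^{-5}$,
$G_b = 110$ mg/dL, $k_{gut} = 1/40\,\mathrm{min}^{-1}$, $V_g = 160$ dL,
$t_{max,I} = 55$ min, $V_i = 8.4$ L, $f = 0.8$) were chosen once for
qualitative realism: an untreated 60 g meal peaks about +94 mg/dL, a lone
6 U bolus dips about −27 mg/dL, and the largest 5-minute step on a
defect-free trace is under 10 mg/dL. Integration is fixed-step RK4 at a
1-minute internal step subsampled to the 5-minute grid — stable for these
stiffness-free kinetics without pulling in an adaptive-solver dependency.
Cohorts add log-normal jitter (CV 10%) to $p_1, p_3, G_b, k_{gut}$ per
subject so subjects differ but share the model family.

**Sensor noise** is additive AR(1) with lag-1 correlation 0.7 and marginal
SD 3 mg/dL — CGM noise is autocorrelated, and 3 mg/dL is a mid-range
single-sensor noise floor. Clinical-style defects are separate, explicit
operators: dropped intervals (`inject_missingness()`), additive spikes
(`inject_outliers()`), and the frozen-sensor artefact
(`inject_frozen_sensor()`, default 2 h).

**What the generator does *not* emulate** — and therefore what passing
tests cannot certify about real data: exercise, stress and illness effects;
sensor drift and compression artefacts; inaccurate self-reported meal
sizes; circadian insulin-sensitivity rhythms; and the heavy-tailed timing
irregularities of real life. Results on this cohort demonstrate that the
pipeline is implemented correctly and that the method ordering holds under
the generator's assumptions, not that clinical accuracy figures transfer.

# Preprocessing

Real exports have gaps (transmission loss), literal-zero readings (mapped
to invalid on input), spikes and frozen stretches. The pipeline treats
training and testing asymmetrically, because only training may look ahead:

* **Training:** maximal invalid runs are detected by run-length encoding;
  interior gaps of at most 24 slots (2 h) are filled by first-order
  interpolation between the bounding samples; a centred running median
  (window 5 slots = 25 min) then removes 1–2-slot spikes. The 2-h cap
  quantifies "short": linear fill across multi-hour gaps would fabricate
  physiology, so longer gaps split the record into independent segments.
  The 5-slot window removes isolated spikes without flattening meal peaks.
  The median filter never bridges a gap; window shrinkage at segment edges
  keeps windows symmetric, so edge samples pass through.
* **Testing:** future samples are unknown, so missing values are estimated
  causally by the least-squares line through the last $k = 6$ valid samples
  (30 min of trend; $k = 2$ degenerates to slope continuation, fewer than 2
  valid samples fall back to hold-last-value with a flag). The 6-sample
  window trades noise robustness against responsiveness to trend changes.

A gap quoted as lying "between 17:10 and 18:00" covers the slots strictly
after 17:10 through 18:00 — ten slots — and the injectors and detectors
share that convention.

# Windows, labels and splits

Windows slide with stride 1: 12 steps of history, label
$G(t+6) - G(t)$, one window per anchor slot whose full extent and target
lie inside a contiguous valid segment — a segment of length $len$ yields
$\max(0, len - 17)$ windows, and no window ever spans a filled-over long
gap or a subject boundary. Bolus and meal channels hold the event quantity
at the administration slot and zero elsewhere (no smearing): the cell can
learn absorption dynamics itself.

# Baselines

All baselines consume the identical window sets and the identical
test-time extrapolation, isolating the predictor:

* **ARX(3):** least squares of $\Delta$BG on the last 3 lags of all four
  channels plus intercept — the named third-order autoregressive-exogenous
  model class realized without a proprietary system-identification toolbox.
  Rank-deficient designs (e.g. constant channels) fall back to the
  minimum-norm SVD solution and are flagged.
* **NNPG:** three fully connected layers (64 and 32 tanh units, linear
  output; widths chosen for capacity comparable to the DRNN), trained on
  $\Delta$BG with the same RMSprop machinery at learning rate 0.001 and
  batch 32. It predicts $\Delta$BG rather than the absolute level for
  comparability with the other methods — a documented deviation risk, since
  conventional formulations of this baseline sometimes regress the level.
* **SVR:** RBF-kernel $\epsilon$-insensitive regression ($C = 100$,
  $\gamma = 0.01$) via the established libsvm solver; targets standardized
  by the training SD with $\epsilon = 0.1$ on that scale. The quadratic
  solver cost is bounded by training on the most recent windows (cap
  configurable via `max_train`).

# Evaluation

For forecasts $\hat{y}_{t|t-PH}$ paired with observations $y_t$:

$$\mathrm{RMSE} = \sqrt{\tfrac1N \sum_t (\hat{y}_{t|t-PH} - y_t)^2}, \qquad
\mathrm{MARD} = \tfrac{100}{N} \sum_t \left|\frac{\hat{y}_{t|t-PH} - y_t}{y_t}\right|,$$

and the time lag is the delay maximizing the cross-correlation between the
forecast and observed series. Two numerical choices there: Pearson
correlation of the overlapping segments is used rather than the raw
(unnormalized) cross-product, so the arg-max is scale-free and amplitude
cannot masquerade as delay; and the integer arg-max over shifts
$\delta \in [0, PH]$ (a forecast cannot lead its target) is refined by
parabolic interpolation through the peak and its two neighbours, giving
the sub-slot (fractional-minute) resolution that per-subject lag tables
require. The interpolation is validated against a 100×-oversampled
dense-grid oracle. MARD errors outright on non-positive actuals rather
than skipping them; a constant series has no defined lag and says so.

Method comparisons use two-sided paired $t$-tests on per-subject metric
vectors; zero-variance differences are reported as a degenerate case with
$p = 1$ rather than raised mid-pipeline.

# Problem sizes used by the shipped experiments

The packaged experiments (test suite and `scripts/acceptance.R`) run a
scaled-down study: a 5-subject cohort of 35 days each (30 train / 5 test),
DRNN budget 100 epochs with patience 10, the method ranking reported as a
median over 3 training seeds, and the transfer-learning comparison on a
6-day target with five 6-day donors sharing physiology, 50 total epochs,
median over 5 seeds. These sizes were chosen so a complete replication
runs on a single CPU core in minutes while leaving the qualitative
ordering of methods stable across seeds; the full-scale study conditions
(10 subjects, 360 days, 103,680 instances per subject) remain available
through `sim_scenario(n_days = 360)` and the same entry points.

# Known limitations

* The generator's minimal model is far simpler than licensed research
  simulators; absolute error levels on it are not comparable to published
  clinical figures (see the generator section for what is not emulated).
* Vanilla cells only; LSTM/GRU enter through the parameter-count formulas
  and are an extension point, not a trained option.
* Single forecast horizon per window set; no multi-horizon labels.
* Correctness is preferred over throughput: the recurrent chains are
  evaluated sequentially (no within-layer parallelism), which is fine at
  the shipped problem sizes.
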