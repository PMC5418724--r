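---
title: "Wrist-position-independent myoelectric control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrist-position-independent myoelectric control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myowrist)
```

## The problem

Pattern-recognition control of a partial-hand prosthesis classifies hand
grasps from surface EMG recorded over the extrinsic (forearm) and intrinsic
(hand) muscles. Users of such prostheses retain wrist motion, and moving
the wrist changes muscle geometry and electrode-muscle alignment, which
changes the statistics of the EMG. A classifier trained with the wrist in
one posture therefore degrades as the wrist moves — the *wrist position
effect*. `myowrist` implements an offline study of this effect and of a
training scheme that removes the need to record training data in many
postures: model how each EMG feature's mean and variance change with wrist
angle, then *synthesize* multi-posture training data from recordings made
only at neutral.

## The synthetic session generator

There is no public dataset with simultaneous multi-channel hand/forearm EMG
and three-DOF wrist angles under this protocol, so the package ships a
seeded generator (`generate_session()`) that emulates the study design: 9
extrinsic + 4 intrinsic channels at 1000 Hz, four motion classes (rest,
hand open, chuck grip, key grip), 3-second holds repeated 6 times in each
of 13 wrist positions (neutral, plus mid- and end-range for flexion,
extension, adduction, abduction, pronation, supination).

The EMG model is the standard surface-EMG interference model:
amplitude-modulated, band-limited (30–350 Hz) Gaussian noise. The
per-channel signal scale for class $c$, channel $i$ at wrist angle
$\theta \in \mathbb{R}^3$ (degrees) is

$$\sigma_{ci}(\theta) \;=\; g_{ci}\,\bigl(1 + s_{ci}^\top \theta + q_{ci}^\top \theta^2\bigr) + \epsilon_0,$$

with base gain $g_{ci}$, slope $s_{ci}$ (per degree), non-negative
curvature $q_{ci}$ (per degree², acting on the elementwise square), and a
position-independent noise floor $\epsilon_0$. The quadratic form is
deliberately smooth but *not* linear, so the 3-3-1 regression networks
below have something genuinely non-linear to learn while a linear baseline
would fall short. `true_ratio()` exposes the implied analytic
feature-scale ratio of any position relative to neutral — the ground truth
for parameter-recovery tests.

Default parameter choices, made once and used for every study-scale test:

* **End ranges** 60° flexion/extension, 20° ab-/adduction, 80°
  pro-/supination — typical wrist ranges of motion (the protocol's actual
  subject ranges are not published); mid-range is half of end-range.
* **Angle-modulation strength** (`sensitivity_scale = 0.8`,
  `curvature_scale = 0.6`): per-channel amplitude can change severalfold
  between opposite end ranges, consistent with reported joint-angle effects
  on surface EMG amplitude, and sized so that a classifier trained only at
  neutral loses substantial accuracy at the end ranges (neutral-only
  training error around 20 % on combined channels, matching the magnitudes
  the study reports for real data).
* **Intrinsic channels** get half the extrinsic angle sensitivity,
  mirroring the finding that intrinsic-muscle signals are less
  position-affected.
* **Class profiles** (`class_contrast = 0.12`): the three active classes
  differ by smooth spatial activation patterns around the channel ring;
  the contrast is sized so real-data classification error is several
  percent, not zero — grasp classes overlap in practice.
* **Repetition jitter** (`rep_gain_sd = 0.08`): lognormal gain noise per
  repetition (a shared "effort" term plus per-channel terms). Without it
  every class is a point mass and classification is degenerate; 8 % is a
  conservative figure for within-session contraction variability.
* **Angle traces**: the goniometer channels hold the target posture with
  slow, clipped jitter, honouring the protocol's ±5° tolerance.

What the generator does **not** emulate: motor-unit structure and
firing-rate spectra, electrode shift, fatigue, force variation beyond the
gain jitter, day-to-day nonstationarity, and — importantly — any
position dependence of the EMG *spectrum*. Because only the amplitude is
modulated, spectral features (zero crossings, slope-sign changes, AR
coefficients) are position-invariant by construction here, whereas in real
EMG they change too. Tests passing on this generator therefore validate
the pipeline's mechanics and the amplitude pathway of the ratio model, not
the full physiological generality of the method.

## Conditioning and windowing

EMG is band-pass filtered 30–350 Hz with an 8th-order Chebyshev type-I
design and the wrist-angle channels low-pass filtered at 10 Hz with a
3rd-order Butterworth (`filter_spec()`). Unstated details resolved as
design choices: 0.5 dB passband ripple (a common hardware-emulation
figure); single-pass causal filtering by default, matching the real-time
use such a controller targets, with a zero-phase option for offline parity
work. The goniometer low-pass is applied to the deviation from the trace's
initial value so a held 60° posture does not produce a spurious
step-response transient. Signals are segmented into 200 ms windows with a
20 ms frame increment; windows never span two repetitions (cross-trial
windows would mix classes).

## Features

Per window and channel, the TDAR set: mean absolute value (MAV), zero
crossings (ZC), slope-sign changes (SSC), waveform length (WL), and the
six coefficients of a 6th-order autoregressive model — 10 values per
channel. The optional POS set appends the three mean wrist angles in
degrees. AR coefficients use Burg's lattice recursion (stable at order 6
on 200-sample windows) in the prediction convention
$x_t = \sum_k a_k x_{t-k} + e_t$; the implementation is a column-vectorized
Burg recursion that processes all windows of a trial at once and agrees
with `stats::ar.burg()` to machine precision (a zero-variance window
yields all-zero coefficients). The ZC/SSC deadzone defaults to 0; the
synthetic signals are noise-free enough not to need one. MAV and WL scale
linearly with signal amplitude while ZC, SSC and the AR coefficients are
amplitude-invariant — the property the ratio model's scaling rests on.

## Classifiers

Four classifiers (`classifier_spec()`): LDA and QDA as closed-form
Gaussian discriminants (pooled vs per-class covariance), and
one-hidden-layer perceptrons with identity (LNN, 4 hidden units) or tanh
(MLPANN, 7 hidden units) activations. Decisions the source material leaves
open, resolved as the era's standard pattern-net design: softmax outputs
with cross-entropy loss and one-hot targets, argmax decision; training by
scaled conjugate gradients (a Hessian-free batch second-order method),
early-stopped when the validation loss has increased 6 consecutive times,
restoring the best-validation weights; 3 seeded restarts keeping the best
validation loss; inputs z-scored with training-set statistics (required
once mV-scale EMG features mix with degree-scale POS features);
discriminant covariances ridge-regularized by
$\varepsilon\,\mathrm{tr}(\Sigma)/d$ on the diagonal with
$\varepsilon = 10^{-6}$ to survive near-singular fixtures. With identity
activations the LNN is mathematically a reduced linear softmax model, and
the tests verify its predictions agree with an independently fitted
multinomial logistic regression.

Rows are split 50 % train / 20 % validation / 30 % test, stratified per
(class, position) cell. "Two-fold" is read as the literal exchange of the
train and test partitions: fold 2 trains on the fold-1 test rows, keeps
the same validation rows, and tests on the fold-1 training rows, so every
row is tested exactly once. Reported errors are computed per wrist
position and averaged with equal weight over the 13 positions.

## The ratio model

For every (class, channel, feature) and each moment (mean, variance), a
small regression network maps the wrist angle triple to the feature's
moment *relative to neutral*: 3 inputs, 3 tanh hidden units, 1 linear
output, trained by the same SCG machinery. Construction of targets
(`compute_targets()`):

* Windows of each (class, position) cell are split 50/20/30. The 50 %
  statistics set provides the training targets — per-cell mean and
  variance divided by the corresponding *neutral* value from the same set
  (so the neutral training target is exactly 1). The 20 % and 30 % sets
  give independent estimates at the same 13 angle inputs, used for early
  stopping and for the reported test $r^2 = 1 - SS_{res}/SS_{tot}$.
* Angle inputs are scaled by the grid's end ranges to $[-1, 1]$ — tanh
  units saturate on raw degrees.
* A feature whose neutral mean magnitude falls below $10^{-3}$ of its
  cross-position spread switches from ratio to difference-from-neutral
  (ratios against a near-zero denominator are meaningless for signed
  features such as AR coefficients); neutral variances are floored at
  $10^{-12}$.
* Networks whose training targets are near-constant (spread below 1 % of
  the target scale) are flagged *uninformative*: they return the constant
  and report `NA` for $r^2$. Under this generator that covers the
  amplitude-invariant features, whose ratio targets are sampling noise
  around 1; fitting them would only launder noise into the bank.

All networks in a bank share the same 13 angle inputs, so the whole bank —
a thousand networks for the combined channel set — trains in lockstep as
one column-vectorized SCG problem with 16 parameters per column, in
seconds. Each network also gets 3 seeded restarts with per-network
best-validation selection.

`bank_recovery_summary()` compares the bank against the generator's
analytic `true_ratio()`: networks whose ground-truth ratio actually varies
(the amplitude-scaling features MAV and WL) are averaged, reporting both
their held-out test $r^2$ (the study's measure) and the $r^2$ of their
grid predictions against the exact ratios. On a default session the mean
networks reach test $r^2 \approx 0.99$ and truth $r^2 \approx 0.9$; the
variance networks are consistently lower — variance estimates from six
repetitions are far noisier than mean estimates, the same asymmetry the
study observed on real data. Note one subtlety: because all three window
splits draw from the *same six repetitions*, shared trial-level noise can
make even a position-invariant feature's targets reproducible across
splits; the uninformative flag and the ground-truth selection in
`bank_recovery_summary()` keep such networks out of the headline numbers.

## Simulated multi-position training data

`simulate_adjusted()` draws every feature column independently from a
normal distribution with mean = neutral mean × predicted mean ratio and
variance = neutral variance × predicted variance ratio, per (class,
position) cell — a two-moment description implies the Gaussian choice.
Count-valued features (ZC, SSC) are sampled continuously: the discriminant
is moment-driven and rounding would distort low-variance cells. Predicted
variances are floored at $10^{-12}$. `simulate_unadjusted()` is the
baseline that uses the neutral distribution for every position. Feature
independence is an explicit modeling assumption (no cross-feature
covariance is preserved); multivariate simulation is out of scope.

The three-dataset comparison (`three_dataset_comparison()`) trains LDA
classifiers on (1) real multi-position data, (2) adjusted simulated data,
(3) neutral-only simulated data, and tests all three on the same held-out
real rows from all 13 positions. On default sessions the ordering is
error(real) ≲ error(adjusted) < error(unadjusted), with the adjusted
training recovering roughly half to three-quarters of the
neutral-training error on the combined channel set. The residual gap
between real- and adjusted-trained error is the price of the feature
independence assumption.

## Experiment drivers

`run_grid()` evaluates classifier × feature set (TDAR vs TDAR+POS) ×
muscle set (extrinsic / intrinsic / combined) with two-fold
cross-validated, position-averaged error — 24 cells — plus the relative
error change from adding POS. `subset_search()` exhaustively evaluates all
$\binom{13}{n}$ training-position subsets per $n$, breaking ties by the
lexicographically smallest position tuple (the enumeration order of
`combn()`), since only one best combination is reported per $n$.
`compare_paradigms()` contrasts one classifier trained on all positions
against 13 position-specific classifiers. Repeated-measures ANOVA and
post-hoc testing are deliberately out of scope — the error tables are
emitted in long format for external statistics packages.

## Numerical choices and degenerate inputs

* Chebyshev design realized as `cheby1(order/2)` — a band-pass doubles the
  prototype order, so the realized filter is 8th order overall.
* Burg recursion on mean-removed windows; reflection coefficient set to 0
  when the error energy vanishes (constant windows).
* SCG per-column state with gradient-norm stopping at $10^{-8}$ and scale
  parameter clamped to $[10^{-15}, 10^{100}]$.
* `relative_improvement(0, x)` returns `NA` rather than raising — a zero
  baseline error makes the percentage undefined.
* Stratified splits fail loudly when a (class, position) cell is too small
  to yield non-empty train/validation/test parts.

## Problem sizes used by the test suite

Structural tests run on reduced sessions (0.6–1.5 s holds, 2–3
repetitions). The study-scale checks — ratio-model recovery, the
three-dataset comparison and the design-count identities — use full
default sessions (312 trials, 141 windows each, 43,992 feature rows), with
three independent sessions (synthetic subjects) for the real-vs-adjusted
comparison; the classifier grid identity thins windows tenfold and caps
network iterations, exercising the bookkeeping rather than asymptotic
network accuracy.

## Known limitations

* Amplitude-only position modulation: the spectral features' position
  dependence seen in real EMG is absent, so the bank's benefit here flows
  entirely through MAV/WL. Real-data deployments should expect informative
  spectral-ratio networks too.
* One synthetic subject per seed; between-subject heterogeneity is
  emulated only by re-seeding.
* Feature independence in the simulator (inherited assumption); classifier
  covariance structure in simulated training data is diagonal.
* Offline analysis only; no real-time buffering, majority voting, or
  proportional control.
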