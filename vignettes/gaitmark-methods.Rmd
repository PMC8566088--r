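---
title: "Template matching and automatic marking for IMU gait recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template matching and automatic marking for IMU gait recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmark)
```

## The problem

A wearable recognizer for leg movement patterns degrades from one day to
the next: sensor placement, tissue coupling and environment shift the
signal distribution, and collecting fresh manual labels every day is not
practical. gaitmark implements an *automatic marking* loop around a
window-level classifier: per-pattern gait-cycle templates, built once
from labeled data, label newly completed cycles by dynamic time warping
(DTW), and the trustworthy pseudo-labels retrain the classifier for the
new day's conditions.

The sensor model is ten IMU channels (triaxial acceleration, pitch and
roll for each of two units) plus one footplate pressure channel. The
pressure channel drives gait segmentation; the ten IMU channels carry the
discriminative information. Five movement patterns per subject are
assumed throughout (configurable).

## Pipeline and assumptions

### Gait events and cycles

Foot contact (FC) and foot off (FO) are detected from the pressure trace
by a hysteresis state machine: FC where pressure rises through an *on*
threshold (default 20% of the recording's maximum) while unloaded, FO
where it falls through an *off* threshold (default 10%) while loaded. Two
guards reject noise without biasing timing on clean signals:

* a **forward confirmation window** (default 5 frames). An FC candidate
  must keep the window *minimum* above the on-threshold — during stance
  the plateau is uniformly high, so a lone noise spike in swing cannot
  fire an FC, while a true FC confirms at its exact sample. An FO
  candidate (sample below the on-threshold) must have the window *mean*
  below the off-threshold — swing pressure is only near zero on average
  under noise, so requiring the minimum there would slip the event late,
  and requiring the mean keeps the detected index at the true sample.
  The asymmetry mirrors the asymmetry of the signal itself.
* a **debounce** dead time (default 100 ms) after each accepted event.

A gait cycle is one FC-to-FC stride; the interior FO splits stance from
swing. FC pairs without exactly one interior FO (e.g. a pressure dropout)
are dropped with a warning. These rules assume a pressure signal whose
loaded plateau sits clearly above both thresholds; heavily saturating or
baseline-wandering force sensors would need recalibrated fractions.

### Limiting filter

Orientation filters occasionally emit large isolated pulses on the Euler
angle channels. The limiting filter holds the last accepted value
whenever a sample jumps by more than a threshold (default 20, in degrees)
relative to it. It runs at every pipeline entry point before cycle
extraction. The threshold matters: left unfiltered, a single ±30° pulse
adds roughly as much DTW cost as an entire cycle of σ = 0.3 noise, making
the cost distribution bimodal and the data-selection threshold
meaningless. The filter is idempotent and causal; its only failure mode
is a pulse on the very first sample of a recording, which would anchor
the hold-last reference wrongly — with realistic pulse rates this is
negligible.

### Phase normalization and templates (time normalization)

Cycle durations vary stride to stride, so cycles are resampled to a
common length before averaging or comparison: stance to 60 points and
swing to 40 points (the standard ~60/40 split of the gait cycle),
per-channel, by cubic splines over normalized phase *within each phase*.
Interpolating the phases separately pins the FO event to row 61 of every
normalized cycle, which is what makes pointwise averaging meaningful. The
template of pattern *i* is the mean over its K contributing cycles,
t_i = (1/K) Σ a_{n,i}, computed on z-scored data; averaging shrinks noise
roughly as 1/sqrt(K) (the test suite verifies a >3× RMS reduction at
K = 20, σ = 0.2). Four samples per phase is the hard spline minimum;
shorter phases raise an error naming the cycle.

Channel statistics for z-scoring templates are computed from the
template-building cycles only and stored on the library.

### DTW matching and cost normalization

A new cycle X (J frames × 10 channels) is compared with each template M
(I = 100 rows) through the cost matrix c(j,i) = ‖x_j − m_i‖² and the
cumulative-cost recursion

D(j,i) = min( D(j−1,i−1), D(j−1,i), D(j,i−1) ) + c(j,i),

with D(1,1) = c(1,1) and border cells accumulating along their only
predecessor (the recursion's boundary conditions are the standard
convention; no warping band or slope constraint is applied). The
backtracked path prefers the diagonal on ties, making results
deterministic. The compiled recursion lives in `src/dtw_core.cpp`; the
test suite pins it to a brute-force enumeration of all monotone paths on
small instances.

Because J varies across cycles, all thresholding uses the
**length-normalized cost** D(J,I)/K, K the path length. The suite checks
the normalization is invariant to duplicating every frame of both
sequences.

### Normalizing the cycles being labeled: a deliberate design choice

The cycles entering automatic labeling are z-scored with channel
statistics estimated *from the session being labeled* (the default
`normalize = "session"` of `autolabel_cycles()`), not with the template
library's statistics. This was the single most consequential design
decision in the package. Cross-day drift in this pipeline behaves like a
per-channel affine perturbation; normalizing the new session by its own
mean and standard deviation cancels exactly that component in the DTW
comparison, while leaving the classifier's raw feature windows drifted —
which is the point: templates must keep labeling reliably on a drifted
day precisely so that the classifier can be retrained on that day's
drifted windows. With library-statistics normalization (available as
`normalize = "library"`), a selection threshold tuned on a same-day
cross-test selects no data at all on a moderately drifted day (the
normalized costs inflate several-fold), and the whole incremental loop
stalls. Session statistics are computed from unlabeled data only, so no
label information leaks.

### Data selection, suppression, and the threshold k

A cycle's pseudo-label is trusted when its best normalized cost is below
k. The data selection rate DR = D_C/D_I is the fraction passing; the
success rate SR = N_C/N_I is the fraction of (selected) pseudo-labels
matching truth. SR is computed over the selected cycles, the set that
actually enters retraining. Where two adjacent cycles disagree in
assigned pattern, both cycles' swing-phase windows are excluded from
retraining (transitions happen in swing; the stance data on either side
still belongs to a single pattern).

k is tuned per subject on a labeled morning/afternoon cross-test:
`tune_k()` returns the smallest grid value maximizing SR subject to
DR ≥ 0.9 (the floor is configurable; if no candidate reaches it, the
highest-DR candidate is returned with a warning — a signal that the grid
or the data are off, not a silent success). The tuned value is then held
fixed for deployment. With the session normalization above, a k tuned
within-day transfers across days: in the packaged day-shift scenario the
tuned k ≈ 2.5 yields deployment DR ≈ 1.0 at SR = 1.0.

### Classifiers

Four classifiers sit behind `classifier_spec()` / `train_classifier()` /
`predict()`, all operating on 300 ms windows stepped by 10 ms (30 × 10
matrices at the 100 Hz default), with separate stance and swing models
that never see each other's windows, and a causal 5-point majority vote
over the prediction stream (ties keep the previous output when it is
among the tied modes):

* **QDA** (`MASS::qda`) on a PCA projection of the flattened window
  (default 20 components, fitted on training windows only). The
  projection is not optional: a 300-dimensional flattened window cannot
  yield a nonsingular per-class covariance at realistic sample counts.
* **SVM** (`e1071::svm`): one-vs-one C-SVC, polynomial kernel, defaults
  C = 1, degree 3, coef0 = 1 — choose(5,2) = 10 binary machines for five
  patterns, which the test suite reads off the fitted model.
* **CNN**, implemented in-package with batched array arithmetic: 5
  kernels of 5×2 (valid) → 26×9×5, average-pool 2×1 → 13×9×5, 8 kernels
  of 4×2 applied per map → 10×8×40, pool 2×1 → 5×8×40, then a softmax
  over the 1600 features; tanh activations, Adam (lr 1e-3), mini-batches
  of 32, default 40 epochs. The shape plan fails loudly if a
  configuration breaks divisibility.
* **LSTM**, implemented in-package: single layer, hidden size 64,
  read out at the last step into a softmax; BPTT with Adam (lr 1e-3),
  default 30 epochs. Forget-gate biases start at 1.

Both networks' gradients are verified against numerical differentiation
in the test suite, and training is deterministic given (spec, seed,
data). None of the network hyperparameters comes from a published
protocol; all are package defaults exposed through `hyper`.

On the synthetic generator the four classifiers reach 0.91–0.98
cross-day window accuracy (QDA lowest); the package does not assert any
finer ordering among them, which on this synthetic task is not stable.

### Experiments

`run_cross_day()` trains on each labeled day and tests on a held-out day.
`run_T_vs_AL()` compares manual training (T) with the automatic-marking
strategy (AL): templates from the train day, pseudo-labels from the test
day's morning session, evaluation on its afternoon — the afternoon never
enters any training set, which a test asserts. `run_template_accumulation()`
grows the template library day by day (AL1..ALm) before running the AL
protocol. Directional findings (AL improves on T under day shift;
accumulating template days does not hurt) are asserted as
majority-over-seeds and median properties, not point values.

## What the generator emulates — and what it does not

`gait_gen_config()` builds per-pattern waveforms as a shared harmonic
base plus a pattern-specific harmonic component (weight
`pattern_separation`), evaluated on a per-cycle phase grid with variable
cycle durations (default 1000 ± 100 ms, clipped at 40% of the mean),
a stance fraction of 0.6, additive Gaussian channel noise, Euler-angle
pulses (rate 0.002/sample, magnitude 30), a pressure plateau of
0.6–1.0 in stance and ~0 in swing, and a per-day affine channel
perturbation for cross-day drift. Defaults were chosen once as plausible
for 100 Hz lower-limb IMU data and are not tuned per test. Each recording
starts with a short unloaded lead-in and ends with a short loaded tail so
every generated cycle is delimited by detectable events, and exact truth
tables (cycle boundaries, FO indices, labels) accompany every recording.

What it does not emulate: biomechanically realistic waveform shapes,
within-day non-stationarity, label noise in the manual labels,
cross-subject variability, or drift that is nonlinear in the channels.
Consequently, passing tests demonstrate the machinery — segmentation,
normalization, matching, selection, retraining, scoring — under
controlled conditions; they do not certify recognition rates on real
recordings. The day-shift scenarios are deliberately affine because that
is the component the session normalization is designed to cancel; a
recognizer facing non-affine drift would retain a residual cost penalty
and correspondingly lower DR.

## Numerical choices and degenerate inputs

* Squared-distance local costs are clipped at zero against rounding in
  the Gram-matrix formulation.
* DTW backtracking tie order: diagonal, then (j−1,i), then (j,i−1).
* Tie between template costs: lowest pattern id wins.
* Majority-vote ties keep the previous output when it is among the tied
  modes, otherwise the smallest tied label — so the vote never emits a
  label absent from its window.
* Channels with zero variance get standard deviation 1 in z-scoring, so
  constant channels map to zero rather than NaN.
* Empty recordings, empty window sets, single-class training data,
  channel mismatches, too-short phases and out-of-range labels all raise
  immediate, specific errors.
* Problem sizes in the tests and the acceptance script (2–6 cycles per
  pattern per day for experiment harnesses, 500 cycles for the labeling
  accuracy check, 10 seeds for directional claims) were chosen as the
  smallest sizes at which the checked properties are stable.

## Known limitations

* Automatic labeling is batch-wise per session (statistics need the
  session's cycles); a streaming variant would need running statistics.
* The QDA route depends on the PCA dimension; 20 components is a
  default, not an optimum.
* The CNN and LSTM are small reference implementations in R — correct
  (gradient-checked) and deterministic, but not fast; the experiment
  harnesses default to QDA/SVM scales.
* `tune_k`'s DR floor (0.9) is a policy default; subjects or conditions
  with genuinely noisy cycles may need a lower floor.
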