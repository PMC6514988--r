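---
title: "Gait type classification from insole sensor arrays: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait type classification from insole sensor arrays: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insoleGait)
```

This vignette documents the model behind `insoleGait`, the assumptions it
makes, the parameters that matter, and the design decisions taken where the
problem left genuine freedom. It states no empirical result beyond what the
package's own tests and `scripts/acceptance.R` compute.

## The measurement model

A two-insole sensor suite samples, at 100 Hz, three synchronized arrays:

* **pressure** — 8 sensors per foot, 16 channels total, each frame
  quantized to 0 (no contact), 1 or 2 (increasing load);
* **acceleration** — three axes per foot, 6 real-valued channels;
* **gyro** — three axes per foot, 6 real-valued channels.

Channels are ordered left foot first (pressure sensors 1–8, then right
9–16; accel/gyro left x,y,z then right x,y,z). The physical placement of
the 8 pressure sensors inside the insole is not standardized across
hardware; the package only relies on the left-foot channels being columns
1–8, with heel-ish sensors listed first — an artifact convention, not a
hardware fact.

During gait, each foot alternates a **stance phase** (foot on the ground,
some pressure sensors non-zero) and a **swing phase** (foot airborne, all
of that foot's pressure sensors zero). The atomic analysis unit is the
**unit step**: the interval from a left-foot swing start to the end of the
following stance.

## Segmentation and the swing-phase artifact

`detect_phase_boundaries()` scans the left foot only: a swing starts at
the first frame where the 8-channel sum reaches zero (or at frame 1), and
the paired stance starts at the first later frame with **two or more**
non-zero channels. Requiring two sensors makes the stance detector immune
to the hardware artifact described next. Frame indices are 1-based with
half-open `[start, end)` intervals — the idiomatic choice in R; every
boundary in the package follows this convention.

Insole pressure hardware occasionally reports a single sensor at level 1
while the foot is airborne (electrical rather than mechanical in origin,
and typically tied to one specific sensor). Left untreated, the artifact
makes one swing look like two, corrupting the segmentation.
`reduce_swing_noise()` therefore zeroes the offending channel on every
frame *inside* a swing interval whose left-foot sum is exactly 1. Two
deliberate edge rules:

* **A sum of 2 is never touched** — one sensor at level 2, or two sensors
  at level 1, is not the single-sensor level-1 artifact (two active
  sensors would in fact open a stance). The cleaning rule is deliberately
  narrow; whether a lone level-2 reading during swing should also be
  cleaned is left to future hardware evidence.
* **Backward extension.** If the artifact lands on the *first* frame of a
  swing, the zero-sum onset is masked and the detected swing start shifts
  late — and the artifact frame then sits inside no swing interval. A
  maximal run of sum-1 frames immediately preceding a detected swing start
  is therefore attributed to the same artifact and zeroed too. This is the
  minimal rule that makes cleaning invert artifact injection exactly
  (verified frame-for-frame in the tests). Its cost: on real data, a
  genuine single-sensor level-1 stance tail directly adjacent to the swing
  would also be zeroed; such frames are rare and carry little load
  information.

`segment_unit_steps()` detects boundaries, cleans, re-detects on the
cleaned array, and emits steps `[swing_i, swing_{i+1})` so that steps tile
the recording without gaps or overlaps. A final stance that runs into the
end of the recording cannot be certified complete, so that step is
dropped; a trailing swing start (even with no following stance) is what
certifies the last step. Frames before the first swing start are
discarded.

## Normalization, flattening, k-step samples

Walking speed varies within and across sessions independently of gait
type, so every unit step is resampled to a common length `t` (default 63,
the shortest unit step observed in the reference experiment; when
processing a new corpus `preprocess_recordings(..., t = NULL)` recomputes
it as the shortest observed step). Resampling is linear interpolation on a
uniform grid over `[0, L−1]` evaluated at `t` points — the minimal
assumption for "resizing" a discrete signal. Pressure channels are then
rounded (R's round-half-to-even) and clipped so the {0,1,2} domain
survives; accel/gyro stay continuous. Steps shorter than 2 frames cannot
be interpolated and raise an error.

A normalized step flattens time-major into vectors of length
`t·W`: 1008 (pressure), 378, 378. For classification, `k` consecutive
steps within a recording are stacked into a `(t·k) × W` array;
windows are **non-overlapping** and leftover steps are dropped — the
sample-count bookkeeping of the reference protocol is consistent with
non-overlapping windows, not sliding ones.

Per-feature standardization (`standardize_samples()`) is fitted on the
training split only — each time/channel cell gets zero mean, unit
(n−1-denominator) variance; zero-variance cells map to 0 — and the frozen
transform is applied to the test split. Refitting inside every split
prevents test-set leakage.

## The networks

Each single-modal DCNN (`build_single_modal()`):

| stage | configuration |
|---|---|
| conv 1 | 32 filters, extent H = 20 spanning all W channels, stride s |
| conv 2 | 64 filters, extent 20 over the 32 feature channels, stride 1 |
| conv 3 | 128 filters, extent 20 over 64 channels, stride 1 |
| head | flatten → dense 256 → dense 128 → dropout 0.5 → softmax (7) |

with ReLU activations and batch normalization **after** the activation in
every conv block, valid padding throughout, and Xavier-uniform
initialization. The first-layer stride follows the sample length: s = 1
for k ∈ {1, 2}, s = 2 for k ≥ 3 (`default_stride()`), keeping the deeper
feature maps long enough for the 20-frame filters; later layers always
use stride 1, since only the first layer faces the long input. There are
no pooling layers — stride provides the only downsampling, and the
concrete reference configuration names none. A valid layer over `len`
frames yields `conv_output_length(len, H, s) = ⌊(len−H)/s⌋ + 1` positions;
for k = 1 the chain is 63 → 44 → 25 → 6, giving 768 flattened features.

Choices the architecture left open, fixed here as defaults:

* **Hidden sizes 256 and 128** for the two fully connected layers
  (configurable via `fc_sizes`): large enough for the 768–2304-long
  feature vectors, small enough for datasets of a few thousand samples.
* **Dropout 0.5** (the explored range is 0.5–0.7), applied once, after the
  second hidden layer, immediately before the output layer.
* **Accel/gyro width W = 6** (both feet). Storing per-foot 3-axis arrays
  and treating each foot as its own 3-wide modality is supported through
  `split_feet()`, whose outputs can be fused like any other modality.
* **Epochs default to 50**, with optional early stopping on a held-out
  fraction of the training split (`validation_split`,
  `early_stopping_patience`); both histories are kept on the returned
  network.

Training (`train_model()`) is plain backpropagation: categorical
cross-entropy, Adam (learning rate 1e-4, β₁ = 0.9, β₂ = 0.999, ε = 1e-8),
batch size 32, shuffled mini-batches. Batch-norm running statistics use
momentum 0.9 and ε = 1e-5; inference (`predict()`, `extract_features()`)
uses the running statistics and disables dropout. All randomness —
initialization, shuffling, dropout — derives from the configured seeds,
and the caller's RNG state is always restored. Argmax ties in prediction
resolve to the lowest class code.

The multi-modal classifier (`build_multi_modal()`) is two-stage by
design: single-modal networks are trained end-to-end first so each array
learns its own feature map; their convolution stacks are then frozen and
a fresh head is trained on the concatenated features. Freezing makes the
fusion cheap (features are extracted once per training run) and keeps the
per-modality extractors interpretable in isolation.

## What the simulator emulates — and what it does not

`simulate_recording()` generates, per step: a truncated-Gaussian duration
(per-class means 105, 85, 68, 115, 95, 110, 100 frames for walking, fast
walking, running, stair climbing/descending, hill climbing/descending;
SD 6, clamped ≥ 4 frames — about a second per step for level walking at
100 Hz, faster gaits shorter, ascent longer); a swing of `1 −`
stance-fraction of the step (stance fractions 0.62, 0.58, 0.45, 0.64,
0.60, 0.63, 0.61 — running spends the least time on the ground); left-foot
stance pressure following a heel-to-toe template (heel sensors active from
stance onset — guaranteeing the ≥ 2-sensor stance start — forefoot from
~0.3, toes from ~0.5 through toe-off); a right foot half a step out of
phase; and accel/gyro channels as sums of three harmonics of the step
cycle with class-specific amplitude mixes and phases plus Gaussian noise
(SD 0.1 at unit base amplitude). Twelve all-zero pressure frames are
appended after the final stance so the last step is demonstrably
complete. `simulate_dataset()` additionally injects the swing artifact at
probability 0.05 per swing frame on left channel 3 — the sensor reported
to misread — so the pipeline's cleaning is exercised under its intended
conditions. Ground-truth boundaries are returned alongside every
recording.

What this deliberately does **not** model: biomechanical kinematics,
subject-specific gait signatures, sensor drift, inter-class confusability
calibrated to real insoles, or the real per-class step-count imbalance.
Because the class signal lives in cleanly parameterized harmonic mixes,
the synthetic classes are *more* separable than real gait types: passing
tests demonstrate that the pipeline and networks are implemented
correctly and can extract class structure end-to-end, not that real-world
accuracy would reach the same level. The chance-level test (training on
label-shuffled data lands at ≈ 1/7 accuracy) guards against the opposite
failure — accidental label leakage through the pipeline.

## Evaluation protocols

`split_random_subsample()` draws disjoint train/test index sets without
replacement, independently per repetition (defaults 1000/1000, 20
repetitions). `split_kfold()` partitions `n` samples into K folds whose
sizes differ by at most one (equal-as-possible; 13,531 samples in 7 folds
give exactly 1,933 test and 11,598 training samples). `run_experiment()`
stratifies splits by class by default — small synthetic runs would
otherwise occasionally lose a class from a training set; set
`stratify = FALSE` for the unstratified protocol. Within every split the
driver refits standardization, trains one network per modality plus the
fused head when several modalities are requested, and aggregates
per-repetition accuracies (mean, SD, pooled confusion matrix). All
per-fit seeds derive from the protocol seed and are recorded in the
result.

## Problem sizes used by the shipped tests

The test-suite and acceptance sizes are the package's own choices,
balancing statistical force against desk-scale runtimes: the headline
check trains on the default synthetic dataset of 200 one-step samples per
class (1,400 total; 8 recordings × 25 steps per class) with a stratified
1000/400 split and 15 epochs; the fusion-versus-single-modal comparison
uses 5 seeded repetitions of a 245/105 split on a 350-sample dataset at 4
epochs; the chance-level check uses the same dataset with 3 epochs.
Property suites (boundary recovery, artifact round-trip, convolution
arithmetic up to length 400) run at full strength since they are cheap.

## Known limitations

* Segmentation is left-foot-anchored by definition; a recording whose
  left-foot pressure channels fail entirely yields no steps.
* The cleaning rule addresses the single-sensor level-1 artifact only;
  other fault modes (stuck-at-2 sensors, cross-channel crosstalk) pass
  through.
* Training determinism holds for a fixed seed, platform and BLAS; exact
  weight equality across different BLAS builds is not guaranteed.
* The pure-R network engine is sized for the small architectures used
  here (≤ a few million parameters); it is not a general-purpose
  deep-learning framework.
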