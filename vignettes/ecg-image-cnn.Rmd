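---
title: "Methods: image-based MI detection and localization from 12-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based MI detection and localization from 12-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgmi)
```

## The pipeline

Myocardial infarction (MI) leaves localized signatures on the 12-lead
electrocardiogram: ST-segment deviation, pathological Q waves and T-wave
inversion appear in the lead group that "looks at" the infarcted wall
(inferior infarcts in II, III, aVF; lateral in I, aVL, V5–V6; posterior
infarcts as reciprocal ST depression in V1–V3; and so on). This package
implements a deliberately preprocessing-free pipeline that turns raw
multichannel voltage into a classification decision in three stages.

**Signal to images.** Each record is cut into non-overlapping windows of
`W = 1000` ms (`window_spec()`), the width chosen because a resting heart
beats about once per second, so a window typically contains one beat. No
beat detection, alignment, filtering or detrending is performed — the
method's premise is that a convolutional network can absorb the resulting
variation. Every lead's window is rasterized (`rasterize_window()`) onto a
64 × 64 canvas with 256 gray levels: time maps linearly to x, per-window
min–max-normalized amplitude to y (positive voltage up), and the samples
are joined into a polyline drawn at 4× supersampling, one final pixel
thick, then box-downsampled. The downsampling is what produces smooth
antialiased gray ramps on oblique strokes. The twelve images from one
window form an *ECG image set*, the classification unit.

**The 12-branch CNN.** Each lead has its own tower of six 3 × 3 valid
convolutions (batch-normalized, ReLU) interleaved with three max-pooling
layers; the towers do not share weights, so each lead's morphology is
learned separately. Pooling strides are not free parameters: the published
layer dimensions (64 → 62 → 60 → 29 → 27 → 25 → 12 → 10 → 8 → 3) force
stride 2 for every pool and stride 1 / no padding for every convolution
under the standard arithmetic `out = floor((in + 2p − k)/s) + 1`
(`layer_output_size()`). Each tower flattens to 32 × 3 × 3 = 288 features;
concatenating 12 towers gives 3456, followed by dense layers
3456 → 2048 → 1024 → K and a softmax. Training minimizes cross-entropy
against one-hot labels with Adam. `K` is task-dependent: 2 for detection
(all MI classes merged into one positive label), 11 for full localization,
8 for localization under the subject-held-out protocol.

**Evaluation.** Two cross-validation protocols are implemented
(`run_cross_validation()`). *Setting 1* stratifies the image sets of each
class equally and randomly over ten folds; image sets of one subject may
appear in both partitions, deliberately. *Setting 2* is leave-one-subject-
out: each fold tests exactly one subject's image sets and trains on
everyone else, and classes with a single subject are excluded (a held-out
singleton could never be trained on). A single confusion matrix is
aggregated over folds; sensitivity TP/(TP+FN), specificity TN/(TN+FP) and
accuracy (TP+TN)/total are reported for detection, per-class
(diagonal/row-total) and overall (trace/total) accuracy for localization.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| window width `W` | 1000 | ms | one resting beat per window |
| window shift | `W` | ms | non-overlapping tiling; trailing partial window discarded |
| image side | 64 | px | published raster size |
| gray levels | 256 | – | published depth; antialiasing needs the head-room |
| supersample | 4 | – | smooth oblique strokes after box-downsampling |
| margin | 2 | px | keeps the 1-px trace and its halo off the border |
| learning rate | 1e-3 | – | Adam convention |
| batch size | 64 | – | Adam convention |
| epochs | 30 | – | unstated upstream; exposed in `train_config()` |

## Decisions the sources left open

* **Amplitude normalization** is per-window, per-lead min–max. No
  preprocessing stage exists to remove offset or trend, so scaling must be
  local; min–max preserves baseline trend as visible slope, which matches
  the reported failure modes (strong-trend windows misclassify). A direct
  consequence is exact affine invariance: `a·v + b` (a > 0) renders
  pixel-identically. The normalized amplitude is quantized to 2^-20 before
  pixel mapping so that floating-point noise in affine-equivalent inputs
  cannot flip a rounding boundary.
* **Flat windows** (max = min) render as a single centered horizontal line
  at row `floor(side/2)` — deterministic, no division by zero.
* **Trace polarity**: background 0, trace 255. Any fixed choice works
  since it is constant across classes; sparse nonzero support is
  convenient.
* **Pooling type** is max pooling (unstated upstream); standard for
  trace-on-background images and configurable.
* **Batch-norm placement** is after each convolution/dense layer, before
  the activation — the conventional reading of a per-layer "BN: true"
  table. Batch statistics are used in training, running averages
  (momentum 0.1) at prediction.
* **Ties** in the output probabilities break toward the lowest class
  index, documented in `predict()`.
* **Report rounding** is half-up to 4 decimals, matching the printed
  tables (`round()`'s round-half-to-even would disagree).
* **"Two-fold cross-validation where one patient is used for testing"** is
  read as leave-one-subject-out iterated over all eligible subjects: one
  train/test split per patient is the only reading consistent with
  aggregate confusion matrices that cover every image set exactly once.
* **Macro averaging scope** for multiclass sensitivity/specificity
  defaults to all classes and is configurable (`macro_scope = "mi"`); the
  upstream summary averaging is not defined, so these two summary numbers
  are not golden-tested.
* **Class imbalance is not corrected** — the subject-held-out specificity
  loss is attributed to imbalance upstream and left uncorrected there too.

## The synthetic 12-lead generator

No clinical waveforms ship with the package; a seeded generator
(`make_subject()`, `synthesize_record()`, `generate_dataset()`) stands in
for them so every stage is testable offline.

A beat is a sum of five Gaussian wavelets (P, Q, R, S, T) with fixed
centers, widths and amplitudes, projected onto the 12 leads by per-lead
multipliers (R upright in I, II, V4–V6, inverted in aVR). A subject is a
deterministic function of `(label, seed)`: per-wave amplitude jitter
(±20%), a global timing scale (±10%, order-preserving), lead-multiplier
jitter (±10%) and a heart rate drawn from 55–90 bpm — all drawn from a
label-independent stream, so matched seeds give the same underlying beat
across classes. The label then adds its infarct signature on the class's
lead group: a smooth ST plateau between the S and T waves (sigmoid
shoulders, τ = 8 ms), Q deepening and T attenuation/inversion on primary
leads, ST depression on reciprocal leads (V1–V3 for posterior
involvement). Records add white noise (σ = 0.03 mV), sinusoidal baseline
wander (0.1 mV at 0.3 Hz, random phase per lead) and per-beat onset jitter
(σ = 8 ms). The infarct-site → lead-group map is configuration
(`mi_lead_map()`), using standard clinical correspondences.

Per-subject perturbation magnitudes are drawn uniformly (ST shift
0.25–0.50 mV, Q deepening 0.15–0.35 mV, T inversion factor 0.5–0.9).
These ranges were calibrated once so that the corpus satisfies the
module's own separability requirement — a width-reduced network must reach
≥ 90% accuracy under random-split evaluation, establishing that the
fixture carries learnable class signal — while magnitudes still vary
enough between subjects that held-out-subject generalization remains
visibly harder. They are within the range of marked, established
infarction on clinical ECGs.

**What a green test does and does not establish.** The generator emulates
class-discriminative morphology, between-subject variability, noise and
trend; it does not emulate arrhythmia, electrode misplacement, pacing,
conduction blocks, heteroscedastic muscle artifact, or the covariate
structure of real patient populations. Green synthetic tests establish
that the pipeline's machinery is correct and that the protocol gap
(random-split accuracy > subject-held-out accuracy) emerges when
between-subject variability exists; they do not certify clinical
performance, and the published full-scale accuracies are not reproducible
without the clinical corpus and GPU-scale training.

## Numerical and engineering notes

* The network is implemented in R with C++ kernels (direct 3 × 3 grouped
  convolution — the 12 per-lead towers run as one grouped layer with
  block-diagonal weights — fused batch-norm/ReLU, max-pool with cached
  argmax). Gradients are verified against numeric differentiation in the
  test suite. Training is single-threaded and bit-reproducible given the
  seeds; there are no stochastic layers beyond shuffling.
* He-normal initialization; Adam with β₁ = 0.9, β₂ = 0.999, ε = 1e-8 and
  bias correction; BN ε = 1e-5.
* Large short-lived activation tensors are glibc-tuned at package load
  (`mallopt`: no mmap for large allocations, no trim) — on virtualized
  hosts with slow page faulting, first-touch cost otherwise dominates
  training time.
* The acceptance experiment scales the published world down (8 classes ×
  5 subjects × one 10-s record; width-reduced towers 1–4 channels; 5
  epochs) so the split-protocol comparison runs in minutes on one CPU.
  Accuracies at this scale are far below the full-scale ones by design;
  only their order (random split > subject-held-out) is asserted.

## Known limitations

* WFDB support covers the header/signal pair in format 16 (the PTB
  layout), not the full WFDB zoo (multi-segment records, other formats).
* Class labels are external inputs: the artifact/arrhythmia screening of
  the source corpus was manual and is not reproduced.
* Fixed window width; no heart-rate-adaptive windowing, residual blocks,
  attention, or saliency explanations (listed upstream as future work).
* The reduced-scale CNN underfits relative to the full-width model; the
  full-width architecture is available but impractical to train here.
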