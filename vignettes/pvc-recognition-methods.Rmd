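---
title: "Methods: patient-specific PVC recognition from single-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-specific PVC recognition from single-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvcnet)
```

## The problem

A premature ventricular contraction (PVC) is an ectopic beat arising in
the ventricles rather than the sinoatrial node. On a single-lead ECG it
shows a characteristic morphology: the P wave is absent, the QRS complex
is wide (beyond 120 ms, against 60–120 ms for a sinus beat), the R-peak
amplitude is either markedly larger (left-ventricular focus, above 125%
of a normal R) or markedly smaller (right-ventricular focus, below 50%),
the T wave is discordant (inverted relative to the QRS), and the beat
arrives early, with a shortened coupling interval followed by a
compensatory pause that perturbs the otherwise regular 0.6–1.2 s RR
rhythm.

`pvcnet` implements a full recognition pipeline for this beat class:
annotated ECG records are segmented into individual beats, each beat is
rendered as a small RGB image, and a residual convolutional network with
a two-class softmax head separates PVC from normal beats. Evaluation is
*patient-specific*: a model is never tested on beats from a subject it
saw during training, which is the setting that matters for wearable and
clinical deployment on unseen patients.

## Pipeline stages and the choices behind them

### Record IO and resampling

Records follow the PhysioNet WFDB convention (`.hea` header, 16-bit
`.dat` signal, MIT-format `.atr` beat annotations), with amplitudes
normalized to mV at read time using the header gain, so every downstream
stage works in one unit. Annotation symbols map totally onto three
labels: `N` → NORMAL, `V` → PVC, everything else → OTHER. OTHER beats
stay in the record (raw data are lossless) and are filtered only at
segmentation time. The normal-symbol set is configurable (e.g. folding
bundle-branch-block beats `L`/`R` into NORMAL) because annotation
conventions differ across archives.

Resampling uses polyphase band-limited interpolation at the reduced
rational ratio p/q. Annotation indices are rescaled by the same ratio
and rounded half-to-even — a deterministic, unbiased tie-break. When a
fixed-size subset of an archive is wanted (selection policies also drop
excluded record ids and records without PVCs), truncation is by
ascending record id: the archives this mirrors do not document which
subset was used, so the rule must above all be reproducible.

### QRS detection

R peaks are located with the Pan–Tompkins algorithm. The classic
integer-coefficient recursive filters are specified for a 200 Hz
sampling rate, so records are resampled to 200 Hz for detection — this
removes all filter-design ambiguity and makes the stage bit-reproducible.
The cascade is: band-pass (~5–15 Hz, the low-pass
`y[n] = 2y[n-1] − y[n-2] + x[n] − 2x[n-6] + x[n-12]` followed by the
high-pass `y[n] = y[n-1] − x[n]/32 + x[n-16] − x[n-17] + x[n-32]/32`),
five-point derivative, squaring, and a 150 ms moving-window integration.
Peak picking on the integrated signal uses adaptive dual thresholds
(`threshold_2 = 0.5 × threshold_1` at all times), a 200 ms refractory
period, T-wave rejection by slope comparison within 360 ms, and
search-back at the lower threshold when no beat is found within 1.66 ×
the recent RR average.

Two details are conventions of this implementation rather than classic constants of the algorithm, and are documented as such:

* the learning phase initializes the signal level from 0.25 × the
  maximum and the noise level from 0.5 × the mean of the first 2 s of
  integrated signal;
* each detection is refined to the extremum of the raw 200 Hz signal in
  an asymmetric window (−120 ms, +40 ms) around the delay-compensated
  integration peak. The asymmetry matters for ectopic beats: a wide PVC
  spreads its integration energy late, so the R wave sits toward the
  early edge of the integration hump. Detections are then mapped to
  native-rate indices by the exact rational ratio.

### Beat segmentation and labelling

A beat spans from the midpoint between its R peak and the previous one
to the midpoint toward the next one:
`[floor((R_{k−1}+R_k)/2), floor((R_k+R_{k+1})/2))`, half-open, 0-based.
The first and last peaks have no two-sided midpoint and are dropped, so
the windows tile the covered span exactly. An alternative reading of the
midpoint rule — a window of ± half the local RR centred on R — coincides
with this one for uniform rhythm; the implemented reading is the stated
one and the anchoring is configurable. Beats are anchored on reference
annotation positions when available and on detector output otherwise
(both modes exist because annotated archives are trained on, yet a
deployed system only has the detector).

Each segmented beat takes the label of the nearest annotation within
0.15 s of its R index; beats with no match, or matching an OTHER
annotation, are discarded and counted.

### Beat-to-image rendering

Each beat becomes an RGB raster: the waveform drawn as a connected
polyline on a plain background, no axes or margins, vertical axis
min–max normalized per beat (removing inter-record gain differences; a
constant beat renders as a mid-height line), horizontal axis spanning
the window. Rendering is a pure function of the samples and the render
configuration — the package rasterizes the polyline itself rather than
going through a graphics device precisely so that identical inputs give
byte-identical pixels on any platform. Defaults: 224 × 224 (matching the
expected input of standard pretrained backbones), white background,
2-pixel dark-blue line; all style parameters live in `render_config()`.

### The classifier

The network is the 18-layer basic-block residual architecture: a 7×7
stride-2 stem convolution (64 filters) with 3×3 stride-2 max pooling,
four stages of two basic blocks with (64, 128, 256, 512) filters, global
average pooling, and a fully connected softmax head with 2 outputs. Each
basic block computes `y = relu(F(x) + shortcut(x))`, where `F` is two
3×3 convolutions with batch normalization after each and ReLU between.
When input and output dimensions agree the shortcut is the identity and
adds no parameters; where the dimension increases (first block of stages
2–4, stride 2) the default is a learned 1×1 projection `W_s`
(`y = F(x) + W_s x`), with a parameter-free strided zero-padding variant
available. Channel count doubles exactly where spatial extent halves.
Batch normalization is the standard companion of this architecture; a
pass-through mode exists solely so the residual identities can be
checked algebraically in tests.

Transfer learning is an *input*, not something the package reproduces:
`build_model(spec, pretrained_backbone = TRUE, backbone_path = ...)`
loads externally supplied backbone weights and randomly initializes the
head; without a weights file the call fails with instructions to run
with `pretrained_backbone = FALSE` (the offline default, He
initialization everywhere). Backbone layers are not frozen during
fine-tuning; freezing is a config-level choice left to the caller.

Because the head is global average pooling, the model accepts any raster
size; `input_size` in the spec documents the intended one. A reduced
`resnet_tiny_spec()` (16-filter stem, stages (16, 32), 64 × 64 input)
ships for desk-scale end-to-end runs — training the full 18-layer
network on CPU is out of scope for routine testing, and the tiny spec
exercises every code path (projection shortcuts, striding, the head) at
a few-minutes scale.

### Imbalance-aware training

PVC datasets are heavily imbalanced, so three mechanisms keep the
minority class visible:

* **Per-batch class weights** `η_c = 1 − |X_c|/|X|`: the complement of
  the class's share of the batch, so the rarer class carries the larger
  weight and a balanced batch gives 0.5/0.5.
* **Weighted binary cross-entropy**
  `l = −(1/n) Σ η_{i(x)} [y ln p + (1−y) ln(1−p)]`, with the predicted
  PVC probability clamped to `[1e−7, 1−1e−7]`. The sign convention makes
  the minimized quantity non-negative with zero exactly at (clamped)
  perfect prediction, matching the loss's purpose. Reduction is the
  batch mean. A literal single-class batch would zero the present
  class's weight and kill the gradient; the weighted sampler makes this
  effectively impossible, and if it does occur the batch falls back to
  unweighted loss with a warning.
* **Weighted random sampling** with replacement, each item weighted
  inversely to its class frequency, so an epoch's expected class mix is
  50/50 regardless of the dataset imbalance.

On-the-fly augmentation applies a small random affine jitter per draw
(translation ≤ 5% of the raster, scale 0.95–1.05, rotation ≤ 5°) and is
never persisted. There is deliberately no horizontal flip: time reversal
would change what the beat means.

Optimization is Adam at an initial learning rate of 0.001 with batch
size 32. A random 10% of the training items forms the validation split —
by item, not by subject, which accepts a degree of subject-level overlap
between the training and validation portions as part of the protocol
(the *evaluation* subjects remain strictly disjoint and this is asserted
at fit time). After each epoch the learning rate is multiplied by 0.1 if
the validation loss has not improved for 5 successive epochs, and
training halts after 8 such epochs or at the epoch cap; "has not
improved" means no decrease beyond 1e−6, since exact equality is too
strict for floating point. Best-validation weights are restored at the
end. One numerical safeguard is specific to small-data training: with
only a handful of batches per epoch, exponential running estimates of
the batch-norm statistics lag behind the fast-moving weights, corrupting
the validation loss that the scheduler and early stopping react to.
Before each validation pass the running statistics are therefore
recalibrated by plain averaging over a few fixed unaugmented training
batches.

### Evaluation designs and metrics

Four patient-specific designs: train on one archive and test on a
disjoint-subject second archive (both directions), and
leave-one-subject-out cross-validation within each archive. LOSOCV folds
are aggregated by summing the per-fold confusion matrices (micro
aggregation — the aggregate total then equals the dataset size, and a
single whole-dataset matrix is reported); per-fold reports are also
kept. Subject identity equals record identity (one record per subject in
the archives this models). Beat-level hold-out and stratified k-fold
harnesses exist as non-patient-specific baselines; stratification deals
each class round-robin over folds, so per-fold class counts match the
dataset proportions to within one beat.

The metrics engine computes per-class precision, recall, F1 and
specificity (each class in turn as positive), overall accuracy, macro
averages, and balanced accuracy = (recall + specificity)/2 with PVC as
positive — equal to macro-average recall in the binary case. Balanced
accuracy is computed from raw counts, not from pre-rounded table
entries; the two can disagree in the last printed digit. Metrics with a
zero denominator are reported as `NA` and flagged, never coerced to 0.
Printed percentages round half away from zero to two decimals.

## The synthetic generator: what it emulates and what it does not

Every stage above is testable without external data because the package
generates annotated synthetic ECG with known ground truth. A beat is a
sum of Gaussian bumps, one per wave phase. The normal template carries a
P wave (~80 ms, 0.15 mV, 160 ms before R), a QRS complex measuring
80–120 ms at the 10% amplitude crossing, and an upright T wave; RR
intervals are drawn around a configurable mean within the normal
0.6–1.2 s band. The PVC template has no P wave, a QRS wider than 120 ms,
an inverted T, an R amplitude 140% of normal by default (configurable
below 50% for the right-ventricular variant), a 0.7× shortened coupling
interval and a 1.3× compensatory pause. Rendered class separation in QRS
width exceeds 20 ms by construction, which is what guarantees
learnability at desk scale.

The generator emulates morphology, rhythm and additive Gaussian noise —
and nothing else. Real recordings contain baseline wander, powerline
interference, muscle artifact, electrode motion, beat-to-beat morphology
drift within a subject, and annotation errors; none of these are
modelled. Synthetic subjects differ only through their RR/noise
realizations, not through systematic morphology differences. Passing
tests on this data therefore demonstrate that the pipeline's mechanics
are correct (detection, tiling, labelling, learning, fold hygiene), not
that benchmark-level performance transfers to clinical recordings;
results on the real archives require downloading them and
fine-tuning the full pretrained network, which is outside the package's
test scope.

`measure_beat()` closes the loop: it measures QRS duration (length of
the contiguous region around R where the 10 ms-dilated amplitude
envelope exceeds 10% of the R amplitude — the dilation bridges the zero
crossings of biphasic complexes), R amplitude, and P-wave presence, and
the test suite asserts the template invariants through it.

## Desk-scale problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to exercise every component in a few minutes of CPU:
detector checks use 200-beat records (clean and with 0.05 mV noise);
segmentation properties use 1000 random peak sets; the end-to-end
patient-specific run uses 400 beats (20% PVC) from 10 synthetic
subjects, 64 × 64 rasters, the tiny spec, and 8-epoch training per
LOSOCV fold. The full 224 × 224 / 18-layer configuration is the default
for real use.

## Known limitations

* The WFDB codec covers format-16 signals with scalar gain — the subset
  the package writes and the common arrhythmia archives use — not the
  full format zoo.
* The detector is single-lead; no multi-lead voting or alternative
  (wavelet, neural) detectors.
* Only additive Gaussian noise in the generator (see above).
* No ROC/AUC reporting and no significance tests between experiment
  designs; the report surface mirrors the confusion-matrix metric set.
* Training is plain single-threaded CPU; no mixed precision, no
  distributed training, no hyperparameter search.
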