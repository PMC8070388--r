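---
title: "Blood-pressure level classification from PPG spectral images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-pressure level classification from PPG spectral images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgplus)
```

## The problem and the pipeline

Hypertension is mostly silent, and a single cuff reading is a poor summary
of a person's blood-pressure state. A photoplethysmogram (PPG) — the optical
blood-volume pulse that any fingertip sensor records — carries
blood-pressure-related information in its waveform morphology: as pressure
rises, the tidal wave migrates toward the systolic (main) wave until the two
merge, the peak grows rounder, and the descending branch steepens. The first
derivative (PPG′) tracks aortic flow velocity and the second derivative
(PPG″, the acceleration plethysmogram) vascular elasticity, so the
derivatives carry complementary information.

This package implements a full image-based classification pipeline over
that idea:

1. **Pairing and labelling.** 10-s PPG records at 125 Hz are paired with
   simultaneous arterial-pressure (ABP) waveforms, cut into 5-s segments,
   and each PPG segment inherits the JNC7 class (normotension NT,
   prehypertension PHT, hypertension HT) of the systolic/diastolic
   pressures extracted from its ABP segment.
2. **Preprocessing.** Zero-phase 0.4–8 Hz Butterworth band-pass, min–max
   normalisation.
3. **EEMD denoising.** Ensemble empirical mode decomposition splits each
   segment into intrinsic mode functions (IMFs); reconstruction from the
   0.4–13 Hz IMFs removes residual motion artifact and baseline drift.
4. **Hilbert–Huang spectra.** Each IMF's analytic signal yields per-sample
   instantaneous amplitude and frequency; amplitudes are binned on a
   0–13 Hz × 0–5 s grid.
5. **PPG+ images.** The spectra of PPG, PPG′ and PPG″ become the R, G and B
   channels of a 1247 × 770 8-bit image; network inputs are standardized
   3 × 224 × 224 tensors.
6. **Classification.** A convolutional classifier is trained per binary
   trial (NT vs HT, NT vs PHT, NT+PHT vs HT) under a stratified, grouped
   7:3 split with 5-fold cross-validation, reporting F1, sensitivity (TPR),
   specificity (TNR) and ROC curves.

## The synthetic cohort: what it emulates and what it does not

Everything here runs from a synthetic cohort generator, so the pipeline is
testable end to end without any clinical download.

A beat is modelled as a sum of three Gaussian bumps on the circular beat
phase — systolic wave, tidal wave, dicrotic wave — because that is the
smallest parametric family that can express the tidal-wave migration and
descending-branch steepening described above. Distances on the beat phase
are wrapped, so consecutive beats join without discontinuities and a clean
beat train at heart rates up to 2 Hz keeps its spectral content below the
13 Hz spectrogram ceiling (verified to −40 dB in the tests). The class
templates place the NT tidal wave well after the systolic peak (two visible
maxima), merge the HT tidal wave into a single rounded maximum with a
steeper descending flank (right-flank width narrowed 1.25×), and put PHT in
between.

Per-class pressures are drawn uniformly from disjoint JNC7-consistent
boxes: NT SBP ∈ [100, 119] / DBP ∈ [60, 79]; PHT SBP ∈ [120, 139] /
DBP ∈ [80, 89]; HT SBP ∈ [140, 180] / DBP ∈ [90, 110] mmHg. The ABP
waveform is rescaled so its global extrema equal the drawn pressures
exactly, which is what the labelling stage extracts. Heart rate is uniform
in 0.8–2 Hz with ±5% beat-to-beat jitter (a perfectly periodic train has a
degenerate line spectrum that flatters the spectral stages). Contamination
is additive white noise plus a sub-0.4 Hz sinusoidal drift, both
amplitude-configurable.

What the generator does **not** emulate: pulse-transit-time physiology,
sensor-specific artifacts (clipping, motion spikes), respiratory
modulation, inter-subject morphology variability beyond the three
templates, or any within-class correlation between pressure and waveform
shape. Passing tests therefore demonstrate that the pipeline's machinery is
correct and that morphology-separable classes are learnable from PPG+
images — not that the classifier would reach any particular accuracy on
clinical recordings.

## EMD, EEMD and the Hilbert spectrum: numerical choices

**Sifting.** Envelopes are cubic splines through the local maxima/minima
with the two edge extrema mirrored past each end (suppresses end swings).
Sifting stops on the Cauchy criterion `sum(m^2)/sum(h^2) < 0.2` — the
canonical threshold — or after 50 iterations; IMF extraction stops when the
residue has too few extrema to sift or after 10 IMFs. The decomposition
reconstructs the input exactly by construction (telescoping sum), and the
tests hold it to 1e-8 relative error.

**EEMD.** Default ensemble of 100 members with noise at 0.2 × signal SD and
deterministic per-member sub-seeds. `ensemble_size = 1, noise_std = 0`
reduces exactly to plain EMD. The pipeline runs EEMD at ensemble size 4 by
default: the synthetic segments are short and clean, the tests show mixing
suppression already at small ensembles, and the full ensemble of 100 is a
per-call option rather than a pipeline default. Desk-scale problem sizes
used throughout the examples, tests and the acceptance script — 60-record
cohorts (120 segments), ensemble 4, 10 training epochs — are the package's
chosen study conditions for CPU execution.

**Analytic signal.** The discrete Hilbert transform treats its input as
circular, so a non-periodic oscillation has a wrap discontinuity whose
leakage corrupts envelope and phase far into the segment (a 7.5-cycle tone
in a 5-s window is off by ~9% across the interior under the plain
transform). `analytic_signal()` therefore extends the signal on both sides
with its *characteristic wave* — the spline interpolant reflected about the
sub-sample position of the first and last extremum, which continues any
oscillation smoothly and a pure tone exactly — transforms, and crops. Over
a tone grid of 0.8–9 Hz crossed with arbitrary phases the worst interior
envelope/frequency error is 1.5%. Instantaneous frequency is the forward
difference of the unwrapped phase, clamped at zero and 5-sample median
smoothed; signals with fewer than two extrema are transformed without
extension.

**Mean IMF frequency** (used by the band-selective reconstruction and the
ordering property) is the amplitude-weighted mean of the instantaneous
frequency: where an IMF's envelope is near zero its phase slope is
meaningless, and weighting suppresses exactly those samples.

**Spectrum and rendering.** Amplitude (not squared energy) is accumulated
on a 130 × per-sample grid (0.1 Hz bins) and rendered by nearest-neighbour
resampling to 1247 × 770 with linear max-to-255 intensity scaling —
rendering only ever aggregates, never interpolates new mass. Per-channel
max scaling makes the image invariant to overall amplitude, which is
intentional: morphology, not gain, is the signal.

## Dataset and training design

**Grouped splits.** Both 5-s halves of a record are near-duplicates, so the
7:3 split and the fold assignment group by record; no record ever straddles
train and test (twin-segment leakage). Both operations stratify by class;
`make_folds()` refuses configurations that would leave a fold without one
of the trial classes.

**Augmentation and tensors.** Training-time augmentation is a seeded
random aspect-ratio crop (area 0.7–1.0, ratio 3/4–4/3), horizontal flip at
p = 0.5, then a centre square crop; the evaluation path is the
deterministic centre crop. Tensors are 224 × 224, scaled to [0, 1] and
standardized with the widely used pretrained-backbone channel statistics
(0.485/0.456/0.406, 0.229/0.224/0.225). The pipeline's default desk-scale
training uses the deterministic path for both splits; per-epoch
augmentation is available through `augment()` for users who want it.

**Backbones.** `adapt_backbone()` performs the usual fine-tuning surgery:
AlexNet loses its 1000-way head and gains dropout plus a fresh 4096 → 2
layer (57.01M trainable parameters, 0.71 GMACs per forward pass at
3 × 224 × 224 under the documented counting convention: kernel × positions
for convolutions, fan-in × fan-out for affine layers, biases/activations/
pooling excluded); ResNet18/34 swap in a fresh 512 → 2 head. No pretrained
weight archive ships with the package, so `pretrained = TRUE` keeps the
fine-tuning *structure* with seeded random initialisation of the retained
layers. AlexNet and `small_cnn` are executable end to end in the package's
own CPU layer engine (im2col convolutions over BLAS, verified against
numerical gradients to 5e-9); the ResNets are architecture tables for
adaptation and counting.

**small_cnn.** The desk-scale backbone: input zero-centering, 4× average
pooling (224 → 56), three conv/ReLU/max-pool blocks (8/16/32 channels),
then 1568 → 64 → 2 affine layers (~106k parameters). Two of its choices
matter and were made deliberately:

- *Input centering.* Spectrogram tensors are mostly background, which the
  natural-image standardisation constants map to ≈ −2 per channel; a ReLU
  stack initialised symmetrically around zero then starts mostly dead and
  short training runs stall at the majority-class rate. Zero-centering each
  input tensor inside the network restores the usual initialisation
  regime. (The dataset-side constants are kept as-is because they are the
  convention the pretrained backbones assume.)
- *Head dropout 0.2.* The 0.6 used for AlexNet regularises a 4096-unit
  head; on a 64-unit head it mostly prevents the model from fitting
  anything in short runs. `model_spec()` therefore defaults dropout to 0.6
  for the wide backbones and 0.2 for `small_cnn`, overridable either way.

**Loss.** Softmax cross-entropy with class-balanced weights
(w_c = n / (K·n_c)) and Adam (lr 0.001, the standard moment constants).
Random class draws make fold class counts unequal; unweighted training at
desk scale collapses to the majority class — every score lands on one side
of the 0.5 decision threshold, which both inflates and deflates
threshold-based metrics in misleading ways. Balanced weighting makes the
0.5 threshold meaningful and makes the no-signal (label-shuffled) control
behave like chance instead of like a constant predictor. Batch size
defaults to 16.

**Trials and the positive class.** NT (alone or together with PHT) is
scored as the positive class in every trial, so TPR reads as "fraction of
actual normotensive(+prehypertensive) samples recovered".

**Metrics.** Confusion counts at threshold 0.5; F1 on the positive class;
ROC by sweeping all distinct scores, trapezoidal AUC. The AUC equals the
Mann–Whitney U statistic of the scores (tested against pairwise
enumeration to 1e-9).

## Degenerate inputs and edge policies

- Constant signals: `normalize()` and `extract_bp()` reject them
  (degenerate signal / implausible waveform); a flat ABP segment drops the
  pair from labelling with a logged count.
- Monotonic signals: EMD returns zero IMFs and the input as residue;
  `denoise()` refuses an empty decomposition, and the pipeline falls back
  to the unreconstructed segment if every IMF is out of band.
- JNC7 boundaries: the printed table leaves 139–140 and 89–90 uncovered;
  the default rule closes them as ≥140 / ≥90 → HT per the guideline, with
  the literal printed bands available via `strict_table = TRUE`.
- SBP/DBP are segment extrema by default ("maximum values" reading);
  beat-wise averaging is available via `extract_bp(method = "beat_mean")`.
- Ties in ROC sweeps take scores in decreasing order with `>=`
  thresholding; pooling argmax ties take the first index, so everything is
  reproducible bit for bit under a fixed seed.

## Known limitations

- The synthetic cohort's class signal lives entirely in beat morphology;
  a real cohort's signal is weaker and confounded (age, medication,
  sensor site), so desk-scale accuracies here say nothing quantitative
  about clinical performance.
- The EEMD ensemble default (100) follows common practice, not a
  convergence analysis; the pipeline's desk-scale default (4) trades
  fidelity for runtime and is configurable.
- The layer engine is single-threaded R; it is sized for the compact
  backbone and AlexNet-scale forward passes, not for training the large
  backbones.
- GoogLeNet's 299 × 299 input path is not implemented; ResNet18/34 are
  counting/adaptation slots without a wired forward pass.
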