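---
title: "Seizure detection with a convolutional autoencoder and Bi-LSTM"
author: "deepeeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure detection with a convolutional autoencoder and Bi-LSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Epileptic seizures appear in scalp EEG as high-amplitude rhythmic
discharges against a lower-amplitude oscillatory background. `deepeeg`
classifies short multichannel EEG windows as ictal (in-seizure) or
interictal (between seizures) with a deep convolutional autoencoder
(DCAE) whose latent representation feeds a recurrent classification
head.

A recording is cut into non-overlapping windows of 1, 2 or 4 s. Each
window is a channels x samples plane (23 x 1024 for 4 s of 23-channel,
256-Hz EEG). The encoder alternates four 3x3 same-padded ReLU
convolutions (32, 32, 64, 64 filters) with four 2x2 max-pooling stages;
a 23 x 1024 plane shrinks to a 1 x 64 x 64 bottleneck. The decoder
mirrors this with nearest-neighbour up-sampling and convolutions of 64,
32, 32 and 1 filters (final sigmoid), reproducing the input shape
exactly. The bottleneck also feeds a classification head:

* **mlp** — flatten, dense(50, ReLU), dropout(0.75), softmax(2);
* **lstm** / **bilstm** — the bottleneck's reduced time axis becomes a
  sequence (64 steps of 64 features for a 4-s window); an (Bi-)LSTM with
  80 units per direction returns per-step outputs which are averaged
  over time, then dense(50, ReLU), dropout(0.75), softmax(2).

The `dcnn-mlp` baseline is the encoder plus MLP head without a decoder.
Training minimises `cross_entropy + lambda * reconstruction_MSE`
(`lambda = 1` by default) in a single joint phase, with Adam at learning
rate 1e-4, batch size 50 and 40 epochs as package defaults.

## Design choices in detail

Several aspects of this architecture family are conventionally left
open; the package fixes them as follows.

**Pooling arithmetic.** Spatial sizes are integer-halved at each pooling
stage (23 -> 11 -> 5 -> 2 -> 1 along the electrode axis of a 23-channel
input). The electrode axis clamps at one row: once collapsed, later
pooling stages pass it through unchanged, so recordings with fewer than
16 channels (for example the 8-channel synthetic benchmark) remain
usable. The time axis must survive four halvings, so windows need at
least 16 samples. The decoder undoes the floor losses by resizing each
stage to the encoder's recorded pre-pool shape rather than blindly
doubling.

**Kernel and pooling sizes.** 3x3 kernels, 2x2 pooling, stride 1,
same-padding: the minimal standard choice consistent with alternating
convolution/pooling stages on 2D planes.

**Bottleneck-to-sequence mapping.** The recurrent heads read the reduced
time axis as the sequence dimension (features per step = reduced height
x 64 feature maps). This preserves temporal ordering, which is the
point of using a recurrent head at all.

**Average pooling position.** A literal reading of the layer order would
place temporal average pooling *after* the fully connected layer; a
dense layer emits a vector per window, after which a temporal average is
ill-posed unless the dense layer is applied per time step. The default
(`avgPoolPosition = "before_dense"`) averages the recurrent outputs over
time and then applies the dense layer — the functional interpretation.
`"after_dense"` applies the dense layer per step and averages
afterwards, for the literal order.

**Dropout.** `dropoutRate = 0.75` is the probability of dropping a unit,
applied (inverted-dropout) to dense-layer inputs only, at training time
only.

**Batch size.** Both 50 and 10 appear in the sources this architecture
family derives from; the package defaults to 50, configurable.

**Normalisation and leakage.** The reference pipeline pools *all*
segments when fitting z-score and min-max parameters. Fitting on
everything leaks test statistics into training, so `crossValidate()`
defaults to fitting per-channel z-score and global min-max parameters on
each fold's training split and applying them to the held-out split with
clipping to [0, 1] (`normalization = "fold"`); `"pooled"` restores the
literal batch behaviour for comparability.

**Segment labeling.** A window is ictal only when entirely inside an
annotated seizure interval (half-open `[onset, offset)`, seconds from
record start) and interictal only when entirely outside all of them;
boundary-straddling windows are discarded. This avoids mixed-content
labels at seizure boundaries at the cost of a few windows per seizure.

**Class balancing.** The majority class is undersampled uniformly
without replacement to the minority count — never oversampled — so no
segment is duplicated.

**Metrics.** The positive class is ictal everywhere. Metrics are kept at
full precision internally; formatted tables round half-up to one
decimal. A metric whose denominator is zero is reported `NA`, never 0.
Headline cross-validation figures are unweighted means of per-fold
metrics; the pooled confusion matrix over all test folds is reported
alongside.

## The synthetic generator

No clinical recordings ship with the package; the generator provides
labeled data with the gross spectral structure of scalp EEG:

* **Background**: per-band FFT-filtered Gaussian noise with relative
  powers for delta (0.5-4 Hz), theta (4-8), alpha (8-13), beta (13-30)
  and gamma (30+), plus a weak 10-Hz sinusoid, mixed across channels by
  a random orthogonal matrix (channels share sources, as scalp channels
  do), scaled to 20 uV RMS — a typical scalp-EEG amplitude.
* **Ictal episodes**: amplitude-ramped spike-wave trains (3-Hz
  fundamental plus weaker second and third harmonics) added over a
  half-open interval, scaled so in-interval RMS is `ictalAmpGain`
  (default 5) times the background RMS, and annotated.
* **Artifacts**: EMG as 20-60 Hz band-limited noise on all channels;
  eye blinks as sparse 400-ms raised-cosine transients on frontal
  channels; white noise as i.i.d. Gaussian on all channels.

Everything is deterministic under the spec seed, with per-record
substreams derived by counter so cohorts reproduce independently of
generation order.

What the generator does *not* emulate: electrode geometry and volume
conduction, non-stationary background state changes (sleep stages,
medication), preictal dynamics, the enormous morphological variety of
real seizures, or recording dropouts. A model that separates this
synthetic data has demonstrated that the architecture, gradients and
pipeline work — not that it detects clinical seizures; clinical claims
require real annotated EEG read through the same `readEDF()` /
`parseAnnotationSummary()` path.

## The benchmark and problem sizes

The standard end-to-end benchmark (`makeBenchmarkSegments()`) is 400
balanced 4-s segments over 8 channels at gain 5, evaluated by 5-fold
cross-validation. The sizes were chosen so the full benchmark — a few
teraflops through the DCAE+Bi-LSTM across the five folds — runs in
minutes on a single CPU while still exercising every pipeline stage at
realistic segment dimensions (8 x 1024 planes).

`benchmarkTrainConfig()` trains it with Adam starting at learning rate
1e-3, halved every 3 epochs, for 8 epochs at batch size 50. The initial
rate is ten times the package default because a 320-segment training
split yields only ~50 optimisation steps over 8 epochs — two orders of
magnitude fewer than a full-corpus run — and the benchmark's
separability (the band-power logistic baseline, `bandPowerBaseline()`,
scores ~100%) makes aggressive rates safe; the step decay damps the
oscillation such a rate otherwise shows once converged.

## Numerical choices

* All arithmetic is double precision; convolutions run as im2col + BLAS
  GEMM, pooling/resizing/LSTM as dedicated C++ kernels, all verified
  against naive R reference implementations and finite differences.
* Cross-entropy clamps probabilities at 1e-7, so a zero-probability true
  class yields a large finite loss.
* Softmax subtracts the row maximum before exponentiation.
* Weights initialise uniform under the model seed with fan-in scaling:
  ±sqrt(6/fan-in) on ReLU layers (He scaling — without it the deep ReLU
  stack starts with vanishing activations and training stalls on a
  50%-accuracy plateau for several epochs) and ±sqrt(1/fan-in)
  elsewhere; LSTM forget-gate biases start at 1.
* Max-pooling ties resolve to the first (lowest-index) element; argmax
  classification ties resolve to the interictal class.
* z-scoring refuses channels with standard deviation below 1e-12 rather
  than dividing by ~0.
* EDF quantisation uses the ±1000 uV physical range by default, keeping
  the 16-bit step (~0.03 uV) far below signal amplitude.

## Known limitations

* Synthetic validation only, as discussed above.
* The encoder pools the electrode axis to a single row; no attempt is
  made to model spatial electrode adjacency (channel order is
  arbitrary from the convolution's point of view).
* EDF support covers continuous uniform-rate recordings; EDF+
  discontinuous records and TAL annotations are out of scope, as are
  montage re-referencing and non-integer resampling.
* Training is single-threaded CPU; the package aims at reproducibility
  and auditability rather than throughput.
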