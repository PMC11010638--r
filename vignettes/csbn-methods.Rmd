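---
title: "Methods: differential-entropy EEG features and the CSBN classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential-entropy EEG features and the CSBN classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(csbn)
```

## The problem

Music reliably evokes emotional states, and scalp EEG carries enough
signal to classify those states along Russell's two axes: **valence**
(pleasant vs. unpleasant) and **arousal** (activated vs. calm). Listeners
rate each musical trial on the 1–9 Self-Assessment Manikin (SAM) scale;
ratings are binarized at 5 and a classifier is trained to predict the
binary label from the EEG of each 2-second window. This package
implements that pipeline end to end: preprocessing, differential-entropy
(DE) features, the CSBN network (CNN → self-attention → BiLSTM →
softmax), and cross-validated experiment suites — together with a seeded
synthetic-EEG generator so every stage is testable without access to any
restricted recording dataset.

## Preprocessing

Raw multichannel recordings (the emulated acquisition used 128 electrodes
at 1024 Hz, 18–20 s musical trials) pass through:

1. **Broadband filter** — order-3 Butterworth band-pass, 1–45 Hz, applied
   forward and backward (`signal::filtfilt`). The zero-phase double pass
   squares the magnitude response and removes phase distortion that would
   otherwise shift band power across window boundaries. The paper-style
   description names only "a Butterworth filter of order 3"; zero-phase
   application is this package's choice.
2. **Downsampling to 128 Hz** — Fourier-domain resampling (spectrum
   truncated at the new Nyquist, then inverse-transformed). A polyphase
   implementation was evaluated and rejected: its edge transients visibly
   distorted short trials, while the FFT method reproduces in-band
   sinusoids essentially exactly.
3. **Baseline correction** — the per-channel mean over the first 2 s of
   stimulation is subtracted from the whole channel and the baseline
   window is then dropped. Whether the original procedure corrected in
   signal space or feature space is not documented; signal-space
   correction is the default here because it is the common EEG convention
   and commutes with the linear band filters.
4. **Segmentation** — non-overlapping 2-s windows (256 samples at
   128 Hz; a 128-channel recording yields 128 × 256 segments). Each
   window is multiplied by a Hann taper and rescaled by
   `1/sqrt(mean(w^2))` so stationary-noise power is preserved; whether
   the original "Hanning window" tapered the data or merely named the
   segmentation is ambiguous, so `taper = "none"` is available for
   sensitivity checks.
5. **Labels** — ratings below 5 map to 0, above 5 to 1. The boundary
   rating 5 maps to 1: the published rule covers only the strict
   inequalities, and assigning the boundary to the high class keeps the
   mapping monotone; the choice is recorded in the output metadata.

Trailing partial windows are discarded, and interactive ICA artifact
removal is represented by a pass-through hook (`remove_artifacts`), since
that step requires visual component inspection and is out of scope.

## Differential-entropy features

Each segment is decomposed into theta (4–8), alpha (8–13), beta (13–30)
and gamma (30–45 Hz) by order-3 zero-phase Butterworth filters. For a
Gaussian signal with variance $\sigma^2$ the differential entropy has the
closed form

$$h = \tfrac{1}{2}\log_2\!\left(2\pi e \sigma^2\right)\ \text{bits},$$

and the package computes one such value per channel per band from the
unbiased sample variance of the band-filtered window, assembling rows of
an $N \times (C \cdot B)$ matrix in band-major order (the layout is
written into the matrix metadata because no canonical ordering exists).
With 128 channels and 4 bands each row has 512 entries.

Two numerical choices matter:

* **Zero-mean assumption.** Band-passed EEG is zero-mean, so the
  mean-dependent correction term $L(\mu/\sigma)$ is identically zero. The
  symmetric two-Gaussian density whose entropy exceeds the Gaussian's by
  $L \in [0, \ln 2]$ is retained as a quadrature oracle
  (`mixture_de_numeric`) and the tests verify both the Gaussian reduction
  at $\mu = 0$ and the $\ln 2$ saturation — but it is never the feature.
* **Variance floor** of `1e-10` before the log, so constant (synthetic)
  channels produce a large negative feature instead of $-\infty$; floored
  entries are reported with a warning.

Base-2 logarithms (bits) are the default; natural log is available and
all internal comparisons are base-consistent.

## The CSBN network

The classifier is built from scratch in R matrix operations — no
deep-learning framework is involved — with analytically derived
backpropagation that the test suite verifies against central finite
differences for every variant.

**Convolutional stack.** The canonical stack for a 512-length feature
vector reproduces the recommended stage table exactly: seven 1-D
convolutions (32/32/64/64/128/128/64 filters), one max-pool and two
average-pools, batch normalization and spatial dropout after each block.
Kernel sizes are not part of the published table; they are derived as the
unique no-padding sizes reproducing the printed output lengths
(2, 6, 5, 6, 3, 2, then 3 with padding 1), and the final pool maps length
3 → 2 with a size-2 stride-1 window — the only parameterization
consistent with the printed shape. `shape_trace()` checks all of this
symbolically, and the tests pin every row.

**Multiplicative residuals.** Each convolution pair is wrapped in a
multiplicative residual: the block input passes through a linear 1×1
convolution `h` whose stride is the pair's cumulative stride, and the
output is the elementwise product `h(x) · F(x)`. Because the unpadded
main path can be slightly shorter than the strided skip path, the skip
output is truncated to the main path's length (left-aligned positions).
The number of residual wrappings (one per conv pair) is this package's
reading; the source text describes the mechanism but not the count.

**Self-attention.** The CNN output — 64 channels at 2 positions — is read
as a length-2 sequence of 64-dim features and passed through single-head
scaled dot-product attention, $A = \mathrm{softmax}(QK^\top/\sqrt{d_k})V$
with $d_k = d_v = 64$. The sequence axis is an interpretation: the
source describes a "one-dimensional vector" entering the attention/LSTM
stages, which cannot literally be a sequence; positions-as-sequence,
channels-as-features is the reading that preserves the printed shapes.

**BiLSTM.** Three bidirectional layers with 128, 64 and 64 hidden units.
Gates follow the standard equations (logistic gates on
$W\,[h_{t-1}, x_t] + b$, tanh candidate, $c_t = f_t c_{t-1} + i_t g_t$,
$h_t = o_t \tanh c_t$); the final feature is the concatenation of the
last layer's forward and backward final states (length 128).

**Variants.** `CNN` (stack → flatten → softmax), `BiLSTM` (input reshaped
to 64-dim steps when the length divides by 64, otherwise band-major
band-count steps), `CNN-BiLSTM` (full model minus attention), and `CSBN`
(the full model). A 2-class softmax head closes every variant.

**Reduced stacks.** Feature vectors shorter than 512 (fewer channels, or
a band subset selected by `select_bands`) cannot support the canonical
kernels. `model_spec()` then builds a reduced stack by the same pattern —
conv pairs with the 32/64/128 filter progression and pooling while the
length budget allows, then a 64-filter convolution to length 2 — so the
attention and BiLSTM stages always see the same length-2, 64-dim
sequence. The construction is deterministic in the input length and the
resulting trace prints with the spec.

**Initialization and hyperparameters.** Glorot-uniform initialization
from a seeded generator; spatial dropout rate 0.3; batch-norm momentum
0.1 and epsilon 1e-5 — all unstated in the source and fixed here as
configuration. Training uses Adam (lr 1e-3, betas 0.9/0.999, batch 64)
on the categorical cross-entropy; the published account names only the
optimizer and loss, with 100 epochs as the default horizon.

## Evaluation

Stratified segment-level 10-fold cross-validation, each fold's model
re-initialized from a seed derived from (config seed, fold index).
Whether the original splits were subject-independent is not documented;
segment-level pooling matches the reported setup style, and a grouped
splitter (`groups =` trial ids) is provided because pooled splits let
windows of one trial straddle the train/test boundary — pooled accuracies
should not be read as cross-subject generalization. Metrics: accuracy,
positive-class precision and F1 from argmax predictions, and rank-based
(Mann–Whitney) AUC from the positive-class probability; macro averaging
is deliberately not silently substituted. Folds aggregate as mean and
max.

`run_ablation_suite()` crosses the four variants with both tasks;
`run_band_suite()` restricts the DE matrix to band subsets (4 singletons,
6 pairs, 4 triples) and rebuilds the model spec for each reduced input
length.

## The synthetic-data generator

Each channel is unit-RMS $1/f$ Gaussian background noise (spectral
shaping; exponent 1, configurable) plus narrowband components per band —
band-pass-filtered white noise normalized to the profile's amplitude —
scaled by a small per-channel gain ($1 + 0.05\,\mathcal N(0,1)$).
Filtered noise rather than sinusoids keeps the per-window variance (and
hence the DE features) fluctuating as real EEG does. Per-trial ratings
are drawn from $\mathcal N(\text{mean}, \text{sd})$ and clipped to
[1, 9], with the four default class profiles using the stimulus-study
statistics: fear 3.03 ± 0.29 / 7.12 ± 0.28, happy 6.98 ± 0.30 /
7.02 ± 0.28, calm 5.85 ± 0.22 / 3.56 ± 0.27, sad 3.55 ± 0.29 /
2.86 ± 0.45 (valence/arousal).

Band-power signatures are **alpha-dominant by construction**: the default
profiles differ only in alpha amplitude (1, 2, 4, 8 for fear, happy,
calm, sad) with equal unit amplitudes in the other bands — consistent
with the observation that musical stimulation is most visible in the
alpha band. No quantitative per-class band-power statistics are
published, so these amplitudes are free generator parameters chosen once,
not estimates. One consequence worth knowing: a strong alpha component
bleeds a few percent of its power into the neighbouring band estimates
through the order-3 Butterworth roll-off (about 4.7% into beta, 2% into
theta), so in the band-subset experiments the non-alpha bands remain
weakly informative about class even though no class contrast was placed
in them — as in real EEG, band features are not spectrally independent. Randomness is counter-based: every (seed, class, trial,
channel, component) tuple maps to its own substream, so a dataset is
byte-reproducible and trials are independent.

What the generator deliberately does **not** emulate: ocular/muscular
artifacts, volume conduction, electrode geometry, nonstationarity within
a trial, or any subject-level variability. Passing the recovery tests
therefore demonstrates that the pipeline's arithmetic and learning
machinery work — not that the published accuracies would reproduce on
real EEG.

## Problem sizes used by the packaged experiments

The test and acceptance runs use the generator at a reduced scale chosen
once for the package: 8 channels at 128 Hz (generated directly at the
post-downsampling rate), 10-s trials, 25 trials per class — after
baseline removal, exactly 100 two-second segments per class (400 total,
32 features). Suites train with Adam for 12 epochs at batch 64, enough
for the loss to plateau on this task (convergence is reached around
epoch 8), under full 10-fold cross-validation. On these conditions the
full model's cross-validated mean accuracy exceeds 0.9 on both axes,
every ablation variant clears 0.6, and alpha is the strongest single
band — the package's headline functional checks. Full-size generation
(128 channels, 1024 Hz, 20-s trials) is a constructor argument away and
exercises the canonical 512-input architecture.

## Known limitations

* The mean-correction term of the DE (the two-Gaussian mixture density)
  contradicts the Gaussian assumption under which the closed form is
  exact; this package computes the Gaussian form and keeps the mixture
  only as an oracle. Which of the two the original feature pipeline used
  is not determinable from the text.
* The attention stage sees a sequence of length 2; its weights are
  well-defined but the "global context" it can model is limited — that is
  a property of the published architecture shapes, not of this
  implementation.
* Training is single-threaded, deterministic R; it is engineered for the
  package's experiment scales (hundreds of segments, tens of epochs),
  not for GPU-scale workloads.
* Pooled (segment-level) cross-validation optimistically estimates
  generalization across trials and subjects; use the grouped splitter
  for leakage-free estimates.
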