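---
title: "Channel-partitioned multi-scale spatial-channel attention for EEG seizure detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-partitioned multi-scale spatial-channel attention for EEG seizure detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprsca)
```

## The problem

Epileptic seizures appear in scalp EEG as abnormal high-amplitude rhythmic
discharges — classically spike-and-wave complexes near 3 Hz — against ongoing
background activity. Window-level seizure detection casts this as binary
classification: a recording is cut into short fixed-length windows
(here 3 s at 256 Hz), each labeled ictal (inside a seizure) or interictal
(between seizures), and a classifier maps each multichannel window to one of
the two classes. `cprsca` implements this pipeline end to end: EDF input,
standard preprocessing, a residual convolutional classifier built around the
CPRSCA attention mechanism, and the two evaluation protocols the field uses
(within-patient splits and leave-one-subject-out), plus a synthetic
spike-and-wave generator so everything runs reproducibly with no external
data.

## The CPRSCA mechanism

A window enters the network as a single-plane feature map of shape
(1 × electrodes × time); deeper in the network an activation tensor has C
channels, height H (electrode rows) and width W (time). The CPRSCA block
combines three ingredients.

**Channel-partitioned resolution module (CPRM).** The C channels are split
into N mutually exclusive contiguous subsets (N = 4 by default). Subset *i*
is filtered by a 2-D *depthwise separable* convolution — one k×k spatial
filter per channel, then a 1×1 cross-channel mix — with kernel size
k = 2i + 1, i.e. 3, 5, 7, 9: early subsets see local detail, later subsets
broad context, at a parameter cost of C·k² + C² instead of a standard
convolution's C²·k². The filtered subsets are concatenated back to C
channels, group-normalized (per sample, over fixed channel groups), and
passed through a softmax **across channels**, producing a channel-attention
descriptor M whose entries are positive and sum to 1 over channels at every
position.

**Coordinate attention (CA).** M is average-pooled along each spatial axis
separately, giving per-channel profiles over height (C × H) and width
(C × W). These are concatenated along the spatial axis, compressed by a
shared 1×1 transform to `ceiling(C/r)` channels (reduction ratio r, default
16 at full scale; a floor of one unit), passed through ReLU, split back, and
expanded by per-axis 1×1 transforms followed by sigmoids. The result is a
pair of positional gates `gh` (C × H) and `gw` (C × W) in \[0, 1\].

**Squeeze-and-excitation (SE).** Global average pooling per channel
(squeeze) feeds a bottleneck fully connected pair with ReLU and sigmoid
(excitation), yielding channel weights `S` in \[0, 1\].

**Composition.** The block computes

```
M  = CPRM(x)
A  = x ⊙ gh(M) ⊙ gw(M)      (coordinate gates broadcast over the other axis)
out = A ⊙ S(A)              (channel weights broadcast over space)
```

How the three stages share data was a genuinely open design choice: the
CPRM softmax map M has entries of magnitude ~1/C, so letting it carry the
main signal would shrink activations with depth. The composition above
therefore treats M purely as a *descriptor* — the gates are computed from
it but modulate the block input — and SE recalibrates the gated map. This
keeps the softmax's 1/C magnitude out of the signal path while the
multi-scale information still steers both gate pairs. Because all gates lie
in \[0, 1\], the block's output never exceeds its input entrywise — a
property the tests assert.

Two related choices are fixed in the same spirit: the CPRM normalizer is a
softmax across channels (a sigmoid would normalize nothing across channels
and lose the distribution property the invariants rely on); and when the CA
stage is ablated the CPRM map modulates `x` directly as `x ⊙ (C·M)` — the
factor C makes the mean gate 1, so the map acts as a relative
spatial-channel weight rather than a uniform attenuator.

## The backbone

The classifier is a ResNet-34-style network adapted to (1 × electrodes ×
time) inputs: a (1, 5) stride-(1, 2) stem convolution to the first stage
width, group norm, ReLU and (1, 3)/(1, 2) max pooling; four stages of basic
blocks (depths 3, 4, 6, 3 and widths 64–512 by default) whose convolutions
are (1, 3), so only the time axis is ever downsampled; one CPRSCA block
inside every residual block, applied to the second convolution's output
before the skip addition (the placement convention of SE-ResNets); global
average pooling and a 2-class linear head. Normalization throughout is group
normalization, which is independent of batch composition — appropriate for
the batch size of 4 used in training. Odd time lengths under stride 2 are
handled by zero same-padding with floor division.

The forward and backward passes are implemented in the package itself —
grouped convolutions via im2col + BLAS in compiled code, everything else as
vectorized R — keeping the dependency surface small and every numerical
step inspectable; each hand-derived gradient is verified against central
finite differences in the test suite. Architectures are pure
functions of (config, seed); checkpoints store every parameter array with
the config, its hash, and the seed, and round-trip bit-exactly.

## Preprocessing

The EDF reader handles standard 16-bit EDF with per-channel physical
scaling; seizure intervals arrive as a sidecar table (file, onset_s,
offset_s), are validated, sorted, and merged when overlapping. The chain
then follows the field's convention: select a fixed ordered channel set
(the 18 CHB-MIT bipolar derivations) or derive a bipolar montage (the 12
standard pairs from 15 monopolar 10-20 electrodes), resample to 256 Hz with
a polyphase anti-aliased FIR (`signal::resample`), cut non-overlapping 3 s
windows, and label each window ictal only if it lies entirely inside a
seizure interval and interictal only if it clears every interval by a guard
margin (default 60 s); boundary and peri-ictal windows are discarded so both
classes stay pure. Interictal windows are then undersampled per subject to a
1:1 class ratio (seeded). Signals stay in microvolts; no amplitude
normalization is applied.

Window overlap, the guard width, and the class ratio are conventions rather
than constants of the task; non-overlapping windows, 60 s, and 1:1 are the
package defaults (all configurable), the last motivated by the
near-symmetric sensitivity and specificity this task typically exhibits
when classes are balanced.

## The synthetic cohort

The generator emulates a small hospital-style acquisition so that the full
pipeline — including the resampling step — always runs: 15 monopolar
electrodes at 500 Hz, five subjects, 900 s each, three seizures of 30–50 s
per subject. Background activity is 1/f^β-coloured noise (β = 1) plus an
alpha-band sinusoid, linearly mixed across electrodes and scaled to a 50 µV
RMS. Ictal segments superimpose a periodic spike-and-wave train (sharp
biphasic spike plus a dominant half-sine slow wave per cycle, 3 Hz) at an
ictal-to-background amplitude ratio of 3, spliced in with 0.5 s cross-fades
and exact ground-truth annotations. The discharge carries a scalp topography
with per-electrode gains of varying magnitude and random polarity — as
generalized spike-wave fields invert across the head — which matters
mechanically: a spatially uniform train would largely cancel under the
bipolar montage. Subjects differ in amplitude, spectral slope, alpha
frequency, and mixing, drawn deterministically from a master seed; every
output is a pure function of its seeds.

What the generator does *not* emulate: artifacts (eye blink, EMG, electrode
pops), focal seizures with localized onset and evolution, inter-channel
propagation delays, or non-stationary background. Passing tests on this
cohort therefore demonstrate that the implementation is correct and that the
training and evaluation machinery works — not that the model reaches any
particular accuracy on clinical recordings.

## Training and evaluation

Training minimizes softmax cross-entropy with AdamW (decoupled weight decay
0.01, betas 0.9/0.999), batch size 4, base learning rate 5e-4 under a linear
warm-up over the first 5% of steps followed by cosine decay to zero; the exact
warm-up span and decay shape are package choices within the standard
warm-up-then-decay family. Runs are reproducible: shuffling and
initialization derive from explicit seeds, and the recorded learning-rate
trace is asserted against the schedule's closed form in the tests.

Two protocols are implemented. **Patient-dependent:** each subject's windows
are split 4:1 within subject, stratified by label (test side
`round(n/5)` per class with a floor of one window); one shared model is
trained on the union of all subjects' training windows and evaluated per
subject on the held-out fifth. The shared model follows the usual reading of
"patient-dependent" in this literature — the contrasting protocol is
described as keeping patient identities *strictly separated*, which implies
the dependent setting mixes them — and it is also the reading that scales:
per-subject models trained on a few dozen windows are optimization-starved
at desk scale, which would invert the expected ordering between the
protocols for reasons that have nothing to do with subject variability.
**Leave-one-subject-out (LOSO):** one fold per subject, trained from a fresh
fold-seeded initialization on all other subjects, tested on the held-out
subject; plans are asserted to have full coverage and zero subject leakage.

Metrics are accuracy, sensitivity, F1 (2TP/(2TP+FP+FN)) and specificity from
the window-level confusion counts; predictions are the argmax of the two
logits with ties resolved to the negative class. Ratios with zero
denominators are flagged undefined rather than coerced to zero, and
per-subject aggregation (unweighted mean ± population standard deviation)
excludes flagged entries while reporting how many were excluded.

## Problem sizes and numerical choices

The desk-scale experiments in the tests and the acceptance script use a
tiny configuration — one block per stage, widths 8/16/32/64, reduction
ratio 4 — trained 5 epochs on the ~400-window synthetic cohort; at these
sizes the full pair of protocols runs in a few minutes on one CPU. Numerical
safety: the channel softmax subtracts the per-position maximum; group
normalization uses population variance with eps = 1e-5; group count equals
the number of CPRM subsets (4), aligning normalization groups with
resolution subsets; weights are fan-in-scaled zero-mean normals, biases
zero, convolutions bias-free (normalization follows them). EDF quantization
is 16-bit with per-channel ranges, so write/read round-trips are exact to
one digital step.

## Limitations

The network trains on CPU at desk scale only; reproducing full-scale
clinical results would require the original recordings and GPU-scale
training of the 34-layer configuration, which is outside this package's
test surface. The EDF reader supports the common single-rate 16-bit layout
(not EDF+ annotations, which are replaced by the sidecar table). The
synthetic cohort's idealizations listed above mean measured accuracies here
say nothing quantitative about clinical data. Event-level evaluation
(detection latency, false alarms per hour) is deliberately out of scope;
all metrics are window-level.
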