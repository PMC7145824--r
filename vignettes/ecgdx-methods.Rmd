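---
title: "Methods: synthetic ECGs, weak-supervision labels, and the 1D residual network"
author: "ecgdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ECGs, weak-supervision labels, and the 1D residual network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgdx)
```

# Overview

`ecgdx` implements an end-to-end system for classifying six abnormalities in
short (7–10 s) standard 12-lead ECGs: first-degree AV block (1dAVb), right and
left bundle branch block (RBBB, LBBB), sinus bradycardia (SB), atrial
fibrillation (AF) and sinus tachycardia (ST) — always in that canonical order.
The pipeline has five stages: a synthetic 12-lead ECG generator with ground
truth; container I/O and preprocessing; a weak-supervision label-construction
engine for free-text reports and heterogeneous annotations; a unidimensional
pre-activation residual network with its training loop; and a multi-label
evaluation suite. This vignette documents the models, the tunable parameters,
the numerical choices, and the limits of what the synthetic experiments can
show.

# The synthetic 12-lead ECG generator

Clinical ECG archives are not redistributable, so every downstream stage is
exercised against a generator whose records carry their own ground truth.

**Beat model.** A heartbeat is a sum of five Gaussian bumps (P, Q, R, S, T),
projected onto the 12 leads through a fixed weight matrix with a plausible
normal axis (dominant R in II and V5–V6, rS in V1, negative aVR). The timing
convention ties the parameters to their clinical definitions:

* the QRS complex occupies `[-d/2, +d/2]` around the R centre, where `d` is
  the QRS duration: the Q and S bumps sit at `∓0.3 d` with sd `d/10`, so
  their 2-sd support edges fall exactly on the QRS onset/offset;
* the P-wave onset (centre minus two P sds, sd 25 ms) precedes the QRS onset
  by exactly the PR interval;
* the T-wave centre scales with the RR interval (`0.42 × RR`, clamped to
  200–330 ms), a coarse analogue of rate-dependent QT shortening that keeps
  the preceding T wave from invading the P-wave region at fast rates.

Amplitudes are nominal (R ≈ 1 mV in lead II, P 0.15 mV, T 0.3 mV); the source
material gives no device amplitude statistics, so these are round mid-range
values. Noise defaults to additive Gaussian (sd 0.02 mV) plus a 0.33 Hz
baseline-wander sinusoid (0.05 mV); both are configurable and `noiseFree()`
disables them for measurement-closure tests.

**Rhythm model.** Sinus rhythm draws RR intervals from a Gaussian around
60/HR with a 30 ms jitter sd. AF draws log-normal RR intervals (mean 60/HR,
log-sd 0.25, giving an RR sd of roughly 0.25 × RR ≈ 130–200 ms) and removes
the P wave. Draws are truncated to [0.25, 2.5] s and accumulated until the
record duration is covered.

**Flag-to-parameter mapping.** SB draws HR in (35, 48) bpm and ST in
(103, 123), respecting the clinical 50/100 bpm boundaries with a margin wider
than the ±2 bpm measurement tolerance; the ST upper bound keeps the P wave
separable from the preceding T wave, which is also why ST records draw a
slightly short PR (125–160 ms, consistent with sympathetic-tone PR
shortening). 1dAVb draws PR above a configurable prolonged-PR cutoff
(default 200 ms, drawn in cutoff + 15 … + 85) and restricts HR to (55, 80)
so the long P wave stays clear of the preceding T wave. RBBB/LBBB draw QRS in
(125, 150) ms and override the V1/V6 projections to give the characteristic
opposite polarities (RBBB: tall V1 R′, deep wide V6 S; LBBB: V1 QS, broad
positive V6 R). Rhythm classes are mutually exclusive by construction, as are
RBBB/LBBB; 1dAVb is suppressed on AF records because a PR interval requires
P waves. Conduction flags otherwise co-occur freely with rhythm flags.

The generator's SDNN is whatever the drawn RR sequence produces (~130–200 ms
for AF); it makes no attempt to exceed the harmonization engine's AF
threshold default of 646, whose unit the source material leaves unstated —
that threshold is plainly configurable and the tests exercise the rule with
explicit values.

**Prevalences.** `defaultPrevalences()` reproduces the study population
rates (1.5/2.7/1.7/1.6/1.8/2.1%); `balancedPrevalences()` (15–20% per class)
is used for training experiments so a few thousand records contain hundreds
of positives per class.

# Preprocessing and the measurement oracle

Records are resampled to 400 Hz and zero-padded to 4096 samples per lead —
the single fixed network input shape. Padding is at the end by default
(configurable to symmetric); records longer than the target are rejected
rather than silently cropped, since the source pipeline never produces them.

Resampling is zero-phase band-limited interpolation: an 8th-order
forward-backward Butterworth low-pass at 0.9× the new Nyquist frequency when
downsampling, then Hann-windowed sinc interpolation (half-width 16 input
samples) on the new grid. A causal polyphase implementation was rejected
because its uncompensated anti-aliasing group delay shifts the waveform by
several samples, which is fatal to interval measurements downstream.

The measurement oracle is a minimal stand-in for a commercial analysis
program, sufficient for rule evaluation and simulator closure:

* **R peaks**: 5–25 Hz zero-phase band-pass on lead II, local maxima of the
  absolute filtered signal above 0.4× its 99.5th percentile, a 200 ms
  refractory period (strongest peak wins), and refinement to the raw-signal
  extremum. Offsets are removed by the band-pass, so detections are invariant
  to constant shifts.
* **Heart rate / SDNN**: 60 / mean RR and the sample sd of the NN intervals,
  reported in ms (the unit scale is a parameter).
* **PR / QRS**: computed on a per-sample median beat across all complete
  beats (window ±min(380, RR/2)/(450, RR/2) ms around each R peak), with the
  baseline estimated as the mode of the beat's amplitude distribution —
  robust, unlike the mean or median, when waves occupy much of the window at
  fast rates. QRS support is the contiguous region around R where the
  absolute beat exceeds a 0.02 mV floor (gaps ≤ 12 ms bridged, search limited
  to ±160 ms). The P wave is the largest interior local maximum in a
  pre-QRS window that is prominent (≥ 0.06 mV above its surrounding troughs),
  narrow (full width at half maximum ≤ 120 ms) and consistent across beats
  (inter-beat IQR at the peak ≤ 0.06 mV) — the consistency requirement is
  what rejects the smeared bumps that irregular AF rhythms leave in a median
  beat. The P onset walks left from the peak until the signal drops below
  the floor or turns back up, bounded by a width-based estimate (2 sd ≈ 1.7×
  the half-width at half maximum) that guards against contamination by the
  preceding T-wave tail.

On noise-free synthetic records the oracle recovers heart rate within
±2 bpm and PR/QRS within ±10 ms across classes, durations and sampling rates
(300–600 Hz); this closure is asserted in the test suite. These tolerances
are claims about the generator's idealized morphology, not about clinical
ECGs: real P waves can be biphasic, notched or buried in noise, and the
oracle makes no claim to delineation-research quality.

**Splits.** `splitDataset()` provides the three 90/5/5 strategies: random,
by patient (a patient's records never straddle parts) and chronological
(order-preserving by acquisition date).

# The weak-supervision label pipeline

Training labels come from free-text cardiologist reports plus two automatic
annotation sources, harmonized with measurement-based rules.

**Text step.** Reports are lower-cased, punctuation-stripped and tokenized;
stop-words are removed before n-grams (default order 2) are formed. A lazy
associative classifier stores the (feature set, class) dictionary and, at
query time, mines association rules `antecedent → class` restricted to the
query's own features (antecedents up to 3 items, default minimum support
0.01 and confidence 0.5), scoring classes by mean rule confidence. A
rule-based disambiguation step keeps classes above a 0.6 confidence
threshold, resolves the mutually exclusive rhythm classes to the
highest-confidence one, and suppresses classes whose trigger phrases appear
within three (stop-word-free) tokens of a negation cue ("sem", "ausência"…).
The dictionary composition and disambiguation rules of the original system
are not public; the package's phrase templates and rules are documented
stand-ins, and the synthetic report generator exists purely to exercise this
machinery.

**Harmonization.** Each exam carries an expert label vector, two
automatic-classifier vectors and a measurement set. Decisions are per class:

1. *Agreement*: accept when the expert and at least one automatic source
   agree; reject when a single automatic source claims an abnormality against
   both the expert and the other source. A class no source claims is absent.
2. *Measurement rejections* (strict comparisons, on claims still undecided):
   ST with HR < 100 bpm; SB with HR > 50; RBBB/LBBB with QRS < 115 ms;
   1dAVb with PR < 190 ms. Missing measurements leave a rule silent —
   rejecting on absent evidence would be anti-conservative.
3. *Remaining acceptances*: expert-positive RBBB, 1dAVb, SB and ST are
   accepted; expert-positive AF additionally requires SDNN > 646 (threshold
   configurable, unit deliberately unasserted). LBBB is intentionally not in
   this list.

Anything still undecided lands in the manual-review queue with its firing
rule recorded. Boundary semantics are the literal reading of the rules:
"below 100" means strictly `<`, so HR exactly 100 survives; likewise 50,
115, 190 are survivors and 646 is the largest non-accepted SDNN. The
engine's decisions flip exactly once along each measurement sweep, which the
tests assert grid point by grid point.

# The residual network

The classifier is a unidimensional residual network: an initial convolution
(kernel 16, 64 filters) on the 4096 × 12 input, four pre-activation residual
blocks, and a sigmoid head (classes are not mutually exclusive, so outputs
are independent probabilities rather than a softmax).

Each block is BN → ReLU → Dropout → Conv, twice; the second convolution
carries the stride-4 subsampling, so the temporal length after block *k* is
4096/4^k (16 before the head). The skip path max-pools by 4 and, when the
channel count changes, passes through a kernel-length-1 convolution. The
filter counts follow "64 more every second block", read literally as
(64, 64, 128, 128); the reading (64, 128, 128, 192) is equally grammatical,
so the schedule is an explicit configuration vector and swapping it is one
line. Convolutions are same-length zero-padded; weights are He-normal,
biases zero, BN scale/shift 1/0. Dropout defaults to 0.8 (the upper entry of
the original tuning menu), configurable per run.

There is no deep-learning framework in this stack, so the forward and
backward passes are implemented in the package: im2col + GEMM convolutions
(chunked over the batch), fused BN+ReLU, and max-pooling as RcppArmadillo
kernels computing in single precision with double accumulators for BN
statistics and gradient reductions; dense head, dropout masks, Adam and the
training loop in R. Analytic gradients are verified against central finite
differences in the test suite (correlation > 0.999, median relative error
< 2%, the residual disagreement being single-precision forward noise).

**Training.** Adam (default moments) at learning rate 0.001 minimizes the
average binary cross-entropy (predictions clipped at 1e-7); the rate is
divided by 10 after exactly seven consecutive epochs without a strictly
lower validation loss; training runs at most 50 epochs and the final model
is the checkpoint with the best validation loss. "Improvement" has no
minimum delta, and checkpoint selection equals the argmin of the recorded
history by construction. Shuffling and dropout draw from the seeded R RNG,
so single-threaded runs are bit-reproducible.

# Evaluation suite

A record is predicted positive when its score is ≥ the threshold. The
precision–recall curve has one point per distinct score; average precision
uses the step-wise rectangle convention (no interpolation), walking
thresholds from high to low; "micro" average precision flattens the
record × class pairs (a per-class macro variant sits behind a flag). The
operating threshold per class is the one maximizing F1 over all distinct
cut-points, ties broken upward; equality with exhaustive search is asserted
on every test input. Ratios with empty denominators are reported missing,
never zero. Bootstrap intervals resample records with replacement at full
size (default 1000 resamples, seeded); resamples where a metric is undefined
are excluded from that metric's percentiles and counted. The McNemar
statistic is (b−c)²/(b+c) on the discordant error counts, with a
continuity-corrected variant and an exact two-sided binomial fallback used
automatically when b+c < 25; Cohen's kappa comes from the 2×2 agreement
table with κ = 1 when both raters are constant and identical. A helper
implements the published model-selection rule: among several training runs,
pick the one whose micro average precision is immediately above the median.

# The desk-scale label-recovery experiment

The full-scale study trained on millions of records; the package's
end-to-end check is deliberately desk-scale: a scaled-down network (2
residual blocks, 16 initial filters, dropout 0 — the small network on an
easy task needs no regularization) trained for 6 epochs (batch 64, learning
rate 0.001) on 4000 synthetic records at balanced prevalences (90% train /
10% validation for checkpointing), then evaluated on 500 independently
generated records against the generator's ground truth with per-class
F1-maximizing thresholds. The acceptance test requires macro-F1 ≥ 0.90.
First-degree AV block is reliably the hardest class — it hinges on a
~40 ms PR difference, the same borderline-measurement failure mode the
full-scale study reports for its network's errors.

Passing shows that the architecture, gradients, optimizer and data plumbing
can jointly learn rate, rhythm-irregularity, QRS-width and PR-interval
features from raw signal. It does not show clinical performance: the
synthetic records have clean, class-separable morphology, no pathological
co-occurrence structure, no electrode noise beyond Gaussian + wander, and
balanced prevalences far from the ~2% clinical rates.

# Known limitations

* The beat model is five Gaussians; it cannot represent notched QRS,
  biphasic P, ST-segment shifts or f-waves, so classes are separable by
  construction.
* The measurement oracle is tuned for that morphology; its closure
  tolerances do not transfer to clinical ECGs.
* The AF SDNN acceptance threshold (646) is carried with its unit unstated,
  as in the source material; the generator makes no attempt to reach it.
* The LAC dictionary and disambiguation rules are stand-ins; the published
  text-extraction F1 scores cannot be reproduced without the private labeled
  reports.
* Training determinism is guaranteed single-threaded; multi-threaded BLAS
  may reorder reductions.
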