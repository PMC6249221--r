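---
title: "Methods: shockable-rhythm detection with pinned-mode decomposition and deep features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shockable-rhythm detection with pinned-mode decomposition and deep features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An automated external defibrillator must decide, from a few seconds of
single-channel ECG, whether the heart is in a shockable rhythm —
ventricular fibrillation (VF) or rapid ventricular tachycardia (VT) — and
only then deliver a countershock. The cost structure is asymmetric: a
missed shockable rhythm delays a life-saving defibrillation, while a false
alarm delivers a shock to a beating heart and can itself induce arrest.
Performance is therefore reported as sensitivity (Se, shockable class),
specificity (Sp, non-shockable class), accuracy (Ac) and the balanced
error rate

$$\mathrm{BER} = 100 - \frac{Se + Sp}{2} \quad \text{(percent scale)},$$

with the shockable class as positive. `shockadvice` implements the full
decision pipeline on non-overlapping 8-s segments sampled at 250 Hz:
preprocessing, channel construction by mode decomposition, deep-feature
extraction with a 1-D CNN, and secondary classification, together with the
record-wise cross-validation machinery used to select and validate the
model.

## Preprocessing

Three stages, in order:

1. a **5-tap centered moving average** (uniform FIR) for smoothing. We read
   "fifth-order moving average" as the 5-point window; applied centered so
   it adds no group delay.
2. a **1 Hz high-pass** removing drift and baseline wander. The filter type
   is not fixed by the design, so we match the stated low-pass and use a
   5th-order Butterworth.
3. a **30 Hz low-pass Butterworth** (order 5) suppressing mains and muscle
   interference.

Both Butterworth stages are zero-phase (forward–backward, i.e. the squared
magnitude response), so QRS morphology is not skewed. Numerically the
zero-phase stages are applied spectrally: the segment is mirror-extended
(making it periodic and continuous), its FFT is multiplied by
$|H_{hp}|^2 |H_{lp}|^2$, and the result is cropped back. This is the exact
forward–backward response without the start-up transients a direct
zero-initial-condition `filtfilt` produces at segment edges — on an 8-s
constant segment the output is zero to machine precision, and a 10 Hz
passband tone retains about 94% of its RMS (the moving average accounts
for the mild loss). Filtering is applied per segment, matching the
segment-wise definition of the preprocessed ECG (pECG); full-record
filtering would differ only near segment boundaries.

Segments are labeled by their **dominant annotated rhythm** (the rhythm
covering most samples in the window), with ties broken toward the
shockable class — the safety-conservative choice. Exclusion rules mirror
the annotation protocol: noise/artifact, asystole and transition windows
are dropped; VT below 150 beats/min (estimated by rectified-peak detection
with a 150 ms refractory period) and VF below 200 µV peak-to-peak carry no
defibrillation benefit and are likewise removed.

## Channel construction by pinned-mode decomposition

VF/VT activity concentrates its spectrum around 4 Hz and falls off sharply
above 10 Hz, whereas the QRS complexes of organized rhythms peak between 4
and 20 Hz. The pipeline exploits this by decomposing each pECG into
$K = 10$ narrow-band modes with variational mode decomposition (VMD),
**pinning** six center frequencies for the entire run: a DC mode at 0 Hz
and five shockable-band centers at 2, 3.5, 5, 6.5 and 8 Hz. The remaining
four centers are free and, driven by the usual power-weighted-mean update,
settle above 10 Hz on ECG-like input (we observe this in 50/50 seeded
synthetic non-shockable segments).

The implementation is the standard frequency-domain VMD ADMM — Wiener-
filter mode updates
$\hat u_k \leftarrow (\hat f - \sum_{i \ne k}\hat u_i - \hat\lambda/2) /
(1 + \alpha(\omega - \omega_k)^2)$,
center updates by the spectral centroid of $|\hat u_k|^2$, and dual ascent
$\hat\lambda \leftarrow \hat\lambda + \tau(\sum_k \hat u_k - \hat f)$ —
with the single modification that pinned $\omega_k$ are never updated
(they are bit-identical to their targets at every iteration). Defaults are
the conventional VMD settings: bandwidth penalty $\alpha = 2000$, dual
step $\tau = 0.1$, tolerance $10^{-6}$, at most 500 iterations. Since the
source design gives no VMD internals, these are exposed in
`mvmd_params()`. Numerical choices:

* the signal is mirror-extended before the FFT and cropped afterwards,
  halving boundary leakage;
* the per-iteration change is measured relative to **total signal energy**
  rather than per-mode energy, so near-empty modes (common when four free
  modes share little high-frequency power) cannot stall convergence;
* free centers are initialized uniformly over (10 Hz, 0.8 × Nyquist),
  consistent with where they end up and away from the pinned set;
* zero-energy input returns all-zero modes with untouched centers;
  non-convergence returns the best iterate with a warning flag.

The **SH signal** is the sum of the five modes pinned above 0 Hz, the
**NSH signal** the sum of the four free modes; the DC mode is discarded.
pECG, SH and NSH form the three aligned CNN input channels. On a 3 Hz +
15 Hz two-tone segment the two sides correlate with their tones at > 0.99,
and the full mode sum reconstructs the input to well under 5% relative
error.

## The CNN family and deep features

The network family is parameterized by five selection parameters: sections
`Ns`, blocks per section `Nd` (structure), and learning rate `Lr`,
momentum `Mo`, regularization `Re` (learning). A block is one convolution
(kernel 101, stride 1, padding 50 — length-preserving) followed by ReLU;
section $s$ uses $10 \cdot 2^{s-1}$ filters (the only schedule consistent
with the published 10/20/40 layer table) and ends in max pooling (kernel
11, stride 2, floor division). Note the accompanying prose defines a block
as *two* convolutions; the published layer table of the selected model
(`Ns = 3, Nd = 1`) lists one convolution per section, and we follow the
table. After the last pool the activations are flattened — for the
selected model $242 \times 40 = 9680$ values — into a fully connected
layer of 100 outputs, then ReLU, dropout, and a final 2-output softmax.

`Re` is interpreted as the dropout probability on the first FC layer: the
design's gloss (preventing reliance on any one neuron) describes dropout,
and the candidate values (0.1–0.2) are typical dropout rates. Training is
plain SGD with momentum (`v ← Mo·v − Lr·g`), cross-entropy loss, He
initialization, epochs 40 and batch 32 by default (both unstated in the
source design and fully configurable); all randomness is seeded, so runs
are bit-reproducible. A non-finite loss aborts with a diagnostic rather
than silently saturating. The engine (im2col + GEMM convolutions with
exact backpropagation, in compiled code) is part of the package.

The **deep feature vector** is the 100 post-ReLU activations of the first
FC layer with dropout disabled — the representation handed to the
secondary classifiers. The same network scored by its softmax output is
the *full CNN* (fCNN) baseline.

## Secondary classifiers

Six conventional learners consume the feature vectors: SVM (RBF, cost 1),
KNN (k = 5), random forest (100 trees), bagging (100 bootstrap trees),
boosting — the pipeline default — and L2 logistic regression (ridge,
small fixed penalty). Boosting is AdaBoost.M1 over depth-1 decision
stumps, 100 rounds; boosting and bagging are implemented as thin
meta-algorithms over `rpart` trees, the other learners call the standard R
implementations. Features are not standardized by default (the source
design is silent); a z-scoring flag is available. These learners are
deliberately conventional — the contribution under study is the channel
construction and feature learning, not the final classifier.

## Selection and validation

All data splitting is **record-wise**: whole patients are assigned to
folds, so no record ever contributes segments to both sides of a split (a
runtime guard enforces this, and `validate_cv()` refuses evaluation
records the extractor has seen). Fold sizes are as equal as possible —
17 records at $k = 5$ give 4,4,3,3,3.

*Selection* is a grid search scored by record-wise 5-fold CV on the
training data: per candidate configuration and fold, a network is trained
on the fold-train side and scored by its softmax (fCNN scorer) and by each
selector classifier (SVM, KNN, RF) trained on fold-train features. Per
scorer the minimum-mean-BER configuration wins; ties break toward fewer
parameters, then lower learning rate. We read "nested" as this
grid-over-CV structure — the published winners are consistent with a
per-scorer argmin over one CV layer, and no second nesting level is
specified. A configuration that diverges (non-finite loss) scores the
worst-case BER of 50 rather than aborting the search.

*Validation* extracts features from the evaluation records once, then
repeats the record-wise 5-fold CV (fresh seeded fold plan per repetition,
repetition $r$ seeded `seed + r` for auditability), training only the
secondary classifier per fold and pooling the five folds' confusion counts
into one report per repetition; means and standard deviations are taken
over repetitions. For the fCNN the network is retrained per fold from its
configuration (the alternative — one fixed network — is a flag; retraining
is the default since a softmax classifier cannot be refit without its
backbone).

## The synthetic generator

Real arrhythmia databases cannot ship with the package, so every stage is
exercised by a seeded generator that reproduces exactly the spectral
structure the method relies on:

* **Non-shockable**: trains of biphasic Mexican-hat (Ricker) QRS wavelets
  (σ = 20 ms, spectral peak ≈ 11 Hz, ~1 mV peak-to-peak) at a configurable
  rate (default 75 beats/min), with small P/T-like Gaussian bumps,
  sinusoidal baseline wander below 1 Hz and Gaussian noise. The
  magnitude-spectrum argmax over 1–30 Hz falls in 4–20 Hz.
* **VF-like**: a sinusoid whose instantaneous frequency follows an
  Ornstein–Uhlenbeck process around 4 Hz (relaxation 0.5 /s, stationary sd
  0.4 Hz) with slow amplitude modulation (~0.7 mV peak-to-peak) —
  irregular like fibrillation yet with negligible power above 10 Hz.
* **VT-like**: a monomorphic train of wide (σ = 50 ms) complexes at
  ≥ 150 beats/min; its fundamental is exactly rate/60 Hz.

Record sets emulate the patient-per-record structure: each record
concatenates labeled segments with an annotation track, and the per-record
shockable count is deterministic, so label counts are identical across
seeds. Default nuisance scales (noise sd 0.02 mV, wander 0.05 mV at
0.3 Hz) are typical of lightly conditioned monitor ECG.

What the generator does **not** emulate: varied non-shockable morphologies
(AF, paced rhythms, bundle-branch block), electrode artifacts,
non-stationary noise, class imbalance at database scale, or inter-patient
morphology variation beyond seed-to-seed waveform changes. Passing the
synthetic experiments therefore demonstrates that the pipeline is wired
correctly and that its stages do what they claim on signals with the
assumed spectral structure — not that the published database-level
performance transfers to clinical ECG.

## Scaled-down study conditions

The package's standard synthetic experiment uses 20 records of 20
segments (30% shockable), split 10 training / 10 evaluation records
(~400 segments), the selected extractor configuration
(`Ns 3, Nd 1, Lr 0.005, Mo 0.9, Re 0.15`), 8 training epochs (the
cross-entropy reaches its floor by epoch 3 on this task), and validation
with $k = 5$, 10 repetitions. The grid-search demonstration uses 8 records
× 10 segments and the four published winning configurations plus a
deliberately divergent `Lr = 0.5` candidate. The secondary-learning
comparison (boosting vs fCNN over 20 seeded replicates) runs on 2-s
segments so each replicate can train a fresh network; it is a logged soft
check, as both classifiers sit at or near zero error on this separable
task and the comparison is only informative about ordering.

## Known limitations

* The 200 µV VF floor assumes amplitudes calibrated in mV; uncalibrated
  input makes the exclusion rule meaningless, so a missing sampling-rate /
  calibration context is an error rather than a silent pass.
* The WFDB support is a deliberate subset (header + format-16 signal,
  plain-text annotation sidecar) sufficient for round-trips of generated
  records; it does not read the binary annotation format of the public
  databases.
* The rate estimate behind the slow-VT rule is a simple refractory peak
  detector, adequate for monomorphic trains but not a general QRS
  delineator.
* Latency is logged per stage by `run_saa()` but never asserted:
  wall-clock behavior is hardware-dependent.
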