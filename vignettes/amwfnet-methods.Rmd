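---
title: "Methods: multimodal wavelet fusion for elbow motor-function assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal wavelet fusion for elbow motor-function assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assessment problem

Clinical assessment of post-stroke upper-limb function relies on ordinal
scales such as the Fugl-Meyer Assessment (FMA-UE), whose elbow flexion and
extension sub-items are scored 0 (severe impairment), 1 (moderate,
synergy-compensated movement) or 2 (normal execution) by trained
therapists. `amwfnet` implements an automated counterpart: during
robot-guided planar reaching, eight surface-EMG channels (1 kHz; FCR, ECR,
FCU, BR, ECU, BB, TBL, TBLa) and the robot end-effector speed (500 Hz) are
recorded for each of 18 standardised actions — three directions (45°, 90°,
135°) × three distances (Near/Mid/Far) × two motion phases (reach-out =
extension, return = flexion), numbered direction-major / distance-minor
with odd IDs for reach-out. The task is six-class classification with the
parity encoding `y = 2 s + p`, which couples the sub-score `s` with the
motion phase `p` so that flexion and extension function are assessed
jointly.

## Signal conditioning

sEMG passes a two-stage zero-phase cascade: a 50 Hz biquad notch
(second-order IIR with Q = 30, i.e. −3 dB bandwidth 50/30 Hz — the common
reading of a "Q = 30 second-order Butterworth notch") followed by a
fourth-order Butterworth band-pass at 20–450 Hz. The speed trace is
smoothed with a zero-phase fourth-order 20 Hz Butterworth low-pass plus a
15 ms Gaussian moving average (σ = window/6, truncated at ±3σ, unit-sum)
and differentiated by central differences; the smooth–differentiate cascade
is repeated so acceleration and jerk are always derivative chains of
smoothed signals. Jerk is therefore never an independently constructed (or
augmented) channel.

"Zero phase" is realised as forward–backward filtering with odd-reflection
padding of three times the filter order. Filtering from rest would leave a
startup transient of the high-Q notch (pole modulus ≈ 0.995) ringing at
50 Hz through the whole trial, so each pass starts from steady-state
initial conditions scaled to the first padded sample; with that choice a
constant input leaves the cascade at ≈ 10⁻¹⁴ of its amplitude. The listed
"quality control" of the acquisition protocol is undefined upstream; only
the minimum-duration drop in `segment_and_label()` is implemented.

## Scalograms

Each conditioned channel is transformed with a complex Morlet continuous
wavelet transform (ω₀ = 6), implemented in the frequency domain with
L2-normalised analytic filters and the scale–frequency mapping
`f = ω₀ · fs / (2π a)`. The 128 analysis frequencies are log-spaced
(linear spacing is available) over 20–450 Hz for sEMG and 0.5–50 Hz for
the kinematic channels; log spacing suits the wide sEMG band, and the
tone-localisation tests confirm that the power ridge of an in-band
sinusoid falls within one scale step of the tone. Power `|W|²` is
compressed with `log1p`, bilinearly resized to 128 × 128, and min–max
normalised **per scalogram** (a constant scalogram maps to zeros), giving
the 11-plane tensor (8 sEMG + 3 kinematic planes). Rows are ordered low →
high frequency. No cone-of-influence masking is applied; the tests assess
ridge positions away from the edges. The printed pipeline order (power →
log1p → resize → normalise) is followed literally.

Per-scalogram normalisation makes every plane amplitude-free: any
discriminative information must be *structural* (where in time, and in
which frequency band, energy concentrates). This shapes both the network's
task and the synthetic generator below.

## The network

Every plane is encoded independently (as a 1-channel image through shared
weights) by a branch encoder of four double-convolution blocks — two 3×3
convolutions per block, each with batch normalisation and ReLU, then 2×2
max-pooling — with channels 1→32→64→128→128, ending in global average
pooling to a D = 128 vector per plane. The per-plane reading (rather than
one 8-channel convolution) is forced jointly by the printed channel
progression starting at 1, by per-muscle attention weights being defined at
all, and by the parameter count: two weight-independent such encoders plus
the heads below give exactly 1,268,554 trainable parameters (~1.27 M,
~4.84 MB at 4 bytes each), which `count_parameters()` reproduces. A single
shared-weight encoder would halve that.

Channel-wise attention pooling scores each plane with a 128→64→1 MLP,
softmax-normalises the N scores of a branch (N = 8 or 3) and returns the
weighted sum — a convex combination whose weights are the interpretability
signal. The two branch vectors are fused by a gating MLP (concatenation →
hidden 256, ReLU → 2 logits) with temperature softmax
`w = softmax(l / τ)`, default τ = 2.5; the fused vector is the `w`-convex
combination of the branch vectors. The classifier concatenates an
18-dimensional action one-hot (no projection) to form a 146-vector, then
hidden 128 → ReLU → dropout 0.3 → 6 logits.

Implementation notes: convolutions are im2col + BLAS GEMM with C++
gather/scatter kernels; each conv feeds a batch norm, so its bias is
folded into the batch-norm shift (exact in both modes — in training the
centering cancels the bias and its gradient is identically zero) and the
bias tensors remain counted parameters held at zero. Batch-norm running
statistics use momentum 0.1 with the biased batch variance for
normalisation and the unbiased variance for the running buffer; inference
uses running statistics, and dropout is inactive in evaluation mode, so
evaluation is deterministic. Weights are He-normal initialised; a fixed
seed makes construction reproducible. All analytic gradients are verified
against central-difference numerical gradients in the test suite.

## Training protocol

Subjects — never trials — are split 60:20:20 (validation and test sizes
rounded down, remainder to training: 40 subjects give 24/8/8). Training
follows two stages: stage 1 on robot-guided passive trials (lr 1e-3, up to
100 epochs), stage 2 fine-tuning on active voluntary trials (lr 5e-4)
initialised from the stage-1 weights. Both stages use AdamW (decoupled
weight decay 1e-4), cross-entropy, batch size 32, global-norm gradient
clipping at 1.0 and early stopping after 10 non-improving validation-loss
epochs, with best-validation weights restored. Histories record per-epoch
loss, validation accuracy, mean gate weights and the post-clip gradient
norm. Mixed precision is not used: all arithmetic is double precision, so
results cannot depend on an AMP toggle.

Training-set class balancing oversamples minority scores with augmented
copies: per-modality amplitude scaling in [0.9, 1.1] (intensity and sensor
gain vary per modality), one shared time-warp factor in [0.9, 1.1]
resampling both streams by linear interpolation (temporal alignment must
survive), and Gaussian noise with σ = 0.05 (sEMG) / 0.005 (kinematics).
Augmentation happens on raw signals and scalograms are recomputed, because
the stated transforms are time-domain operations; jerk is recomputed from
the augmented speed trace, never perturbed directly. Validation and test
partitions are refused by `balance_training_set()`. The augmentation
multiplicity beyond pure balancing is left configurable via the `target`
argument, since only per-stage totals are known for the motivating
protocol.

## The synthetic cohort generator

The study's recordings are private, so `simulate_cohort()` generates
cohorts with the statistical structure the analysis assumes. Subjects
belong to one score group each (score 0/1 "stroke-like", score 2
"healthy-like"); every subject performs all 18 actions in both acquisition
stages. Per trial:

* **sEMG** — 20–450 Hz band-limited noise, amplitude-modulated by a
  movement-locked Gaussian burst. Agonists follow the trial parity
  (flexor group FCR/FCU/BR/BB on flexion). The score modulates burst
  amplitude (up), antagonist co-activation (down), burst width and a
  delayed compensatory sub-burst (impairment widens and fragments the
  burst), and the spectral balance of the carrier (impairment tilts energy
  toward 20–150 Hz, normal function toward 150–450 Hz). Reach-out bursts
  centre earlier in the trial than return bursts — a subject-invariant
  temporal signature of the motion phase.
* **Kinematics** — a minimum-jerk-like speed bell whose peak speed rises
  and whose duration shrinks with score; impairment adds a secondary
  sub-movement and 3–8 Hz tremor ripple; measurement noise on top.
* **Stages** — passive trials have strongly reduced voluntary sEMG
  amplitude (×0.35) and attenuated score effects (×0.6): the robot guides
  the limb, which is exactly why passive data make a useful warm-up stage.

The structural effects (timing, fragmentation, spectral tilt) are
deliberate: they survive the per-scalogram normalisation, whereas purely
multiplicative amplitude effects would not. All score effects scale with
`class_effect_size` (0 switches them off; the defaults correspond to 1);
`signal_channels` and `effect_emg`/`effect_kine` let recovery experiments
plant the class signal in designated channels or a single modality. One
master seed plus per-trial hashed substreams (subject, action, trial,
stage) make cohorts bit-reproducible and extensible without reshuffling.
Trials default to 3 s — long enough to contain a reach, cheap enough for
desk-scale wavelet transforms; per-stage trial multiplicity is a free
parameter because per-subject trial counts are not public. The optional
`class_counts` argument reproduces score imbalance of the motivating
cohort's kind (score 2 ≫ 1 > 0).

What the generator does **not** emulate: motor-unit biophysics,
electrode-placement artefacts, 2-D workspace geometry beyond action
labels, robot dynamics, or inter-session drift. Passing recovery tests
therefore shows that the pipeline can extract planted class structure
under realistic band limits, subject grouping and noise — not that it
reproduces clinical accuracy on real patients.

## Desk-scale experiment sizes

The packaged experiments are sized for a single CPU; these are the
package's standard test conditions, stated here once:

* Recovery cohort: 10 subjects (3/3/4 per score), 2 trials per action and
  stage = 720 trials, `class_effect_size = 3` (strongly separated).
* Scalograms for training experiments: 48 scales, 16 × 16 images; the
  full 128-scale, 128 × 128 pipeline is exercised per-trial in the shape
  checks.
* Width-reduced encoder for training experiments: channels 8→16→32→32
  (all components present; the full-width model is built for the
  parameter-count checks). Stage 1 is shortened to a few epochs — enough
  for the warm-up effect, not the published 100.
* Interpretability recoveries: 9-subject cohorts, single-stage training at
  lr 1e-3 (from scratch, so the stage-1 rate is the appropriate one), 10
  epochs, 3 seeds; success is the planted channel attaining the maximum
  mean attention weight, or the informative modality the larger gate
  weight, in at least 2 of 3 seeds.
* The temperature sweep driver is exercised over the full 9-value grid at
  one epoch per value: enough to validate the driver's contract
  (row-per-τ, determinism, convex weights); converged-entropy trends
  across τ require longer runs than the suite performs and are asserted
  only at the softmax-mechanism level.

## Baselines

The 112-dimensional hand-crafted representation is 8 muscles × {RMS, MAV,
VAR, WL, ZC, SSC, MDF, MPF} (64), 3 kinematic channels × {mean, std, max,
min, median, IQR, RMS, peak-to-peak, jerk index, spectral arc length}
(30), plus the 18-dim action one-hot. ZC/SSC use a configurable deadband
ε, default 0 (the textbook definition). MDF/MPF come from a Welch
spectrum: Hamming windows of min(256, T) samples, 50 % overlap. The jerk
index is defined — the source names it without a formula — as the RMS of
the channel's second derivative times duration² over peak magnitude
(dimensionless, amplitude-invariant); the spectral arc length uses the
amplitude-normalised magnitude spectrum up to a configurable 20 Hz cutoff
with cutoff-normalised frequency. SVM (RBF, C = 10, scikit-learn-style
"scale" gamma = 1/(p · var)) and random forest (300 trees, min node size
2) both use inverse-frequency class weights, with features standardised by
training-partition statistics. The raw-signal baseline mirrors the full
network but swaps 2-D encoders for 1-D ones (double kernel-9 convolutions,
pool 2, same channel progression, same attention/gate/head); whether its
fusion uses gating or concatenation is not specified upstream, so gating
is the default for architectural parity with a `variant = "concat"`
switch.

## Evaluation choices

Metrics are macro-averages over the 6 classes derived from the confusion
matrix; a class absent from both truth and prediction contributes 0 to the
macro means, which keeps small-sample reports deterministic. The Fisher
discriminant ratio is the size-weighted variance of group means over the
size-weighted mean within-group variance; degenerate zero-within-variance
groups return `Inf` with a warning rather than an error, so screening
loops can flag rather than crash. The "no gating" ablation concatenates
the two 128-d branch vectors and linearly reduces 256→128 so the
classifier keeps its 146-wide input — making the comparison head-identical.
All experiment drivers return plain data frames and JSON-serialisable
summaries.

## Known limitations

* The network trains in double precision on CPU; wall-clock performance,
  quantisation and deployment latency are out of scope.
* The generator's class effects are low-dimensional caricatures of
  impairment; distributional realism (co-articulation, fatigue,
  electrode shift) is not modelled.
* Early stopping monitors validation loss only; no learning-rate
  schedules beyond the two-stage drop are implemented.
* Attention and gate weights are interpretability summaries, not
  causal attributions.
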