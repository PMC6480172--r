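---
title: "Methods: synthetic capacitive ECG, CNN classifiers and the hierarchical pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic capacitive ECG, CNN classifiers and the hierarchical pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Capacitive ECG (cECG) measures the heart's electrical activity through cloth,
with the subject lying on electrode-equipped bedding and nothing attached to
the skin. Two intrinsic properties make the raw signal hard to use directly:
the signal quality collapses abruptly whenever the body moves (the coupling
capacitance changes), and the projection of the cardiac dipole onto the
electrode axis — hence the waveform's amplitude, polarity and shape — changes
with sleep position. A processing chain for overnight recordings therefore has
to (i) decide, for every few seconds of signal, whether the segment is usable,
and (ii) for the usable segments, recognize the sleep position, because
position determines how the waveform should be interpreted downstream.

This package implements that chain end to end: segments are labeled
C1 (clear waveform), C2 (blurry waveform with clear R peaks) or N (noise) by a
1D convolutional network (`qua_model`), and only C1 segments are forwarded to
a second network (`pos_model`) that labels the position S (supine),
L (left lateral) or R (right lateral). No R-peak detection or beat alignment
is required anywhere: fixed-length z-scored windows go into the networks
directly.

## The synthetic data generator

No public recordings exist for this measurement setup, so the package ships a
generator whose output has the structural properties the classifiers must
exploit. It is first-class, tested code — every downstream stage is developed
and validated against it.

**Coupling circuit.** The electrode couples through cloth modelled as a
contact resistance in series with a parallel RC branch,

$$|Z_t(f)| = R_\mathrm{cont} + \frac{R_\mathrm{cloth}}
  {\sqrt{(2\pi f\, R_\mathrm{cloth} C_\mathrm{cloth})^2 + 1}},$$

with defaults $R_\mathrm{cloth} = 150\ \mathrm{M}\Omega$ and
$C_\mathrm{cloth} = 70\ \mathrm{pF}$. The magnitude is strictly decreasing in
frequency, from $R_\mathrm{cont}+R_\mathrm{cloth}$ at DC to $R_\mathrm{cont}$
at high frequency. `coupling_filter()` exposes this response as an optional
zero-phase linear filter (normalized to unit DC gain); the generator leaves it
off by default because the circuit model is descriptive — the classifiers see
its consequences (quality loss) through the quality specs instead.

**Beat morphology.** One beat is a sum of five Gaussian bumps (P, Q, R, S, T),
each with an amplitude, a phase center (fraction of the RR interval) and a
width. This is the usual synthetic-ECG construction; any morphology with a
dominant R wave and ordered waves would serve. Defaults give an upright
lead-II-like beat with R amplitude 1.

**Position projection.** A `position_profile` scales a beat by
`polarity * gain` and modulates individual waves:

| position | gain | polarity | wave modulation |
|---|---|---|---|
| S (reference) | 1.00 | +1 | none |
| R | 0.90 | +1 | P, T × 0.8 |
| L | 0.35 | −1 | none |

These values are configuration, not physiology; they encode the geometric
facts the classifiers rely on — the left-lateral projection is the smallest,
and S and R are similar but distinguishable. Note a deliberate consequence:
per-segment z-scoring erases the S/R **gain** difference, so S vs R must be
told apart by the relative P/T shape alone. That makes S/R the hard pair,
and it is why position classification benefits from 4 s windows and deeper
networks while L (polarity-flipped) is easy — the same qualitative pattern the
measurement setting itself produces.

**Quality degradation.** A `quality_spec` adds Gaussian broadband noise,
baseline wander (a random-phase sinusoid plus a random walk with terminal
scale half the wander amplitude), Poisson-timed artifact bursts (damped 8 Hz
oscillations, ~0.3 s), and per-wave attenuation (exact, via the per-wave
component matrix the renderer produces). Defaults per class:

| class | noise sd | wander (amp @ Hz) | bursts (rate, amp) | attenuation |
|---|---|---|---|---|
| C1 | 0.008 | 0.015 @ 0.30 | — | none |
| C2 | 0.06 | 0.25 @ 0.33 | 0.05/s, 0.4 | P,T × 0.35; Q,S × 0.7; R × 1 |
| N | 0.45 | 1.2 @ 0.40 | 0.5/s, 1.5 | all × 0.3 |

The C1 numbers keep the added energy below 10% of the clean energy even for
the weak L projection; C2 preserves the R wave (its defining property) while
blurring P/T; N makes the noise energy dominate and attenuates everything
(coupling lost during movement). At these defaults a single threshold on
ground-truth segment SNR separates C1 from N with 100% accuracy — the classes
are separable by construction, which is what makes the acceptance experiment a
test of the pipeline rather than of the generator.

**Reproducibility.** One root seed drives an experiment; per-record child
seeds are `(root + 7919·counter) mod (2^31−1)` with separate counters for
rendering and degradation, so any record regenerates bitwise identically and
independently. Record lengths are chosen so segmentation yields exactly the
requested number of windows per (quality, position) cell.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real recordings: inter-subject morphology differences,
respiration and heart-rate drift, arrhythmic beats, electrode-position drift
across a night, correlated noise between neighbouring segments beyond window
overlap, and quality classes that blend into each other (a technician's C2/N
boundary is far fuzzier than these specs). Results on synthetic data are an
upper bound, not a clinical claim.

## Preprocessing

* **Band-pass 0.05–40 Hz, Butterworth order 2, zero phase.** The filter is
  applied forward and backward so R-peak timing is not shifted; the magnitude
  response is squared. Each pass starts from the filter's unit-step
  steady-state initial conditions (with short odd-reflection padding). This
  matters: the 0.05 Hz corner has a settling time of thousands of samples, and
  a plain forward-backward pass leaves a DC transient of that length, whereas
  the steady-state start removes a constant offset exactly.
* **Segmentation.** Window `L = round(fs·seg_len)`, step
  `round(L·(1−overlap))`, 0-based half-open windows `[start, start+L)`,
  trailing samples dropped: `floor((N−L)/step)+1` windows. 2 s and 4 s windows
  (600 and 1200 samples at 300 Hz) are the supported study lengths; 50%
  overlap doubles the training data. Both overlap conventions are supported
  because 30 minutes of signal gives 450 non-overlapping or 899 half-overlapping
  4 s windows, and both figures are in circulation for this setup.
* **Labeling.** A window inherits a label only if it lies entirely inside one
  annotation interval of consistent labels; straddling windows are discarded
  and counted. This mirrors per-portion annotation, where a technician marks
  stretches of consistent quality and segmentation runs within them.
* **Normalization.** Per-window z-scoring with the population standard
  deviation (the natural choice for CNN inputs; the exact formula is a
  convention, fixed here and asserted to 1e-9 in tests). Windows with
  sub-1e-12 standard deviation cannot be z-scored; during dataset assembly
  they are rejected and counted, and at inference time they are labeled N by
  convention — a flat line carries no ECG information.

## The classifier family

All networks share one structural rule set, parameterized only by depth
(3–8 blocks) and input length:

* a **basic block** is convolution → ReLU → batch normalization, followed by
  max pooling (size 2, stride 2);
* the first convolution's filters are one second long (`round(fs)` = 300
  samples); each subsequent layer halves the filter length (floor), keeping
  filter duration roughly constant relative to the pooled feature maps;
* with 8 blocks, the pool after block 7 is dropped and block 8 reuses block
  7's filter length, pooling again after block 8;
* every convolution has 10 filters, stride 1, and length-preserving symmetric
  zero padding, so only pooling changes the temporal length;
* the head is flatten → dropout 20% → dense → softmax; BN uses ε = 0.001.

Sweeping depth 3–8 gives exactly 6 variants per input length. `cnn_spec()`
computes every derived quantity (per-stage lengths, flatten width, closed-form
trainable parameter count) and serializes to JSON.

Two printed-formula discrepancies are resolved on the side of standard
practice: the activation is standard ReLU max(0, x) (the step function that
appears in one rendering of the definition has zero gradient almost everywhere
and cannot train), and precision/recall use the standard TP/(TP+FP),
TP/(TP+FN) definitions.

## Numerical and training choices

* **FFT convolution.** The kernels are long (up to a quarter of the input), so
  im2col+GEMM lowering inflates memory traffic by the kernel length and is
  memory-bound. Forward and backward convolutions are evaluated as circular
  convolutions on a power-of-two FFT grid of at least `L+k−1` points, which is
  exact for the linear operation; the direct im2col implementation is retained
  and the test suite asserts both paths agree to 1e-10, and that backprop
  matches finite differences on a small network.
* **Initialization.** Glorot-uniform weights, zero biases, BN γ=1, β=0; all
  randomness (initialization, shuffling, dropout, validation split) flows from
  one seed, so a fit is exactly reproducible.
* **Batch normalization statistics.** Training uses biased batch variance;
  inference uses exponential moving averages with momentum 0.9 **debiased** by
  `1 − momentum^steps` (zero-initialized), the same correction Adam applies to
  its moments. At desk scale a model sees only tens of optimizer steps, and an
  undebiased EMA is still dominated by its initialization — symptom:
  training accuracy climbs while inference-mode accuracy stays at chance.
* **Optimization.** Adam (lr 1e-3 default), categorical cross-entropy,
  batch size 32 (a trailing 1-sample batch is dropped — BN needs ≥ 2), early
  stopping on an inner-validation loss with the best-epoch weights restored.
  Training diverging to a non-finite loss raises an error carrying the
  history.
* **Ties and edge cases.** Odd lengths halve with floor everywhere; max-pool
  gradient goes to the first maximum on ties; softmax uses max subtraction.

## Cross-validation and metrics

Folds are stratified on the joint (quality, position) label — the class mix is
strongly imbalanced, and unstratified folds would occasionally lose a rare
cell entirely. Every segment is tested exactly once; confusion counts are
**pooled** across folds before computing precision/recall (robust when
per-fold class counts are small; the alternative, averaging per-fold ratios,
is noisier and the convention had to be fixed one way). Class-wise precision
and recall come with supports, and model selection uses the support-weighted
average of the two. For the position task only segments with ground-truth C1
quality are admitted during training and evaluation; at inference admission is
by the quality model's prediction — this train/infer asymmetry is deliberate
and mirrors how the system is deployed.

## Shipped experiment sizes

The package's own experiments (the acceptance script and the heavyweight
tests) use sizes chosen to make a single-CPU run practical while keeping every
structural property of the full study:

* ~600 segments of 4 s across the nine (quality, position) cells, in the
  class proportions of the reference recording campaign (`default_cell_counts()`);
* 10-fold stratified CV over the reduced depth grid {3, 6};
* task-appropriate training schedules (Adam lr 2e-3 for both): the quality
  classes separate within ~5 epochs at batch 32 (max 6 epochs, patience 1),
  while the position task needs more optimizer steps to resolve S vs R, which
  smaller batches supply at the same per-epoch cost (batch 16, max 8 epochs,
  patience 2);
* the label-noise sanity experiment uses the position task (the hardest one)
  at a deliberately small training size, so that corrupted labels are not
  simply averaged away by excess data.

## Limitations

The classifiers are validated on synthetic data only; nothing here quantifies
performance on real cECG. The generator's quality classes are cleanly
separable by construction, so absolute metric values (≈ 0.9 and above) say
that the pipeline wires data, models and gating together correctly — not that
a clinical C2/N boundary would be recognized with that accuracy. The depth
sweep explores only the 3–8 block family with the stated rules; no
architecture search, regularization tuning or per-user adaptation is in scope,
and C2 segments are exposed by the annotation track but not further processed.
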