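---
title: "qrseg: model, synthetic world, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qrseg: model, synthetic world, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ambulatory (Holter) ECG is recorded during daily activities, so the entry
point of any rhythm analysis — finding each heartbeat (QRS complex) and
labelling it as a normal sinus beat (N), a premature atrial contraction
(PAC) or a premature ventricular contraction (PVC) — must survive heavy
movement noise and electrode artifacts. The classical pipeline chains a QRS
detector with a separate beat classifier. `qrseg` instead treats the task
as per-sample sequence segmentation: a single forward pass of one network
yields, for every sample of a 30 s window at 100 Hz, a probability over
four channels (no-QRS, N, PVC, PAC), and deterministic post-processing
turns that mask into time-stamped, classified beat annotations.

## The model

The input is a single-lead signal resampled to 100 Hz and standardized per
window to zero mean and unit variance (population variance; a constant
window maps to zeros). Training targets widen each annotated fiducial to a
run of exactly 10 samples of its class, centered on the annotation
(`i - 5 … i + 4`, clipped at window edges); everything else is no-QRS.
Centering is our choice — only the 10-sample width is prescribed — because
a symmetric run lets the post-processing "segment center" rule recover the
original index to within one sample, which the round-trip acceptance test
exploits.

The network is five residual blocks, a gated recurrent layer, and a fully
connected per-position projection to four logits, softmaxed per sample.
The published description fixes this topology but not the internals, so
the block internals are package conventions exposed in `model_config()`:

* each block: two kernel-7 same-padded 1D convolutions with batch
  normalization and ReLU, plus an identity skip (1x1 projection when the
  width changes); no temporal pooling anywhere, so output length always
  equals input length;
* default widths `[16, 32, 64, 128, 128]`, GRU hidden 128, unidirectional
  with a `gru_bidirectional` flag;
* float32 arithmetic in the compiled core, with analytic backward passes
  verified against finite differences in the test suite.

Training follows the published recipe exactly where stated: batch size 64,
per-sample cross-entropy, AdamW at learning rate 0.001, gradient L2 norm
clipped to 1.0, no weight decay, default 70 epochs. Augmentation modifies
the data for each batch: records are drawn by weighted oversampling
(record weight proportional to `sum_c count_rc / total_c`, equalizing
expected class exposure), cropped to a random 30 s window, and inverted
with probability 0.5. No learning-rate schedule is used (none is stated).
Validation is deterministic (the first 30 s of each record) and the
checkpoint with the best validation detection F1 is retained — a standard
choice the source is silent about; the history table makes it auditable.

## Post-processing

Argmax per sample (ties resolve to the lowest channel, i.e. no-QRS), then
maximal same-class runs become segments; runs shorter than 2 samples are
discarded as argmax flicker (the target runs are 10 samples wide, so a
1-sample run is noise). Each segment yields a candidate peak at
`floor((start + end - 1) / 2)` with strength defined as the mean assigned-
class probability over the segment — "strength" is not defined in the
source; mean is robust to single-sample spikes and alternatives (max,
segment length) are exposed as options in code. Finally, while any two
peaks are strictly closer than 0.15 s, the weaker of the closest offending
pair is removed (distance ties: earliest pair; strength ties: the later
peak), iterated to a fixed point. The strict inequality matters: a pair at
exactly 0.15 s survives, and the brute-force oracle test pins the boundary.

Records longer than 30 s are processed in sliding 30 s windows with 50%
overlap; each candidate is kept from the window whose center is nearest
(maximal context on both sides), residual duplicates fall to the
suppression rule, and centers are mapped back to the native sampling rate.
Records shorter than 30 s are zero-padded on the right. Both policies are
package conventions; inference-time windowing is not described in the
source, which used 30 s inputs throughout.

## Evaluation

A predicted beat is a true positive when it lies within 0.1 s —
*inclusive* — of a reference annotation, under a maximum-cardinality
one-to-one matching (greedy nearest pair, then augmenting-path repair; an
exhaustive oracle verifies maximality on small instances). Detection
F1 = 2TP / (2TP + FP + FN). Classification reports per-class, micro and
macro F1 over {N, PAC, PVC}. Whether the published classification scores
condition on successful detection is not stated; the default here is the
stricter self-consistent reading — an undetected PVC counts as a PVC false
negative and a spurious detection as a false positive of its predicted
class — with `matched_only = TRUE` available for the other reading.
Dataset aggregation pools counts within a dataset and reports mean ±
population standard deviation across datasets, matching the presentation
style of the cross-database results.

## The synthetic world

No data ships with the package. The generator emulates the *structure* of
the private development data — 45 s single-lead records at 200 Hz with
N/PAC/PVC beats and heavy movement-noise episodes — without claiming
physiological fidelity:

* **Rhythm.** Sinus RR intervals are Gaussian-jittered (5% CV, a typical
  resting respiratory sinus arrhythmia magnitude); the "irregular" AF-like
  mode uses uniform jitter at 30% CV. Premature beats shorten the
  preceding RR by a factor 0.7 (the clinical meaning of "premature") and a
  PVC is followed by a compensatory pause (factor 1.3). Consecutive
  fiducials never come closer than 0.25 s, safely above the 0.15 s
  suppression threshold.
* **Morphology.** Beats are analytic Gaussian mixtures (P, QRS, T). PVCs
  are wide, large, P-free with discordant T; PACs carry a narrow QRS with
  an inverted ectopic P. A property test asserts PVC templates are
  strictly wider than N templates.
* **Noise.** Movement noise is sub-1 Hz sinusoidal baseline wander plus
  broadband Gaussian noise, both scaled by `noise_level`, plus
  Poisson-placed Hann-windowed high-amplitude bursts (0.5–2.5 s,
  1–2.5x QRS amplitude) emulating electrode/movement artifacts. The source
  gives no quantitative noise statistics, so the default `noise_level =
  0.3` (broadband sd 0.06 against a unit QRS) with one burst per record
  was fixed once as a plausibly "heavily disturbed but analyzable" Holter
  level and not revisited.

What a green end-to-end test establishes is therefore *parameter
recovery*: the pipeline can learn to invert its own generative world at
desk scale (reduced widths `[8,16,16,32,32]`, GRU 32, 200 records, tens of
epochs, one CPU) to detection F1 >= 0.95 under moderate noise and >= 0.99
clean, with macro classification F1 >= 0.80. It does not establish
performance on real Holter data, where noise is non-stationary and
colored, morphologies drift within a patient, and rhythm confusers
(atrial fibrillation, SVT runs — the published failure modes for PAC)
occur.

Two desk-scale training dynamics are worth recording. First, the polarity
inversion augmentation (p = 0.5, per the published recipe) makes P-wave
*polarity* uninformative, so PAC discrimination rests almost entirely on
prematurity — the shortened RR interval — which only the recurrent layer
can measure. Detection and PVC classification converge within ~100
gradient steps, while PAC classification shows a sharp phase transition:
its F1 stays at 0.0 through ~160 steps and jumps above 0.9 by ~200 steps
as the GRU acquires an inter-beat interval representation. Three package
choices follow from this, all in territory the source leaves open:

* the end-to-end test trains 55 epochs (220 steps), past the transition;
* AdamW moments are warm-restarted every 10 epochs
  (`optimizer_restart_every`): no learning-rate schedule is stated, and
  without the restarts the optimizer can sit on the pre-transition
  plateau for the whole desk-scale budget — the restart's transient
  effective-step boost reliably kicks it off;
* checkpoints are selected by the mean of validation detection F1 and
  validation macro classification F1, not detection F1 alone: detection
  saturates long before PAC is learned, so a detection-only criterion
  systematically retains a pre-transition model that has never emitted a
  PAC.

The desk-scale model also uses the bidirectional GRU flag: with context
from both sides of each beat (the shortened RR before a premature beat
and the compensatory pause after a PVC) it reaches a lower loss at equal
step count than the unidirectional default.

## Numerical choices and degenerate inputs

* Resampling is Fourier-domain (exact for band-limited content);
  annotation indices are rescaled arithmetically, never re-detected, and
  post-rounding duplicates collapse to the first.
* Standardization uses population variance; irrelevant at n = 3000 but
  fixed so exactness tests are well-defined.
* Segment centers round down on even lengths; widened runs overlapping
  across classes resolve later-beat-wins. Both are arbitrary but frozen
  for exact round-trips (the generator keeps beats far apart, so the
  overlap path is rare in practice).
* Checkpoints serialize weights as full-precision JSON; save/load
  round-trips inference bit-exactly.
* Records shorter than 1 s are rejected; shorter than 30 s are padded;
  sampling rates below 100 Hz are upsampled with a logged message.

## Known limitations

* The compiled core is CPU-only, float32, single-threaded; the default
  full-width model trains far slower than a GPU PyTorch equivalent, so
  the shipped tests exercise reduced widths.
* PAC discrimination rests on prematurity and a subtle P-wave cue; it is
  the slowest class to converge at desk-scale budgets (see the phase
  transition above) — consistent with the published per-class pattern,
  where PAC is also the weakest class by a wide margin.
* WFDB support covers header/signal formats 8, 16, 80, 212 and MIT
  annotation files, reading only; exotic formats (multi-frequency,
  multi-segment) are out of scope.
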