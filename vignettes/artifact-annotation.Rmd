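---
title: "CNN-guided annotation of EEG artifacts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNN-guided annotation of EEG artifacts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegannot)
```

## The problem

Manual annotation of artifacts — ocular, muscular, movement and electrode
events — remains the gold standard for cleaning resting-state EEG, but it is
slow and error-prone, and there is rarely an independent benchmark to
validate automated detectors against. `eegannot` implements a
human-in-the-loop alternative: train a convolutional network on the expert
annotations, then use the segments it *confidently disagrees with* to drive
a targeted expert re-review. Where two independent raters agree on a new
label, the gold standard is revised; the model is then retrained on the
improved annotations. The classifier never replaces the expert — it
concentrates expert attention where the annotations are most suspect.

## Data model

A **recording** is a channels × samples matrix (volts) with a sampling
rate, 10–20 channel names and a list of half-open artifact intervals
`[onset, onset + duration)` in seconds. The modelling unit is the
**segment**: a 1-s, 19-channel window on a 0.5-s onset grid. Segment labels
are derived from the intervals by an intersection rule (below), giving a
dataset $D = \{(X^{(i)}, y^{(i)})\}_{i=1}^N$ with
$y^{(i)} \in \{\text{artifact}, \text{nonartifact}\}$ and
$X^{(i)}$ a $19 \times 45 \times 100$ time–frequency tensor.

## Minimal preprocessing

* **FIR bandpass 0.5–45 Hz**, Hamming window, with transition bandwidths of
  0.5 Hz (low edge) and 11.25 Hz (high edge). The tap count follows the
  rule $n = \lceil 3.3 \cdot SR / TB \rceil_{\text{even}}$ with $TB$ the
  shorter transition bandwidth — 13,518 taps at 2048 Hz. The filter is
  applied zero-phase: forward convolution followed by a shift of
  $\lfloor (n-1)/2 \rfloor$ samples with reflection padding at the edges.
  Because the even tap count forces a half-sample residual delay, the
  compensation is exact only to half a sample — irrelevant at EEG
  frequencies.
* **Channel selection** to the 19 standard 10–20 channels in a fixed order
  (Fp1 … Pz), case-insensitively, accepting the modern T7/T8/P7/P8 names.
* **Average re-referencing**, subtracting the instantaneous channel mean.
  Whether the average is taken over all recorded channels or only the 19
  retained ones is not uniquely determined by common practice; both orders
  are supported (`reference_scope`), and the default references the
  selected channels.
* Bad-channel spherical-spline interpolation is exposed only as a hook
  (`interpolate_bad_channels`): the synthetic data declare no bad channels
  and no interpolation method is bundled.

## Segmentation and labelling

Windows of 1 s with 50% overlap. A window is

* **nonartifact** if it intersects no annotated interval;
* **artifact** if any single interval intersects it by ≥ 0.1 s, or by any
  amount when the interval itself is ≤ 0.1 s long;
* **ignored** otherwise (a sub-0.1-s sliver of a longer interval).

Ignored windows are excluded from training and evaluation but kept in an
audit table. Intersections are computed in continuous seconds before any
sample-grid rounding, and the artifact test is per interval, not summed
overlap, so splitting an interval into abutting pieces changes nothing —
except where a piece falls under the ≤ 0.1-s special rule, which is a
deliberate property of the rule set.

## Time–frequency features

Each preprocessed recording is convolved per channel with 45 complex Morlet
wavelets, logarithmically spaced over 0.5–45 Hz. The wavelet at frequency
$f$ is $w(t) = e^{i 2\pi f t}\, e^{-4 \ln 2\, t^2 / h^2}$, parameterised
directly by its envelope FWHM $h$, itself logarithmically spaced from 1.2 s
(at 0.5 Hz) down to 0.2 s (at 45 Hz) — better temporal resolution at higher
frequencies. Wavelets are amplitude-normalised so a unit sinusoid yields
unit peak power. Power is the squared magnitude of the convolution.

Two numerical choices matter here:

* **Whole-recording convolution.** A 1.2-s-FWHM wavelet has no support
  inside an isolated 1-s window, so convolution is computed once over the
  recording and sliced into windows afterwards; a zero-padded per-segment
  variant is available behind `per_segment = TRUE` for comparison.
* **Resampling 2048 → 100 Hz** along time is linear interpolation at the
  100 bin-centre time points. Wavelet power is already smoothed by the
  ≥ 0.2-s envelope, so no additional anti-alias filter is warranted, and
  this operator is exact on constant and linearly varying power — which
  makes its unit tests sharp.

Each segment tensor is Z-scored jointly over all channels, frequencies and
time points, giving the network inputs zero mean and unit variance per
segment. Note what this removes: absolute amplitude. A broadband artifact
that only scales the signal is invisible after per-segment normalisation
unless its spectral or temporal shape differs from background — a genuine
limitation shared by any per-segment normalisation scheme.

## Network

Three grouped convolution + ReLU + max-pool stages and one linear layer to
two logits with a softmax (`arch_spec()`):

| layer | maps | groups | kernel | output (C×F×T) | parameters |
|-------|-----:|-------:|--------|----------------|-----------:|
| conv1 | 950  | 19 | 1×5 | 950×45×96 | 5,700 |
| pool1 |      |    | 1×2×2 | 950×22×48 | |
| conv2 | 1900 | 50 | 5×5 | 1900×18×44 | 904,400 |
| pool2 |      |    | 1×2×2 | 1900×9×22 | |
| conv3 | 150  | 1  | 3×3 | 150×7×20 | 2,565,150 |
| pool3 |      |    | 1×1×1 | 150×7×20 | |
| fc    |      |    |     | 2 | 42,000 |

Total: 3,517,250 learnable parameters. The first layer convolves each EEG
channel separately (19 groups); pooling written 1×2×2 acts on the spatial
(frequency, time) axes only; there is no padding anywhere. Convolutions
carry biases; the printed 42,000 = 21,000 × 2 parameter count of the linear
layer is only consistent with a bias-free linear layer, so that is the
default (`fc_bias = TRUE` is available). Weights use Kaiming-uniform
initialisation with the conventional convolution-layer bound
$1/\sqrt{\text{fan-in}}$. The forward/backward kernels are im2col + BLAS
matrix products in compiled code; gradients are verified against finite
differences in the test suite.

## Training and evaluation

Mini-batch training with class-weighted cross-entropy — weight
$1/n_c$ for class $c$, computed on each training set — and an averaged
stochastic gradient descent (ASGD) optimizer: decay term
$\lambda = 10^{-4}$, learning-rate exponent $\alpha = 0.75$, averaging
start $t_0$. Defaults follow the full-scale regime: batch 64, learning rate
$10^{-4}$, 70 cross-validation epochs, 100 final epochs. Once past $t_0$
steps the optimizer maintains a tail average of the iterates, and the
fitted model carries those averaged parameters — the stabilising point of
ASGD.

Evaluation uses subject-wise five-fold cross-validation: subjects are
partitioned into five groups; each fold holds out one group (20%), split
evenly into validation and test halves by a seeded draw, and trains on the
remaining 80%. All recordings of a subject stay together, so no
individual's data spans train and test. Validation loss is monitored per
epoch (no checkpoint selection — the loop-exit parameters are the result);
after the loop the train and validation sets are pooled for exactly one
additional epoch. Test metrics at the 0.5 probability threshold:
sensitivity, specificity, precision and balanced accuracy
$(\text{sens} + \text{spec})/2$, reported as mean ± SD over folds.

### Demonstration scale

The package's tests, examples and the acceptance script run the full
pipeline at a reduced scale chosen to exercise every stage in minutes on
one core: 10 synthetic subjects × 21 s at 256 Hz (≈ 400 segments), a
reduced architecture (`demo_arch_spec()`, same structure and grouping with
19/38/8 feature maps), 10 epochs per fold, batch 8, learning rate 0.02,
$t_0 = 150$. The optimizer settings differ from the full-scale defaults
for a reason worth stating: a full-scale run takes ~10⁵ gradient steps,
the demonstration ~250, so the demonstration needs a learning rate that
converges within its budget (at $10^{-4}$ the loss moves by < 0.001 in 10
epochs) and engages the ASGD tail average within the run. These are
convergence choices, not accuracy tuning.

## The synthetic generator

Because the clinical recordings behind this method are private, the package
ships a seeded generator (`sim_config()`, `generate_recording()`) so every
stage is testable end to end. Background EEG is $1/f$ noise (≈ 20 µV RMS)
plus an amplitude-modulated 10-Hz alpha rhythm weighted toward posterior
channels. Artifacts are drawn from a menu with homogeneous-Poisson onsets:

* **ocular** — slow, high-amplitude frontal deflection (blink-like),
  default 4/min, 0.2–0.5 s, 150 µV;
* **muscle** — 20–45 Hz band-limited burst on temporal channels, 3/min,
  0.3–1.5 s, 50 µV;
* **pop** — single-channel step offset with 10-ms ramps, 1/min, 0.2–0.8 s,
  200 µV;
* **movement** — broadband multi-channel transient, 1/min, 0.5–2 s,
  100 µV.

Events are placed entirely within the window-covered part of the recording,
so every injected interval ≥ 0.1 s yields at least one artifact segment.
Everything is a deterministic function of `(seed, subject index)`, and the
event layer can be re-run independently of waveform rendering
(`sample_artifact_events()`), which the tests use as an oracle.

What the generator does *not* emulate: volume-conducted source mixtures,
cardiac and glossokinetic artifacts, inter-subject spectral differences,
drowsiness patterns, or annotation noise at interval edges. Passing tests
on this data therefore show that the pipeline's machinery is correct and
that the network can learn discriminable TF signatures — not that the
demonstration metrics transfer to clinical EEG.

### The separable condition

Under the default menu, many artifact-labelled windows contain only a
0.1–0.3-s sliver of a brief event; error analysis shows such boundary
windows are missed at ~57% while well-covered windows are classified at
> 90% — exactly the uncertain-boundary phenomenon that motivates revising
gold standards in the first place, and the reason reported
balanced-accuracy figures on real data sit far below 100%. Learning-sanity
experiments, whose purpose is to verify that the pipeline learns when the
classes are cleanly separated, therefore use
`separable_artifact_menu()`: the same four artifact kinds with longer
(0.5–2 s) and stronger (2×) events, and 2/min rates for the rarer kinds so
each has adequate training support. The separation is verified explicitly —
the median within-window RMS of artifact segments exceeds that of
nonartifact segments by well over 1.5× — before any accuracy is asserted.
The default menu remains the package default and models the harder,
realistic short-blink regime.

### Simulated raters

`rater_model()` raters reproduce the true label with probability
`p_agree_true` and otherwise vote `uncertain`, `gray`, or the opposite
label. Two independent raters with `p_agree_true = 1` reproduce truth
exactly (Cohen's κ = 1); coin-flip raters give κ ≈ 0 — both ends are
asserted in the tests.

## The revision loop

Given the final model's predictions on its own training data, candidates
for re-annotation are: nonartifact-labelled segments predicted artifact
with probability in [0.65, 1] (putative false positives),
artifact-labelled segments in [0, 0.4] (putative false negatives), and the
immediately preceding and following overlapping windows of every
band-selected segment regardless of probability. Adjacency does not close
transitively — neighbours of neighbours are not added. With the 50%
overlap grid, "adjacent" means onset ± 0.5 s within the same recording,
the only windows sharing samples with the selected one.

Two raters decide `keep` / `artifact` / `nonartifact` / `uncertain` /
`gray` per candidate. Merging (`merge_decisions()`):

* `gray` by either rater → segment dropped entirely;
* both raters vote the same concrete label (with `keep` resolving to the
  original) → that label;
* anything else — disagreement, both uncertain, or uncertain vs a proposed
  change — → original label kept.

The last clause is the conservative reading of "replace only on explicit
two-rater agreement": when one rater is uncertain and the other proposes a
change, there is no two-rater agreement on the new label, so the original
stands. Inter-rater agreement is quantified by Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$ with chance agreement
$p_e = N^{-2} \sum_m n_{m1} n_{m2}$ from the raters' marginal counts; a
degenerate table where both raters give one identical constant answer
($p_e = 1$) yields an explicit undefined result.

After applying the merged outcomes the surviving segments are stratified
into revision-agreed, non-revised and revision-changed subsets — a
partition, with disagreement-kept candidates counted as "agreed/kept" —
for per-subset performance analysis of any model. The full cycle
(train → select → re-annotate → merge → retrain) is packaged as
`revision_cycle()`. The package's revision experiment corrupts 10% of
synthetic gold labels and uses perfect raters; the network, trained on the
corrupted labels, flags most corrupted segments in its
confident-disagreement bands, and the cycle restores their true labels and
retrains with improved accuracy against the ground truth.

## Probability traces

For display alongside the signal, overlapping-window predictions are
interpolated to one probability per time sample: the arithmetic mean of
the three windows whose centres are nearest in time (two within the first
and last second, where three overlapping windows do not exist), with ties
broken toward the earlier window. The mean over that window set is the
simplest operator consistent with per-sample interpolation from "the
current window, the one before and the one after"; it is idempotent on
constant inputs, monotone, and bounded by the contributing probabilities.
Probabilities are banded into five equal-width categories
([0,0.2) … [0.8,1]) for colour display; the band edges are configurable
since no canonical choice exists.

## File formats

Recordings use a native container: a JSON header (ids, sampling rate,
channel names) plus a raw little-endian float32 array, bounding round-trip
error at 32-bit quantisation rather than EDF's 16-bit dynamic-range loss.
Annotations, segment tables, predictions, rater decisions and traces are
plain CSV with documented columns; numbers are written in shortest exact
decimal form so write → read → write is byte-identical. Model checkpoints
bundle weights, architecture spec, training config and seed.

## Known limitations

* No EDF/BDF reader is bundled; clinical data must be converted to the
  native container first.
* Per-segment Z-scoring discards absolute amplitude (see above).
* The synthetic generator's subjects are statistically identical, so
  subject-wise cross-validation here guards against leakage but cannot
  demonstrate robustness to real inter-subject variability.
* Training is single-core CPU; the full-size architecture at clinical data
  volumes is out of reach of this implementation and would need a GPU
  framework — the package's role is the method, its arithmetic, and
  desk-scale experiments.
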