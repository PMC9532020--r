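# eegannot

CNN-guided improvement of manual artifact annotation in resting-state EEG.

Trained professionals annotate EEG artifacts by hand, and their annotations
are both the training data and the only benchmark for automated detectors —
a circularity that caps how good any detector can look. `eegannot`
implements the loop that breaks it: train a convolutional network on the
expert-annotated segments, find the segments the network *confidently*
disagrees with, send exactly those back to two independent experts, replace
labels only where the experts agree, and retrain on the revised gold
standard. The package is aimed at EEG researchers who preprocess
resting-state recordings and want model guidance for (re-)annotation, and
at methods developers who need a fully testable desk-scale implementation
of the approach.

## What is inside

* **Synthetic data** — a seeded generator of 19-channel 10–20 resting EEG
  (1/f background + posterior alpha) with ground-truth artifact intervals
  (ocular, muscle, electrode pop, movement) and simulated raters, so the
  entire pipeline runs and is tested without clinical data.
* **Preprocessing** — Hamming-window FIR bandpass 0.5–45 Hz whose length
  follows the transition-bandwidth rule `ceil_even(3.3·SR/TB)` (13,518
  taps at 2048 Hz), applied zero-phase; selection of the 19 standard
  channels; average re-referencing.
* **Segmentation** — 1-s windows, 50% overlap; a window is *artifact* if
  any annotated interval intersects it by ≥ 0.1 s (or at all, for
  intervals ≤ 0.1 s), *nonartifact* if untouched, *ignored* otherwise.
* **Time–frequency features** — 45 log-spaced Morlet wavelets over
  0.5–45 Hz with FWHM 1.2 → 0.2 s, power resampled to 100 time points and
  Z-scored per segment: a 19 × 45 × 100 tensor per segment.
* **The network** — three grouped-convolution + ReLU + max-pool stages
  (950/1900/150 maps; the first layer convolves each EEG channel
  separately) and a bias-free linear layer to two softmax logits;
  3,517,250 parameters, written from scratch with im2col + BLAS kernels
  and finite-difference-verified gradients.
* **Training / evaluation** — class-weighted cross-entropy (weight =
  1/class count), averaged SGD, subject-wise 5-fold cross-validation with
  a pooled extra epoch, metrics at the 0.5 threshold (sensitivity,
  specificity, precision, balanced accuracy).
* **Revision** — candidate selection in the confident-disagreement bands
  ([0.65, 1] for false positives, [0, 0.4] for false negatives, plus
  temporal neighbours), dual-rater decision merging, Cohen's κ, and the
  full `revision_cycle()`.
* **Probability traces** — per-sample artifact probabilities interpolated
  from the overlapping windows, banded into five categories for display.

## Worked example

```r
library(eegannot)

# the full-scale reference architecture, instantiated
model <- build_model(arch_spec(), seed = 1)
unlist(count_parameters(model))
#>   conv1   conv2   conv3      fc   total
#>    5700  904400 2565150   42000 3517250

design_bandpass(2048)$n_taps
#> [1] 13518

# synthetic study: 10 subjects, 21 s at 256 Hz, separable artifact menu
sim <- sim_config(n_subjects = 10, duration_s = 21, sr = 256,
                  artifact_menu = separable_artifact_menu(), seed = 7)
recs <- lapply(generate_dataset(sim), preprocess_recording,
               fs = design_bandpass(256))
segs <- segment_dataset(recs)
segs
#> <segment_dataset> 128 artifact / 273 nonartifact / 9 ignored windows

feats <- tensorize_dataset(recs, segs$segments)
cfg <- train_config(arch = demo_arch_spec(), epochs_cv = 10,
                    lr = 0.02, batch_size = 8, t0 = 150, seed = 11)
plan <- make_folds(unique(segs$segments$subject_id), k = 5, seed = 11)
cv <- train_cv(feats$tensors, segs$segments, plan, cfg)
cv
#> <cv_result> mean +/- SD over 5 folds
#>   sensitivity  0.788 +/- 0.223
#>   specificity  0.938 +/- 0.076
#>   precision    0.914 +/- 0.095
#>   bacc         0.863 +/- 0.112
```

The balanced accuracy is the mean of sensitivity (artifact windows found)
and specificity (clean windows kept), averaged over five held-out test
subjects; ~0.86 on this synthetic set means the network recovers the
injected artifact structure from the time–frequency tensors and
generalises across (statistically identical) subjects. Shuffling the
labels drives the same pipeline to ~0.5 — chance — which is the control
that the learning is real.

The revision loop on a deliberately corrupted gold standard (10% of labels
flipped, two perfect simulated raters):

```r
corr <- corrupt_labels(segs$segments, fraction = 0.1, seed = 19)
truth <- setNames(segs$segments$label, segs$segments$segment_id)
raters <- function(cand) {
  dec <- simulate_raters(unname(truth[cand$segment_id]),
                         rater_model(p_agree_true = 1, seed = 5))
  data.frame(segment_id = cand$segment_id, d1 = dec$rater1, d2 = dec$rater2)
}
cyc <- revision_cycle(feats$tensors, corr$segments, cfg,
                      revision_config(), raters, epochs = 10)
```

The network, trained on the corrupted labels, flags most of the flips in
its confident-disagreement bands; the merged rater decisions restore their
true labels, and the retrained model scores higher against the ground
truth than the pre-revision one.

## Formats

Recordings: JSON header + little-endian float32 array (+ annotation CSV).
Annotations / segments / predictions / rater decisions / traces: plain CSV
with documented columns. See the methods vignette
(`vignettes/artifact-annotation.Rmd`) for the model, the design decisions
and the limitations of the synthetic benchmark.
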