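---
title: "Decoding motor imagery from EEG with spatial-frequency energy maps and small CNNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery from EEG with spatial-frequency energy maps and small CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfcnn)
```

## The decoding problem

Imagining a movement attenuates the band-limited oscillations (mu, ~8–14 Hz;
beta, ~18–26 Hz) recorded over sensorimotor cortex, predominantly
contralateral to the imagined limb — event-related desynchronization (ERD).
A binary motor-imagery decoder therefore has to find *where* (which
electrodes) and *in which narrow band* power drops, against a background
whose broadband 1/f power dwarfs the rhythm of interest and whose reactive
band differs between subjects.

`sfcnn` implements a two-stage answer: a deterministic transform that makes
the spatial-frequency structure explicit (energy maps), and a deliberately
small convolutional network whose first layer is constrained to learn pure
spatial filters, so the fitted model remains physiologically interpretable.

## The energy-map transform

For each trial the pipeline applies, in order:

1. **Filterbank.** `make_filterbank(low, high, width, overlap)` tiles the
   analysis range with equal-width bands advancing by `width - overlap`.
   The default, `make_filterbank(8, 30, 4, 2)`, yields ten overlapping 4-Hz
   bands; the cross-validation configuration `make_filterbank(4, 40, 6, 0)`
   yields six disjoint 6-Hz bands. Overlap matters because the subject's
   reactive band rarely aligns with bin edges; 2-Hz hops localize it to
   within a band-width.
2. **Zero-phase bandpass.** Each band is a 4th-order Butterworth applied
   forward and backward. The forward-backward core is algorithmically
   identical to `signal::filtfilt` (a unit test asserts bit-level
   agreement), vectorized over channels; before filtering, the signal is
   extended at both ends by odd reflection over roughly three ring times of
   the band (≈ 3 / bandwidth seconds), which suppresses the edge transients
   the plain zero-padded scheme leaves behind. Filtering precedes
   windowing, so whatever transients remain fall outside the analysis
   window.
3. **Windowing.** The cue-locked window (default 0.5–2.5 s after cue onset)
   is cut from the filtered signal. Windows are half-open in 0-based sample
   indices with bounds rounded to the nearest sample, so 2 s at 1000 Hz is
   exactly 2000 samples.
4. **Log-variance energy.** Each (channel, band) cell becomes
   `ln(var(x))` with the *population* variance (divide by N) and the
   natural logarithm. Nothing downstream depends on either convention: a
   different log base or variance divisor rescales or shifts every cell
   affinely, which the next step absorbs. Variances below 1e-12 are floored
   (with a warning) so degenerate inputs cannot produce `-Inf`.
5. **Per-cell z-scoring.** Cell (i, j) is centred and scaled by the mean
   and population standard deviation of that cell across the *training*
   trials. Fitting the statistics on all trials — the literal reading of
   "all samples" — leaks test information into the transform; the package
   fits on the training partition by default and offers
   `normalization_scope: all` as the literal mode. Cells whose standard
   deviation falls below 1e-8 keep scale 1 (with a warning) instead of
   exploding.

The result is a channels × bands matrix per trial, electrodes along the
vertical axis — the "image" the networks consume.

## The two architectures

Both networks share one skeleton, differing only in activations, the second
kernel width and the dense stack:

| | base | cross-validation variant |
|---|---|---|
| input | n<sub>ch</sub> × 10 | 49 × 6 |
| C1 | 6 kernels n<sub>ch</sub> × 1, stride 1, ReLU | 6 kernels 49 × 1, Elu |
| C2 | 12 kernels width 2, stride 2, ReLU | 12 kernels width 3, stride 2, Elu |
| flatten | 60 (on 21 × 10) | 24 |
| dense | 50 ReLU | 50, 100, 200 ReLU |
| output | dropout 0.5 → softmax 2 | dropout 0.5 → softmax 2 |

Design notes, where the architecture description admits more than one
reading:

* **C1 is a pure spatial projection.** Its kernels span the full electrode
  axis and a single band, so each C1 output value mixes channels but never
  bands — the reason its weights can be read as spatial filters
  (`extract_spatial_filters()`).
* **C2 kernel depth.** A "width 2" C2 kernel takes two adjacent band
  positions from *all six* C1 maps (standard multi-channel convolution with
  implicit depth 6); likewise width 3 in the variant.
* **C2 stride in the variant.** With input width 6, kernel width 3 and
  valid padding, an output width of 2 forces stride 2 or 3; stride 2 is
  used, consistent with the base network's stride.
* **Dropout placement.** "Before the output layer" is implemented as a mask
  on the activations feeding the softmax layer, in both variants (dropout
  is retained for the cross-validation variant and can be disabled via
  `dropout_rate = 0`).
* **Elu** uses α = 1.
* Valid padding throughout: `conv_output_width(w, k, s) = floor((w - k)/s) + 1`.

The forward pass, softmax (computed with the max-logit shift — identical
mathematically, stable numerically) and cross-entropy (predictions clipped
at 1e-12) are hand-written, as is backpropagation. The test suite checks the
forward pass against an independent nested-loop implementation (24 random
parameter draws across both variants, tolerance 1e-5) and the analytic
gradients against central finite differences (relative error below 1e-4), so
the vectorized implementation is never the only witness to its own
correctness.

## Training and model selection

Training follows the full-batch policy: every iteration computes the mean
cross-entropy over the *entire* training set and performs exactly one
parameter update (`n_updates` is recorded and asserted in tests). Weights
initialize from N(0, 0.1²), biases at 0.1, reproducibly from a seed.
Optimizers: Adam (default learning rate 1e-3, β₁ = 0.9, β₂ = 0.999) or
Adadelta (learning rate 1.0, ρ = 0.95) — the learning rates are not pinned
down by the protocol, so the optimizers' conventional defaults are used and
remain configurable. The default iteration budget is 2000; the iteration at which a real
session converges is subject-specific (often on the order of 1500--2000
full-batch updates), so the budget is a ceiling combined with
validation-based selection rather than a constant.

Dropout (rate 0.5) is active only in the training-step forward pass: a kept
unit passes through unscaled, and at inference every activation is scaled by
1 − rate — the classical weight-correction pairing. During training the
mask is drawn per iteration per sample from a dropout-specific RNG
substream; init, dropout, splits and simulation all derive independent
substreams from one master seed, so each component is reproducible in
isolation.

The returned parameters are those of the iteration with the highest
validation accuracy, earliest iteration on ties. With very small validation
sets (a handful of trials) this selection is noisy — an early lucky
iteration can win — which is a property of the protocol itself, visible in
the training-history tibble (`tidy(fit)`).

Argmax prediction ties break toward the lower class index (documented, and
only reachable with exactly equal probabilities).

## Evaluation protocols

* **Fixed split.** `fixed_split(n, n_train, n_test, n_val, ordered)` slices
  train, then test, then validation — sequentially in `ordered` mode (the
  260/10/10 convention for a 280-trial session) or after a seeded
  permutation (the ~80/10/10 convention for small sessions).
* **10-fold CV.** Folds are stratified by class: within each class, indices
  are shuffled (seeded) and cut into contiguous blocks, so folds are
  class-balanced, disjoint and exhaustive — every trial is tested exactly
  once. Within each fold the remaining nine parts split 90/10 into
  training and validation (validation floored at one trial). Normalization
  statistics are refitted on each fold's training portion only; a
  `fit_stats_on = "all"` switch reproduces the literal single-normalization
  reading. A fold whose training portion lost a class entirely is flagged
  with a warning rather than silently mistrained.

A pipeline-level test asserts the no-leakage property directly: perturbing
only the held-out partition of an archive leaves the trained checkpoint
byte-identical.

## The synthetic ERD generator

`sim_spec()` + `simulate_dataset()` generate the statistical structure the
method assumes, nothing more:

* every channel carries 1/f-shaped Gaussian background noise (spectral
  shaping in the frequency domain; slope = `noise_exponent`, default 1,
  scale 5 µV);
* designated ERD channels add a band-limited rhythm — narrowband-filtered
  Gaussian noise in `erd_band` (default 10–14 Hz), normalized to unit
  standard deviation and scaled by `rhythm_amplitude` (default 10 µV).
  Filtered noise rather than a sinusoid keeps per-trial band power
  realistically variable and avoids degenerate zero-variance cells;
* in MI trials the rhythm amplitude is multiplied by `1 - erd_depth`
  (default depth 0.5) *after the cue only*, so the pre-cue segment is
  distributed identically in both classes and the informative region is
  exactly what the cue-locked window should find.

The default geometry mirrors a small finger-imagery recording: 21 channels
at 1000 Hz, 4-s trials, cue at 1 s, ERD confined to one "C3-like" channel
(index 9). Because variance scales with amplitude squared, the expected
MI-minus-rest log-variance gap at the ERD cell is exactly
`2 ln(1 - depth)` in the low-noise limit (`theoretical_logvar_gap()`), which
the tests use as a closed-form oracle: at depth 0.5 with background at 1% of
the rhythm, the empirical gap over 200 trials matches −1.386 within 0.05.

What the generator deliberately does **not** emulate: volume conduction
(channels are independent by default; an optional `mixing` matrix is
provided for harder tests), ocular/muscular artifacts, non-stationarities,
multi-band or bilateral ERD topographies, and continuous recordings.
Passing the recovery tests therefore demonstrates that the implementation
decodes the structure it assumes — not that it attains any particular
accuracy on recorded EEG.

## Numerical choices, sizes and limitations

* Butterworth order 4; bandpass edges must lie strictly inside
  (0, Nyquist). Direct-form IIR recursion with poles near the unit circle
  limits exact linearity of the filter to ~1e-6 relative; the
  scale-equivariance test (scaling a trial by c shifts every unnormalized
  cell by 2 ln c) therefore asserts at 1e-4.
* Cross-entropy clip 1e-12; variance floor 1e-12; normalization degeneracy
  threshold 1e-8.
* Recovery experiments in the test suite run at sizes a workstation
  handles in minutes: the end-to-end experiment uses the full 280-trial
  session geometry (140 trials per class, depth 0.6, seeded 80/10/10
  split, ≤2000 full-batch iterations, held-out accuracy ≥ 0.9 plus a
  label-shuffled control); spatial-filter localization uses 50 trials per
  class over three seeds (a majority must place a C1 peak on the ERD
  channel); structural CV tests use 40 trials per class at 5 folds.
* The 49-channel electrode subset used with the public 118-channel
  competition dataset is not enumerated in the protocol description; it is
  supplied via the configuration (`preprocess$channels`), never hard-coded,
  and nothing in the package depends on the specific montage.
* Only binary classification is supported; there is no artifact handling,
  re-referencing, or vendor-format parsing — trials enter as plain
  matrices or the delimited-text container.
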