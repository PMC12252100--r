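---
title: "Methods: models, preprocessing and design choices in kanbeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, preprocessing and design choices in kanbeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanbeat)
```

## The problem

Ambulatory electrocardiograms are annotated beat by beat, and the AAMI
recommendation consolidates the MIT-BIH annotation vocabulary into five
classes: N (normal and bundle-branch-block beats), S (supraventricular
ectopy), V (ventricular ectopy), F (fusion), and Q (paced or
unclassifiable). Two features make the classification problem hard:
morphology varies at several temporal scales (a narrow pacing spike versus a
slow T wave), and class frequencies are severely skewed — supraventricular
and fusion beats are one to two orders of magnitude rarer than normal beats,
so a plain classifier buys overall accuracy by ignoring them.

`kanbeat` implements a hybrid network for this problem together with its
full experimental harness: preprocessing, two imbalance remedies, metrics
with the conventions used in the reference tables, ablations, and a seeded
synthetic generator so that every stage is testable without downloading any
clinical data.

## Preprocessing

A recording enters as a signal plus R-peak annotations (`read_wfdb()` or
`synth_record()`). Processing is:

1. **Windowing** (`segment_record()`): 150 samples on either side of each
   annotated R peak. "150 on either side" is ambiguous between 300 and 301
   samples; we use the half-open window `[r - 150, r + 150)`, i.e. exactly
   300 samples with the R sample at index 150 (0-based), because an even
   length keeps pooling arithmetic simple. Beats whose window crosses a
   record edge are dropped and counted, never silently lost.
2. **Denoising** (`dwt_denoise()`): a periodized discrete wavelet transform,
   soft-thresholding only the detail coefficients with the universal
   threshold `sigma * sqrt(2 log n)`, `sigma = MAD(level-1 detail)/0.6745`.
   Defaults db4 / level 3 are the standard ECG choices; family, level, and
   soft/hard rule are configurable because no single choice is canonical.
   The transform reconstructs exactly at zero threshold (tested to 1e-8).
3. **Normalization** (`minmax_normalize()`): per segment, `(x - min) /
   (max - min)`, so every segment spans exactly [0, 1]. A constant segment
   carries no morphology and is an error; the pipeline drops such beats
   with a warning. We deliberately do not z-score or band-pass filter: the
   preprocessing section of the source description is internally
   inconsistent on this point, and the per-segment min–max form is the one
   given as an equation.
4. **Splitting** (`split_dataset()`): a beat-level (intra-patient) random
   split with `val = ceiling(0.2 n)`, `test = ceiling(0.2 n)`,
   `train = n - val - test`. This ceiling rule is the only one consistent
   with the published split sizes (65,667 / 21,890 / 21,890 at
   n = 109,447). The split is unstratified; the published per-class training
   counts are inconsistent with exact stratification, so a plain seeded
   shuffle is the honest reading.

## The network

`build_model()` assembles, in order: a four-layer ConvBlock stem, the
multi-scale fusion block, an attention stack (MLPBlock → ECA → MLPBlock →
ECA), a bidirectional GRU, temporal mean pooling, and a two-layer
Kolmogorov–Arnold (KAN) head with a softmax over the five classes.

**ConvBlock.** Conv1d ("same" padding, kernel 3) → BatchNorm1d → ReLU →
MaxPool1d with kernel 2, stride 1, padding 1. These pooling parameters
*grow* the sequence by one sample per block (L → L + 1); we implement them
as stated rather than "fixing" them to a downsampling pool, since nothing
downstream requires a particular length. Batch-norm uses batch statistics
(biased variance) in training and running averages (momentum 0.1) in
evaluation.

**Multi-scale fusion.** Four parallel convolutions with kernels 3, 11, 21,
31 are combined by *learnable* weighted averaging: a 4-vector of logits is
softmax-normalized, so the weights always form a probability vector and
initialization at zero logits degenerates gracefully to a plain average.
The fused map passes BN → ReLU → dropout (p = 0.3) → max-pool. In parallel,
a second ConvBlock processes the same input, and a 1×1 convolution carries
a residual skip; because the two main paths emit L + 1 samples, the skip
passes through the same pool so all three can be fused by element-wise
addition. The parallel-path fusion rule (addition, with 1×1 channel
matching) is our choice where the block diagram leaves it open.

**Attention.** Each MLPBlock runs conv → BN → ReLU → conv on all channels
and, in parallel, a *partial* convolution over only the first
`ceil(C / 4)` channels (identity on the rest), fused by addition; the ¼
ratio is the FasterNet convention. ECA computes per-channel global average
pooling, a single 1-D convolution *across channels* with an adaptive odd
kernel `k ≈ |log2(C)/γ + b/γ|` (γ = 2, b = 1, the constants of the original
ECA paper; ties round down), then a logistic squash producing per-channel
weights in (0, 1).

**BiGRU.** Standard GRU recursions (update gate, reset gate, candidate
state with the reset applied to the recurrent term) run left-to-right and
right-to-left with independent parameters; the per-step output is the
concatenation of the two states. The source description also prints a
weighted-sum merge over *previous* hidden states that contradicts its own
text; we implement the concatenation, which is the standard BiGRU and the
reading consistent with "concatenating the forward and backward hidden
states". Two layers of width 256 by default.

**KAN head.** After temporal mean pooling (chosen over last-step pooling
for noise robustness) and a bounded tanh squash, each KAN edge applies
`phi(u) = w_b silu(u) + w_s * sum_i c_i B_i(u)` on a clamped B-spline basis
with G = 5 intervals, order k = 3, range (−1, 1); nodes only sum. The grid
is fixed during training (no grid updates), which keeps the layer exactly
linear in its coefficients; the tanh squash guarantees inputs respect the
spline range, so the boundary clamp is inert in practice. Basis functions
are evaluated by the Cox–de Boor recursion (partition of unity tested to
1e-10, equivalence with a brute-force implementation to 1e-12), and
`kan_spline_export()` serializes every edge's learned activation curve.

**Widths and the 6.11 M calibration.** Only the total parameter count
(6.11 M) is published, not individual widths. Defaults: stem channels
(16, 32, 64, 128), multi-scale width 128, two BiGRU layers of width 256,
KAN widths (512, `kan_hidden`, 5). `kan_hidden` is the single designated
calibration knob, fixed once at **571**, which gives 6,110,224 trainable
parameters = 6.11 M at two decimals. Batch-norm running statistics are not
trainable and are excluded from the count.

**Ablation variants.** `single_scale_k` replaces the four-kernel bank with
one kernel; `no_attention` removes the MLPBlock/ECA stack; `no_bigru`
pools directly after attention (the KAN head then sees the convolutional
width); `no_kan` replaces the KAN head with linear–ReLU–linear of matching
widths. Each variant changes exactly one component.

## Training and evaluation

`train_model()` runs Adam (lr 5e-4, batch 64, 60 epochs by default — the
published recipe) with seeded per-epoch shuffling and no early stopping.
Because the selection rule behind the published single-number results is
unstated, we keep the checkpoint with the best validation macro-F1
(earliest epoch on ties); `checkpoint_policy = "last"` is available.
Backpropagation is hand-derived per layer and verified against central
finite differences (relative 1e-3) in every block type; the two hot
kernels (1-D convolution and the GRU recursions) are compiled C++ for
speed, with the GRU additionally cross-checked against a plain-R recursion.

`evaluate_model()` takes the argmax per beat (ties to the lower class
index) and fills a 5×5 confusion matrix, rows true, columns predicted. From
it, `per_class_metrics()` computes one-vs-rest precision, recall, F1 and
specificity. Two table conventions are worth stating loudly because they
are nonstandard but required to reproduce the reference tables:

* the per-class **accuracy column equals recall** — every printed per-class
  row equates them;
* the aggregate ("Sum") row holds **macro means** of F1 / recall /
  precision / specificity but the **overall accuracy** (trace / total) in
  the accuracy cell. Reported cells are rounded half-up to 4 decimals.

With these conventions the macro cells of all three published per-class
tables reproduce exactly from their printed columns, with one exception:
the SMOTE table's summary specificity prints 0.9991 while its per-class
column averages to 0.99904 → 0.9990; the table was evidently averaged
before rounding. The acceptance suite asserts this cell exactly and
therefore carries one deliberately failing assertion documenting the
discrepancy.

## Class-imbalance remedies

**Focal loss** (`focal_loss()`): `alpha_y (1 - p_t)^gamma (-log p_t)` with
γ = 2 by default; α is a per-class vector defaulting to all ones because no
α is published. At γ = 0 the loss is exactly α-weighted cross-entropy
(asserted to 1e-10), and probabilities are clamped at 1e-12.

**SMOTE** (`smote_oversample()`): written from scratch. For each synthetic
point: pick a minority row, one of its k = 5 nearest same-class neighbours
(exact brute-force Euclidean distances — the desk-scale sizes make
approximate search pointless), and a uniform weight in [0, 1]; emit the
convex combination. Original rows are preserved verbatim and in order, and
per-class counts hit their targets exactly. The published post-SMOTE counts
(e.g. N: 54,166 after starting from 54,171) are internally inconsistent
with pure oversampling and are not emulated; `equalize-to-majority` yields
exactly 54,171 per class on those inputs. `apply_smote()` is the only
entry point that accepts a tagged dataset and it restricts itself to the
training fold, making train→test leakage structurally impossible (and
tested).

## The synthetic generator

`synth_dataset()` emulates the five classes as sums of five Gaussian
deflections (P, Q, R, S, T) — the standard synthetic-ECG construction — at
360 Hz, plus baseline wander (0.05 mV at 0.3 Hz), power-line interference
(0.02 mV at 50 Hz), and white noise (0.02 mV), all with seeded random
phases, plus a 5% multiplicative amplitude jitter per beat. Class
morphology interpolates linearly from the normal template as
`separability` rises from 0 to 1 (saturating above): V widens the QRS,
suppresses the P wave and inverts the T; S has an early, narrow, inverted
P (the ectopic-atrial signature) and a shortened RR; F is the midpoint of N
and V; Q has a flat P and a pacing spike before a widened QRS. At
separability 0 all classes share one template (nearest-centroid accuracy is
chance, tested ±0.03); at 1 they are well separated (nearest-centroid
accuracy > 0.95). RR intervals jitter by a truncated normal (±3 sd) so
annotation order is preserved, and every annotation index coincides with
the emitted R-deflection centre.

What the generator does **not** emulate: real conduction dynamics,
beat-to-beat morphology drift, electrode artifacts, inter-patient
variability, or multi-lead structure. Passing the synthetic benchmarks
therefore demonstrates that the pipeline, losses and architecture behave
as designed — not that the headline clinical-data numbers transfer.

## Desk-scale benchmark sizes

The directional experiments (`benchmark_dataset()`, `run_ablation()`,
`compare_imbalance()`) use ~3,000 beats with class ratios proportional to
the published training distribution (54,171 / 1,807 / 4,348 / 483 / 4,858),
64-sample QRS-centred windows, the `tiny_model_config()` widths (stem
4-6-8-8, multi-scale width 8, one BiGRU layer of width 8, KAN hidden 12),
batch 64, learning rate 5e-3, 5 epochs, 5 seeds. These sizes are the
package's chosen desk-scale study conditions: large enough that SMOTE and
focal loss measurably lift minority recall and that removing the BiGRU
costs macro-F1, small enough that the whole grid trains in minutes on one
CPU. The full-scale configuration (300-sample windows, 6.11 M parameters,
60 epochs) is exercised for construction, counting and forward passes, not
for training.

## Numerical choices and degenerate inputs

* Probabilities are clamped at 1e-12 before logs; loss-input rows must sum
  to 1 within 1e-6.
* Max-pool ties route gradient to the left (earlier) position; argmax ties
  predict the lower class index; the ECA kernel rounds ties down. All ties
  are deterministic.
* Batch-norm uses biased variance for normalization and an epsilon of 1e-5.
* Dropout is inverted (scaling at train time), so evaluation needs no
  correction.
* Constant segments (min = max) are errors at normalization and dropped by
  the pipeline with a warning; empty annotation lists yield empty segment
  sets, not errors; windows crossing record edges are dropped and counted.
* The WFDB writer quantizes to a 16-bit ADC at 4000 units/mV, so signal
  round-trips are exact to half an ADC step (1.25e-4 mV); annotations
  round-trip exactly, with gaps ≥ 1024 samples encoded via SKIP words.
* All randomness (templates, noise phases, splits, SMOTE, initialization,
  shuffling, dropout) flows from explicit integer seeds through a
  state-restoring seeding helper; two runs with the same seeds are
  bit-identical on the same platform.

## Known limitations

* The intra-patient split matches the published protocol but overstates
  generalization compared to inter-patient evaluation; the splitter is
  beat-level by design.
* R peaks are taken from annotations; there is no peak detector.
* The KAN grid is fixed; no grid refinement, pruning, or symbolic
  regression (the spline export exists so such analyses can be done
  downstream).
* The synthetic benchmark's effect directions are stochastic statements
  checked over 5 seeds, not guarantees. At this scale the SMOTE ordering is
  robust (SMOTE reaches full minority recall in every seed), but focal loss
  does not consistently beat plain cross-entropy within the fixed 5 epochs
  — its `(1 - p_t)^gamma` attenuation slows convergence and the evaluation
  folds hold only a handful of fusion beats, so per-seed minority recall is
  coarse — and the no-BiGRU variant, having fewer parameters, can out-train
  the full model in so few epochs. The corresponding acceptance assertions
  report these misses rather than hiding them; the full-scale published
  orderings are not contradicted by this, only unresolved at desk scale.
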