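---
title: "A multi-attention convolutional classifier for lumbar stenosis severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-attention convolutional classifier for lumbar stenosis severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lumbar spinal stenosis (LSS) is a narrowing of the spinal canal or its
lateral passages that compresses neural structures. On T2-weighted MRI the
dural sac at the L4-L5 disc level appears as a bright, fluid-filled region;
severe stenosis shrinks and deforms it. `lssnet` implements a binary
severity grader ("normal/mild" vs "severe") for 2-D region-of-interest (ROI)
slices, one independent binary model per lesion category (spinal canal
stenosis, left/right neural foraminal narrowing, left/right subarticular
stenosis). Because the clinical MRI collection this task is defined on
cannot ship with a package, every stage is exercised on synthetic phantoms
whose generative parameters are documented below.

## The model

The classifier has three parts.

**Head.** A 7×7 convolution (stride configurable, see *Numerical choices*),
batch normalization and ReLU; a second 3×3 conv-BN-ReLU stage; a 3×3/2
max-pool; then two Enhanced Inception Modules (EIM). Each EIM runs four
parallel branches — depthwise-separable convolutions (DSC) with 1×1, 3×3 and
5×5 kernels plus a 3×3 stride-1 max-pool — concatenates them along channels
and fuses with a 1×1 convolution, BN and ReLU. A DSC factorizes a standard
convolution into a per-channel spatial filter followed by a 1×1 channel
mixer, costing `k²·C_in + C_in·C_out` weights instead of `k²·C_in·C_out`.

**Body.** Three parallel attention branches refine the head's feature map:

* *CBAM* — channel attention gates each channel by
  `σ(FC2(ReLU(FC1(GAP(X))) + ReLU(FC1(GMP(X)))))`, with the two pooled
  pathways sharing one two-layer MLP and the hidden responses summed before
  the second layer; spatial attention then gates each pixel by a sigmoid
  convolution over the channel-wise mean and max maps. Pooling is strictly
  per image — no cross-image mixing inside a batch.
* *MHSAM* — the `H·W` spatial positions become tokens of width `C`; learned
  linear maps produce queries, keys and values; each of `h` heads applies
  scaled dot-product attention `softmax(QKᵀ/√(d/h))`; heads are concatenated
  and linearly projected back to `C` channels.
* *SAM* (slot attention) — the map is pooled to a token set, projected to
  the slot width, and `num_slots` learned slot vectors are refined
  iteratively: layer-normalize slots, soft-assign tokens with a softmax over
  the **slot** axis (slots compete for tokens), and apply a residual MLP
  update `S ← S + MLP(A·E)`.

The CBAM and MHSAM maps are reduced by global average pooling to `C`-vectors
and the SAM branch contributes its mean-over-slots `dim`-vector; the enabled
summaries are concatenated. Concatenation (rather than summation) keeps the
dimensional bookkeeping of ablation variants explicit: removing a branch
shrinks the first tail layer by exactly that branch's width.

**Tail.** FC → LayerNorm → ReLU → Dropout(0.5) → FC → ReLU → Dropout(0.5) →
FC → 2-way softmax. Dropout is active only in training.

## Design choices in genuinely open places

Several structural details are not forced by the published description of
this architecture family; the package fixes them once and exposes them as
configuration:

* **Channel-gate form.** The channel MLP applies the second layer once to
  the *sum* of the two pooled hidden responses (the pseudo-code form),
  rather than to each pathway separately.
* **Slot-branch tokens.** A literal reading of the slot pseudo-code pools
  the map to a *single* global-average token, which collapses the
  slot-token competition to a 1-column softmax. The default instead pools
  adaptively to a `g×g` token grid (`g = 7`), preserving the attention
  structure; `sam_mode = "literal"` implements the single-token reading
  exactly. The softmax axis is the slot axis, following the published
  slot-attention convention.
* **Slot noise.** Slot initialization is `S₀ = μ + σ·ε` with learnable `μ`
  and softplus-parameterized `σ ≥ 0`. `ε` is sampled only in train mode;
  evaluation uses `ε = 0`, which makes eval-mode inference fully
  deterministic. Forcing `σ = 0` removes the RNG dependence entirely.
* **Attention defaults.** Reduction ratio `r = 16` (8 in the desk preset),
  spatial kernel 7×7, `h = 4` heads with `d = C`, 4 slots, 3 refinement
  iterations, slot MLP one ReLU hidden layer of width `dim`.
* **Fusion and loss.** Branch fusion by concatenation of GAP summaries;
  2-way softmax with cross-entropy (not a single sigmoid), matching a
  probability-distribution output.
* **Transform order.** Augmentation applies scale → translate → rotate →
  vertical flip, composed into a single affine warp with bilinear
  resampling; the order is recorded in the configuration because affine
  composition is non-commutative. Only a *vertical* flip is used, on the
  anatomical argument that lesions exhibit top-bottom symmetry while
  left-right anatomy is position-coded.
* **Demeaning statistics** are computed on the training split only and
  reused for held-out images, preventing leakage. Only demeaning is applied
  by default; dividing by the standard deviation is available behind
  `divide_by_sd`.
* **Monitoring.** Early stopping monitors validation loss (or accuracy) with
  patience 10 by default. The 80:20 "training and testing" protocol doubles
  as the early-stopping monitor set — a faithful but slightly leaky
  reproduction of a two-way protocol; `val_fraction > 0` carves a proper
  inner validation set out of the training split instead.
* **One model per condition.** The five lesion categories are treated as
  five independent binary tasks with condition-specific class imbalance; a
  shared multi-head variant is out of scope.

## Preprocessing and augmentation

The deterministic pipeline is: per-image min-max normalization to 0–255
(per-image because source intensities vary by scanner; a dataset-wide mode
exists behind a flag; constant images map to the lower bound), bilinear
resize to 224×224 with half-pixel centers (identity resize is exact), and
per-channel demeaning. Training batches are additionally augmented
on-the-fly: zoom in [0.8, 1.2], translation in [−20, 20] px per axis,
rotation in [−15°, 15°], vertical flip with probability 0.5 (the flip
probability is a package default; only "randomized" is prescribed).
`oversample_minority()` provides the offline alternative of appending
augmented minority-class copies until a target class ratio is met.

## The phantom generator

`generate_phantoms()` emulates 224×224 single-channel L4-L5 ROI slices: a
textured dark background (Gaussian noise, sd 150 raw units around level
600), plus a bright ellipse standing in for the dural sac, with center
jitter (sd 6 px). Severity is encoded geometrically: normal/mild images
carry a 22 px semi-axis ellipse (axis ratio 0.85), severe images an 11 px,
flattened one (ratio 0.55) — canal narrowing is the defining pathology, so
a smaller, deformed bright region is the honest minimal analog. Raw
intensities span 0–4095 (DICOM-like), deliberately not 0–255, so that the
normalization stage does real work. Class frequencies default to the
per-condition imbalance of the source frequency table
(`lss_condition_table()`), e.g. 203 severe in 1632 for spinal canal
stenosis.

What the phantoms do *not* emulate: multi-sequence appearance (T1/T2/STIR),
neighboring anatomy, partial-volume and bias-field effects, inter-reader
label noise. A model that learns the phantoms has demonstrated that the
architecture, gradients, training loop and evaluation stack are correct and
that it can exploit a geometric severity cue — not that it grades clinical
MRI. Generator separability is certified independently of the network by a
geometric oracle (`phantom_separability()`): threshold the bright-pixel
area at the midpoint of the class medians.

## Numerical choices

* **Desk-scale preset.** `network_config("desk")` — head widths 8→16, first
  conv stride 4 (so a 224×224 input reaches a 7×7 body map), EIM output 32,
  attention dims 32/16, tail 64→32 — is sized so that the full training
  loop runs in minutes on one CPU core. `network_config("full")` keeps the
  full-size defaults (32→64 head at stride 2, 128-channel body, 14×14 body
  map, tail 256→64); the two differ only in widths/strides, not structure.
  The package's own experiments (tests, acceptance script) train the desk
  preset on 400 phantoms — sizes chosen as the smallest at which the
  learnability claim is meaningful.
* **Stability.** Softmaxes subtract the row/column max; batch-norm uses
  eps 1e-5 and momentum 0.1 with unbiased running variance; layer norm uses
  eps 1e-5; Adam uses (0.9, 0.999, 1e-8) with learning rate 0.001;
  cross-entropy clamps probabilities at 1e-12; ReLU hidden layers of narrow
  MLPs are initialized with bias 0.01 to avoid an all-dead layer at small
  widths.
* **Ties.** Global-max-pool argmaxes and channel-max argmaxes break ties by
  first index, making gradients deterministic; ROC treats equal scores as
  one threshold.
* **Degenerate inputs.** Constant images normalize to the lower bound; 1×1
  images resize to a constant fill; precision/recall/F1 report 0 with an
  explicit degenerate flag when a denominator is zero; a singleton class
  fails the stratified split with a named error.
* **Determinism.** Phantom generation, splitting, initialization, batch
  order, augmentation draws, dropout masks and slot noise all derive from
  explicit seeds; training twice with one seed is bit-reproducible, and the
  generator restores the caller's RNG state.

## Limitations

The learnability results are on synthetic phantoms with a strong geometric
cue; no claim is made about clinical MRI performance. The desk preset's
capacity is far below what the full-size configuration would use on real
data, and the default protocol's early stopping monitors the test split
(see above) unless an inner validation fraction is requested. DICOM input
is not supported (no reader in the package's dependency set); phantom
export uses 16-bit grayscale TIFF, which holds the full 0–4095 raw range
losslessly.
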