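---
title: "Methods: diagonal-axial MLP segmentation networks in R"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagonal-axial MLP segmentation networks in R}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by **pisnet**, the design
decisions behind it, the numerical conventions, and what the synthetic
data generator does and does not emulate. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The model

The network is a five-stage encoder–decoder for binary segmentation of
single- or three-channel medical images. Stages 1–3 are convolutional
(3×3 convolution, batch norm, 2×2 max pool, ReLU) at widths 16/32/128;
stages 4–5 are tokenized MLP stages at widths 160/256, entered through
stride-2 3×3 token projections with a channel-wise layer norm. The decoder
mirrors the encoder (3×3 convolution, batch norm, bilinear ×2 upsampling,
ReLU) with additive skip connections, and a 1×1 head emits one logit per
pixel. Skip connections are additions, not concatenations: this keeps the
decoder widths equal to the encoder widths, which is what makes the
parameter budget of the MLP family small.

### The diagonal-axial block

Each MLP stage applies a residual token mixer. Channel-wise layer norm is
followed by a grouped *height shift* (five contiguous channel groups
translated vertically by −2…+2 pixels with zero fill), a pointwise linear
(the tokenized projection: each pixel is a token), batch norm and GELU, a
depthwise 3×3 convolution acting as an implicit positional encoding, and
then the block's distinguishing step: the map is translated along *both
diagonals* — up-and-right and up-and-left — by half an adaptive window,

    window = max(1, floor(floor(sqrt(H * W)) / 4)),   s = floor(window / 2),

the two translated copies are concatenated to 2C channels, and a fusion
linear maps them back to C before the residual addition. Because the shift
distance is half the window, windows at successive positions overlap, so
local windows exchange information along both diagonal axes without any
attention weights; the diagonal branches themselves are parameter-free.
One block costs 3C² + 16C parameters. The baseline variant (2) instead
uses the single-branch axial form (shift along width before the first
linear, along height before the second; 2C² + 14C parameters), so the
ablation isolates exactly the dual-diagonal mixing.

Two conventions here deserve note. The window formula is stated as an
adaptive function of the map size; we take one quarter of the *geometric
mean* side, which gives H/4 on square maps and degrades gracefully on
rectangles, and floor it so that tiny maps (window 1, s = 0) reduce the
diagonal branches to the identity rather than erroring. Channel groups for
the height shift follow ceil-sized chunking (52·4+48 at C = 256), so any
C ≥ 5 is usable.

In-block token projections are *pointwise* (1×1), not 3×3: pixels-as-tokens
is the convention of this model family, and a 3×3 in-block projection would
add 9C² per block — tripling the MLP-stage budget and breaking the
calibration described below. Spatial tokenisation with a 3×3 kernel is
used only between stages (the stride-2 patch embeddings).

### Hybrid downsampling

The stage-4→5 transition in variants 5 and 6 runs two parallel paths: the
linear path is the ordinary stride-2 token projection (160 → 256); the
nonlinear path max-pools by 2 and applies a depthwise-separable projection
(3×3 depthwise on 160 channels, pointwise 160 → 256, batch norm). The two
256-channel maps are concatenated and a 1×1 squeeze restores 256, so the
decoder mirror is untouched. The intent is multi-scale fusion: max-pooled
features keep sharp local extrema that strided linear projections average
away.

The package also exposes the module in its generic two-octave form
(`hbds_forward`): two stacked downsampling diagonal-axial blocks with
channel ratio 1:2 each (c → 4c, spatial /4) in parallel with max-pool +
one ratio-1:4 downsampling block, concatenated to 8c. Inside the network
we instantiate the single-transition form above instead: the architecture
has only one halving between its two MLP stages, and the two-octave form
cannot be inserted there without either deepening the network or inflating
the parameter budget several-fold. The generic module remains available
(and tested) for architectures with a full two-octave MLP stage.

### Dynamic residual spatial pyramid pooling

At the end of the encoder (variants 4 and 6), three stride-1 max-pool
branches run in parallel with kernels adapted to the bottleneck size:

    base = max(1, floor(floor(sqrt(H' * W')) / 4)),   k_i = odd(i * base),

with same-padding `floor(k_i / 2)` so all branches preserve the spatial
size (at a 16×16 bottleneck: 5/9/13; at 8×8: 3/5/7; at 2×2 — a 64-pixel
input — the rule degrades to 1/3/3 and still runs). Stride-1 pooling with
same padding is the standard resolution of the shape mismatch that a
strided pyramid would create at the concat; the pyramid contributes no
parameters. Each pooled branch passes a 1×1 projection, the residual
branch a 3×3 convolution, the four 256-channel maps are concatenated to
4C′ and fused back to C′ = 256 by a 3×3 convolution. We fuse to C′ rather
than keeping 4C′ so the decoder mirror is unchanged; both the residual
conv (vs. pure identity) and the fusion width are configurable at the
module level.

### The full model's cross-branch mixer

In the full model (variant 6) the 512-channel concatenation of the two
downsampling branches is token-mixed by one full-width axial-MLP block
*before* the squeeze. Rationale: downstream, DR-SPP pools the bottleneck
at three scales, and without a mixing step the pooled statistics of the
linear and nonlinear branches remain segregated in disjoint channel
blocks; a cheap full-width mixer lets the pyramid see cross-branch
features. The single-branch axial form is used deliberately — a
dual-diagonal block at 512 channels would concatenate to 1024 and double
the fusion cost. With it, the five hybrid variants span 1.47 M (baseline)
to 5.46 M (full model) trainable parameters; the exact per-variant totals
are recomputed by `scripts/acceptance.R` and asserted in the test suite.

### Calibration of the defaults

Stage widths are not free in this package: the default configuration
(widths 16/32/128/160/256, single input channel, 256×256) was calibrated
once so that the re-implemented baseline variant reproduces its published
1.47 M-parameter budget, and the remaining variants were pinned against
their published budgets the same way. That calibration fixed three
otherwise-open choices documented above: pointwise in-block projections,
the single-transition hybrid downsampler, and the full model's
cross-branch mixer. The calibration is an anchor, not a tuning knob; it
is asserted exactly (two decimals in millions) in `test-acceptance.R`.

## Training and evaluation

* Optimiser: Adam, β₁ = 0.9 (the standard reading of "momentum 0.9" for
  Adam), β₂ = 0.999, ε = 1e-8.
* Schedule: cosine annealing from 1e-4 to 1e-5 across the configured
  epochs, `lr(e) = min + (max − min)(1 + cos(πe/(E−1)))/2`; the initial
  rate at epoch 0 and the minimum exactly at the final epoch.
* Loss: `0.5·BCE + 1.0·Dice`. Probabilities are clamped to [ε, 1−ε]
  (ε = 1e-5) before logarithms; the Dice term uses the same ε as additive
  smoothing, under which an empty prediction of an empty mask has zero
  loss. The loss gradient is analytic (the BCE term's gradient is zeroed
  where the clamp is active) and chained through the sigmoid.
* Defaults are 400 epochs at batch size 8 with a seeded 8:2 split. There
  is no third split: validation during training uses the test partition,
  which is reported plainly and is the main caveat when reading training
  logs as generalisation estimates. The best-validation-Dice weights
  (including batch-norm running statistics) are retained; no early
  stopping.
* Evaluation thresholds probabilities at 0.5 (ties count as foreground),
  computes per-image IoU and Dice from TP/FP/FN with ε-smoothing, defines
  empty-vs-empty as perfect (1.0) — the conservative convention for
  lesion-free patches — and averages over images rather than pooling
  pixels.
* A non-finite training loss aborts immediately with a diagnostic rather
  than continuing on poisoned weights.

## Numerical conventions

* All tensors are `(H, W, N, C)` double-precision arrays; convolutions
  are computed as nine (or one) BLAS matrix products over shifted views,
  and every layer's backward pass is the exact adjoint of its forward —
  asserted against central finite differences (relative error ~1e-7) for
  the three graph families (U-Net, baseline, full model).
* Max-pool gradient routing uses first-maximum tie-breaking; the stride-1
  pyramid pools are computed separably (rows then columns) with −∞
  padding, and gradients are routed through both passes' argmaxes.
* Bilinear interpolation uses half-pixel centres with edge clamping,
  implemented as dense per-axis interpolation matrices; the backward pass
  is their transpose. The same kernels drive decoder upsampling and
  `resize_sample` (masks are resized by nearest neighbour and stay
  binary; per-axis scale factors are recorded so distortion remains
  recoverable).
* Zero-fill semantics everywhere content is translated (height shifts,
  diagonal shifts); the adjoint is the inverse translation.
* Weight init is He-scaled Gaussian (fan-in of the receptive field);
  norms start at scale 1, shift 0; all biases at 0. Batch norm uses
  momentum 0.1 running statistics, biased batch variance for
  normalisation, and unbiased updates of the running variance; evaluation
  mode uses running statistics, which is what makes `predict()`
  bit-deterministic.
* Input sizes must be divisible by 32 (16 for the U-Net variant): the
  encoder halves five times and the additive skips require exact shape
  agreement on the way back up. Within that constraint a built model
  accepts any input size — the shift-window and pyramid geometries are
  recomputed per forward pass.

## The synthetic data generator

Three presets emulate the modality *traits* that the architecture
targets, not the physics of the devices:

* `ultrasound_blob` — one or two smooth organic blobs (superlevel sets of
  random anisotropic Gaussian fields) darker than the background, under
  multiplicative speckle-like noise (default σ = 0.25); foreground
  fraction 2–15 %.
* `lesion_aspect` — one large smooth region on images whose native sizes
  are deliberately non-square (aspect ratio 1.3–2.2), so fixed-size
  resizing produces genuinely anisotropic scale factors; foreground
  10–40 %.
* `nuclei_field` — 30–200 small rotated ellipses with radius jitter;
  masks are the exact rasterised union of the analytic supports (the
  per-object pixel sets are retained for oracle tests); foreground
  5–20 %.

Generation is driven by a local RNG derived from the spec seed (the
global RNG stream is untouched), so identical specs are bit-identical.
Blob masks realise their target foreground fraction by rank-selecting
pixels of the smooth field, clamped into the preset band; nuclei reach
the band by rescaling radii over at most six rasterisation attempts.
Blobs being superlevel sets of smooth fields makes them learnable by a
small model within minutes, which is what the overfitting check needs.

What the generator does **not** emulate: physically realistic speckle
statistics, stain variation in histology, calibrated contrast, anatomy,
or annotation noise. A model passing every test here has demonstrated
correct mechanics and the capacity to fit organic shapes — not clinical
performance on real ultrasound, dermoscopy or H&E data.

## Problem sizes in the shipped checks

The test suite runs entirely on synthetic data at sizes chosen to keep a
full run in the low minutes on one CPU core while still exercising every
code path: gradient checks on 32×32 inputs with 5–10-channel stages;
shape and oracle checks on maps from 4×4 to 256×256; the overfitting
check trains a width-reduced full model (widths 8/12/16/20/32) on
sixteen 64×64 speckle-blob images for 300 steps at learning rate 3e-3
and requires train Dice ≥ 0.95 and a smoothed (51-step moving average)
monotone-decreasing loss curve. The patch-slicing check generates 44
synthetic 1000×1000 tiles and verifies the 256/128 window/stride grid
arithmetic (36 patches per tile).

## Known limitations

* Pure-R tensor math is fast enough for desk-scale experiments (a
  300-step run of the reduced full model takes a few minutes) but not
  for full-resolution training at 400 epochs on real datasets.
* Binary segmentation only; one logit head, no multi-class or deep
  supervision.
* The U-Net variant is a standard bilinear-decoder implementation kept
  as a reference point; its parameter count (~31 M) is not calibrated
  against any external figure.
* JPEG input requires the optional EBImage package; PNG and TIFF are
  read natively.
* Batch-norm statistics make training-mode forward passes batch-size
  dependent (as usual); only evaluation mode is guaranteed
  bit-deterministic.
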