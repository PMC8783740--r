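---
title: "Counting tree crowns by density regression with a shifted-window transformer U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting tree crowns by density regression with a shifted-window transformer U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swincount)
```

## The problem

Olive plantations — and orchards generally — cover areas far too large for
manual tree inventories, and very-high-resolution overhead RGB imagery
resolves individual crowns as small bright-tipped blobs trailing shadows.
Counting them automatically is harder than it looks: crowns vary in scale,
tiles differ in orientation and perspective, some plantings are widely
spaced while young trees stand almost crown-to-crown, and bright non-tree
objects (buildings, rock, machinery) invite false detections.

`swincount` approaches this as *density-map regression with point
supervision*. Each tree is annotated by a single center point (or by a
four-vertex bounding box reduced to its vertex-mean centroid). The network
maps an RGB tile to a nonnegative single-channel density map whose spatial
integral estimates the number of trees; peak localisation on the same map
yields per-tree detections for the omission/commission analysis.

## The model

The network is a U-shaped encoder–decoder whose only spatial operator is
windowed multi-head self-attention:

* **Patch embedding.** The image is split into non-overlapping 4×4 patches;
  each patch is flattened (4·4·3 = 48 values) and projected linearly to C
  channels, giving an H/4 × W/4 token grid.
* **Encoder.** Four stages of transformer blocks at resolutions H/4, H/8,
  H/16, H/32 with channels C, 2C, 4C, 8C. Between stages, *patch merging*
  concatenates each 2×2 token group (4K channels, fixed order top-left,
  top-right, bottom-left, bottom-right) and projects to 2K.
* **Blocks.** Pre-norm residual blocks: `x + MSA(LN(x))` then
  `x + MLP(LN(x))`, with the MLP a two-layer GELU network (expansion ratio
  4). Attention is evaluated inside N×N token windows as
  `softmax(QKᵀ/√d + B) V` per head, with B a learned relative-position bias
  read from a (2N−1)² offset table. Successive blocks alternate plain
  windows (W-MSA) with windows shifted by ⌊N/2⌋ (SW-MSA) so information
  crosses window borders. The cyclic shift wraps image content around the
  borders, so shifted attention adds a mask that forbids attention between
  tokens that were not neighbours before the shift; without it, shifted
  windows would mix content from opposite image edges and break locality.
* **Bottleneck.** Two further blocks at H/32.
* **Decoder.** Three stages mirroring the encoder: *patch expanding*
  (linear K→2K, then a 2×2 spatial factor rearranged out of the channels)
  doubles resolution and halves channels; each stage fuses the
  same-resolution encoder features by concatenation plus a linear
  projection back to the decoder width (skip connections at H/16, H/8,
  H/4).
* **Head.** A final 4× expansion restores full resolution, and a per-pixel
  linear projection followed by a smooth rectifier (softplus) produces the
  density map.

All forward *and backward* passes are implemented in the package itself
(R with a compiled attention kernel); no external deep-learning runtime is
involved. Gradients of every layer were verified against central finite
differences during development.

## Design choices where the design was open

Several details of this architecture family admit variants; the package
fixes them as follows.

* **Relative-position bias table.** A window of side N admits 2N−1
  relative offsets per axis, hence a (2N−1)² table indexed by a fixed map
  that depends only on N. (Descriptions of this bias occasionally print a
  (2N−1)×(2N+1) table; no pairing of N×N windows produces 2N+1 column
  offsets, so the square table is used.)
* **Shift size.** The shifted blocks displace the window grid by ⌊N/2⌋,
  the established convention. When a feature grid is no larger than one
  window, shifting is a no-op and is disabled.
* **Head rectifier.** A hard cutoff (ReLU) at the head creates a dead
  zone: with sparse targets the whole map can be pushed below zero early
  in training, after which every gradient vanishes — we observed exactly
  this collapse. Softplus is used instead: still nonnegative, never
  gradient-dead.
* **Density scale.** Ground-truth densities are numerically tiny (a σ = 2
  kernel peaks near 0.04), which would sit deep in the rectifier's
  saturated tail. The head therefore computes `softplus(z) / s` with
  `s = density_scale` (default 100), so order-one activations correspond
  to realistic densities, and the training loss is evaluated on
  scale-multiplied maps. The minimiser is unchanged; the output is a true
  density map in either case.
* **Expanding layer.** The first decoder step maps H/32 × W/32 × 8C
  features to H/16 × W/16 × 4C: resolution doubles, channels quarter after
  the linear doubling, consistently with "upsampling by two" (statements
  that keep the resolution fixed while doubling it are typos of this
  family's literature).
* **Loss.** Mean squared pixel-wise error against the rendered density
  target — the standard choice for density-map counting. Optimiser: SGD
  with momentum 0.9 and weight decay 1e-4; learning rate 1e-2 by default
  with a single 10× decay at 75% of the epochs. All of these are
  `train_config()` fields.

## Supervision targets and metrics

`points_to_density()` places a truncated Gaussian (σ default 2 px, support
3σ) at each annotated center and renormalises **every kernel to unit mass
over the pixels inside the image**, including kernels cropped at borders.
This makes the map's integral equal the point count by construction —
the property that justifies count-by-integration — and the package tests
enforce `|Σdensity − n| ≤ 10⁻³·n`.

Evaluation uses four percentages, computed from pooled counts over a test
set: overall accuracy `OA = NE/NA·100`, omission error `OER = Nm/NA·100`,
commission error `CER = Nf/NA·100`, and estimation error
`EE = |NE − NA|/NA·100`. NE is read from the density integral; Nm and Nf
come from peak localisation (local maxima above half a kernel peak, ≥4 px
apart) greedily matched to ground truth within 4 px. EE is reported as a
magnitude — an over- and an under-count of the same size are the same
error — with the signed value kept as `ee_signed`. Note that OA rewards
count agreement, not correctness: omissions and commissions can cancel in
NE, which is why OER and CER are reported separately.

## The synthetic orchard generator

Real annotated orchard tiles of this kind are not freely redistributable,
so the package ships a seeded simulator that emulates their structure:
soil-toned background with low-frequency mottling and pixel noise; crowns
rendered as radially shaded green-grey discs with a bright tip and an
offset dark elliptical shadow; planting layouts `grid`, `jittered`
(default, jitter 0.2 × spacing) and `clustered` (clumps of closely planted,
overlapping crowns — the known hard case); and bright distractor blobs
that are *not* in the ground truth. Each image records exact center
points, tight crown boxes, and a crown-only mask that lets tests count
rendered trees independently via connected components.

What the simulator does **not** model: radiometric calibration, seasonal
and atmospheric variation, perspective distortion, inter-crop vegetation,
and the full range of non-tree land cover. Passing the synthetic
count-recovery test therefore demonstrates that the architecture,
supervision and optimiser can learn to count crown-like objects end to
end; it does not certify accuracy on real satellite tiles, for which
fine-tuning on real annotations would be required.

## Problem sizes used by the tests and the acceptance script

The shipped experiments use a deliberately small instantiation so that a
full train/evaluate cycle runs on one CPU core in minutes: 128×128 tiles,
embedding width C = 16, two blocks per stage, window 4, heads (2,2,2,2);
250 generated images (200 train / 50 held out) with 12–45 trees each,
crown radii 3–5 px, σ = 2 targets; 6 epochs of single-image SGD steps at
learning rate 1e-2. The default configuration (224×224, C = 96, window 7,
heads 3/6/12/24, ~41M parameters) is exercised for shape and determinism
invariants, and is the intended starting point for real training runs on
a GPU-backed reimplementation or with substantially more patience.

Numerical details fixed by the implementation: LayerNorm ε = 1e-5;
truncated-normal (±2 sd, sd 0.02) weight initialisation; softmax rows are
normalised with a max-subtraction guard; attention masks use −10⁹ as the
additive "−∞"; all RNG flows through a single integer seed per run
(dataset seeds are drawn once from the master seed, so any image can be
regenerated bit-identically from the manifest).

## Known limitations

* Single-image SGD (no batching) — adequate at these scales, slow beyond.
* CPU-only; wall-clock cost grows quickly with C and input size.
* Peak localisation with a fixed radius conflates crowns closer than the
  match radius; clustered plantings are systematically undercounted by
  the detection path (the integral path degrades more gracefully).
* No pretrained weights: all results here are from random initialisation.
```
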