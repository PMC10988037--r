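---
title: "Hepatic vessel segmentation with an improved 3-D V-Net: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hepatic vessel segmentation with an improved 3-D V-Net: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselvnet)
```

## The problem

Hepatic vessels in contrast CT are thin, branching, low-contrast structures
occupying well under 2% of the liver volume. Voxel-wise segmentation of such
structures faces two coupled difficulties: extreme foreground/background
class imbalance, which biases symmetric overlap losses toward the background,
and the loss of fine spatial detail as encoder–decoder networks downsample.
`vesselvnet` implements a 3-D fully convolutional segmentation method that
addresses both, together with the CT preprocessing, post-filtering, metrics
and synthetic-phantom machinery needed to exercise it end to end on a single
CPU.

All network layers — dilated and plain 3-D convolutions, strided
down/up-convolutions, PReLU, dropout, trilinear resampling, softmax — are
implemented in C++ with hand-derived adjoints, assembled on a compact
reverse-mode autodiff tape. Every adjoint is verified against centered finite
differences in the test suite, both per-op and through the whole network.

## The network

The model is a four-level residual encoder–decoder ("V-Net" family) with
three modifications:

1. **Dilated bottleneck instead of a fourth downsampling.** Encoder levels
   1–3 use residual stages of 3×3×3 convolutions (depths 1, 2, 3) with
   PReLU, followed by 2×2×2 stride-2 downsampling convolutions that double
   the channel count. The fourth level replaces further downsampling with
   three dilated 3×3×3 convolutions at rates 3, 4 and 5. A dilated kernel
   spans `kd = k + (k-1)(r-1)` voxels, so the three convolutions have
   effective extents 7, 9 and 11, and their stack reaches a 25-voxel
   receptive field at 1/8 resolution without discarding spatial detail.
   `receptive_field_probe()` verifies these extents by feeding a centered
   impulse through a linearized copy of the stage.

2. **Pyramidal convolution blocks on every skip connection.** Each skip path
   passes through three parallel same-padded convolutions with kernels
   3×3×3, 5×5×5 and 7×7×7, whose outputs are summed, added to an identity
   shortcut, and reduced by a trailing 1×1×1 convolution. Large kernels add
   localization context; the residual form keeps the block initialization-
   friendly (zero weights give an exact identity, which the tests exploit).

3. **Multi-resolution deep supervision.** 1×1×1 heads produce two-class
   logits from the decoder at full, 1/2 and 1/4 resolution (the 1/8
   bottleneck carries no head). The logit pyramid is fused stepwise —
   trilinear upsampling plus element-wise addition — into the final
   prediction, and each path is additionally trained against labels
   downsampled to its own resolution. The total loss is the unit-weight sum

   `L_total = L_all + L_full + L_half + L_quarter`.

The decoder mirrors the encoder with 2×2×2 stride-2 transposed convolutions
halving channels; decoder stages merge the upsampled features with the
pyramid-block output by addition. Dropout (p = 0.5 by default) is applied at
the end of every residual stage. The output head is a 1×1×1 convolution to
two channels followed by a channel softmax: foreground probability `p0` and
background probability `p1`.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `base_channels` | 16 | channels | width at full resolution, doubled per level; the smoke tests use 4 so a CPU covers a full training run |
| `dilation_rates` | 3, 4, 5 | voxels | bottleneck receptive-field schedule |
| `pyramid_kernels` | 3, 5, 7 | voxels | skip-path context scales |
| `dropout_p` | 0.5 | — | regularization at every residual stage |
| `learning_rate` | 1e-4 | — | Adam initial step size |
| `batch_size` | 1 | volumes | whole-crop 3-D training is memory-bound |
| `alpha`, `beta` | 0.3, 0.7 | — | Tversky false-positive / false-negative weights |
| `min_volume_mm3` | 180 | mm³ | post-filter threshold separating noise specks from vessels |
| `mask_margin` | 20 | mm | liver-ROI box dilation per axis |
| `hu_window` | 0–400 | HU | liver intensity range |

Design choices the architecture description leaves open, and how this
package resolves them:

- The three dilated convolutions are arranged **in series** (a `parallel`
  switch exists): series composition grows the receptive field to 25 voxels
  without needing channel-fusion logic.
- Pyramid branch outputs are **summed** before the residual add, keeping the
  block's additive-residual form literal; the trailing 1×1×1 convolution
  follows the sum.
- Deep-supervision fusion merges by **addition** (a `concat` mode with a
  learned 1×1×1 reducer is provided); addition keeps fusion linear, which
  makes the zero- and constant-propagation properties exactly testable.
- Residual stage depths follow the original V-Net convention (1, 2, 3, 3);
  the base width is configurable because it is not intrinsic to the method.
- The supervised paths sit at full, 1/2 and 1/4 resolution with the deepest
  (1/8) level unsupervised — the only assignment consistent with both
  "three supervised paths" and "no head on the lowest layer".
- PReLU slopes are per-channel, initialized at 0.25; weights are He-normal;
  biases zero.

## The Tversky loss family

With per-voxel foreground probabilities `p0`, background `p1`, and binary
labels `g0` (`g1 = 1 - g0`), the Tversky index is

```
T(alpha, beta) = sum(p0 g0) / [ sum(p0 g0) + alpha sum(p0 g1) + beta sum(p1 g0) ]
```

`alpha` prices false positives, `beta` false negatives; `alpha = beta = 0.5`
recovers soft Dice exactly (an identity the acceptance tests check to 1e-6).
The training loss is `1 - T`: the index is an overlap ratio, maximal at
perfect prediction, so its complement is the minimizable form. The defaults
`alpha = 0.3, beta = 0.7` penalize missed vessel voxels more than spurious
ones, which is the right asymmetry when the foreground is ~1% of the volume.

Two numerical choices:

- A smoothing constant `eps = 1e-5` is added to numerator and denominator so
  empty-foreground patches give 1 (loss 0) rather than 0/0.
- The gradients are the exact derivatives of the smoothed index:
  `dT/dp0_i = (g0_i D - N (g0_i + alpha g1_i)) / D^2` and
  `dT/dp1_i = -beta g0_i N / D^2`. Published statements of these gradients
  are inconsistent in their subscripts and constant factors; this package
  differentiates the index directly and treats a centered finite-difference
  oracle (200 random instances, relative tolerance 1e-4) as authoritative.
  Note `dT/dp1_i` vanishes exactly on background voxels.

Four comparison losses sit behind the same `make_loss()` interface, which is
the switch driving the loss-comparison harness (`compare_losses()`): soft
Dice; generalized Dice with squared-reciprocal class weights
`w_c = 1/(sum g_c)^2` (an absent class gets weight 0); two-class
cross-entropy; and focal loss `(1-p)^gamma (-log p)` with `gamma = 2` and no
class weight by default. Each closure returns its value and analytic
per-voxel gradients, so any of them can drive the same training graph.

## Preprocessing

The chain is **clip → resample → normalize**:

1. Intensities are clipped to the 0–400 HU liver window.
2. Volumes are resampled to isotropic 1 mm spacing — separable natural cubic
   splines for intensities, nearest-neighbor for labels (which therefore stay
   binary). Output shape is `round(shape * spacing / target)` with
   voxel-center alignment.
3. Z-score normalization to zero mean and unit variance, computed per volume
   over all voxels, using the population (1/N) variance — the deep-learning
   convention, pinned down by the test `{0, 2} -> {-1, +1}`.

Normalizing after resampling keeps the statistics on the grid the network
actually sees. Per-volume (rather than dataset-global) statistics are a
deliberate choice: CT scanners differ in calibration and contrast timing,
and per-volume normalization absorbs that.

The liver ROI is built by dilating a liver label 20 mm outward **per axis**
(a box structuring element, margin converted to voxels through the spacing;
a `ball` element is available but non-default), then cropping image and
label to the ROI's bounding box with the offset recorded for reinsertion.
Augmentation is limited to seeded joint axis flips.

## Post-processing

Predicted masks are cleaned by connected-component analysis: components with
physical volume (voxel count × voxel volume) strictly smaller than 180 mm³
are removed. "Smaller than" is read strictly — a component of exactly
180 mm³ survives. Default adjacency is 26-connectivity, because vessels are
thin and oblique and face-only connectivity fragments them; 6-connectivity
is a flag. The filter is idempotent, never adds voxels, and its report
accounts for every foreground voxel.

## Metrics

Dice, accuracy, sensitivity and specificity all derive from voxel confusion
counts (`2TP/(2TP+FP+FN)` etc.). A zero denominator yields an explicit
undefined marker (`NA`), never a silent 0 or 1 — though the empty-vs-empty
Dice convention is configurable. Dice is additionally computed by a second
route, `2|P∩G|/(|P|+|G|)`, and the two routes must agree exactly; this
dual-route identity is one of the acceptance checks. Cross-validation
aggregation reports mean ± sample (n−1) standard deviation per metric over
folds produced by a deterministic balanced k-fold split.

## The phantom generator

Phantoms exist so that every downstream stage is testable without clinical
data. Each phantom is a binary branching tree of capsules (finite tubes with
hemispherical caps): the root starts near one face, each segment spawns two
children tilted 20–45° at a random azimuth, lengths shrink ×0.7 and radii
×`radius_taper` (default 0.7) per generation, and endpoints are clamped to
the volume. Rasterization marks a voxel foreground iff its center lies
within a segment's radius of the segment axis; a brute-force point-to-
segment oracle checks this voxel-for-voxel in the tests. CT intensity is a
two-Gaussian model: parenchyma at 80 HU, vessels 100 HU brighter, both with
15 HU noise — values chosen to sit inside the 0–400 HU window with a
contrast-to-noise ratio typical of portal-phase CT. Default trees occupy
roughly 0.5–1.5% of a 64³ volume at 1 mm spacing, matching the foreground
scarcity that motivates the Tversky loss; `make_dataset()` enforces a
[0.25×, 4×] band around the 1% target and derives per-volume seeds as
`master_seed + index`.

What the phantoms deliberately do **not** emulate: realistic portal/hepatic
topology, contrast-phase dynamics, organ context, beam-hardening or partial-
volume physics. Passing the end-to-end tests therefore demonstrates that the
optimization, supervision and post-processing machinery work — that the
network can learn a bright-tubular-structure segmentation task from ~10⁵
gradient-weighted voxels — not that the trained weights transfer to clinical
CT.

## Problem sizes and numerical choices

The package's own desk-scale study conditions, used by the tests and the
acceptance script:

- **End-to-end run:** 9 phantoms of 64³ voxels (8 train, 1 validation),
  48³ training patches, base width 4, dropout 0.5, Tversky(0.3, 0.7), Adam
  at lr 1e-4, batch 1, 200 gradient steps, validation every 25 steps with
  best-by-validation-Dice checkpointing. A fresh phantom (never seen in
  training) is segmented and scored; held-out Dice reproducibly exceeds 0.6.
  The narrow width is a deliberate choice: the phantom task is
  low-dimensional, and width 4 keeps a full run within minutes on one CPU
  while exercising every architectural component at full depth.
- **Determinism:** the identical configuration run twice (15 steps) must
  produce bit-identical loss curves, validation history, checkpoints and
  predictions. All randomness — weight init, patch sampling, flips, dropout
  masks — flows from a single seeded R RNG stream, and all C++ kernels are
  single-threaded.
- **Gradient verification:** every op at toy shapes, plus 8 random
  parameters of the full network at 16³, against centered finite differences
  (relative tolerance 5e-4 end-to-end, dominated by finite-difference
  truncation).
- Inference pads volumes symmetrically with zeros (the post-normalization
  mean) to the next multiple of 8 and crops back, so any grid is accepted.
- Label downsampling for supervision thresholds the trilinear average at
  0.5 with ties going to the foreground, protecting single-voxel vessels.

## Limitations

- Training at clinically useful widths (base 16+, 128³ crops, thousands of
  steps) is far beyond a single-CPU R process; the implementation is exact
  but not fast. The architecture, losses and pipeline are nevertheless
  identical in form at any width.
- The phantom generator's simplicity means quantitative phantom metrics
  (Dice ≈ 0.6–0.7 after 200 steps) say nothing about clinical performance.
- Liver-mask production is out of scope: the pipeline accepts a liver label
  as input; phantoms use the whole volume as ROI.
- Only axis-flip augmentation is provided, matching the method's stated
  augmentation set.
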