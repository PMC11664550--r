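---
title: "Detecting strawberry growth stages with a lightweight convolutional detector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting strawberry growth stages with a lightweight convolutional detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagenet)
```

## The problem

Greenhouse strawberries pass through five visually distinct phenological
stages — flowering, young fruit, fruit expansion, colour turning and
maturation — and production decisions (irrigation, thinning, harvest
timing) depend on knowing which stages are present where.  Manual scouting
is slow and subjective; a detector that runs on portable hardware must be
small in parameters and floating-point cost while still resolving small,
low-contrast targets (a young green fruit against green canopy) in crowded
scenes.

`stagenet` implements such a detector end to end in R: a synthetic scene
generator that stands in for field imagery, annotation I/O in the two
common labelling dialects, photometric/geometric augmentation, a mobile
inverted-bottleneck backbone, a fusion neck with adaptive upsampling and
windowed attention, an anchor-free head trained with an Inner-IoU box
loss, evaluation (mAP@0.5), a parameter/FLOP audit and Grad-CAM++
explanations.  Everything runs on a plain CPU through an in-package
reverse-mode autodiff engine with compiled convolution kernels; no
deep-learning framework is required.

## The model

### Backbone

The backbone is a MobileNet-style stack: a 3x3 stride-2 stem followed by
four stages of Universal Inverted Bottleneck (UIB) blocks

$$F_\text{out} = \mathrm{PW}\big(\mathrm{DW}\big(\mathrm{Expand}(F_\text{in})\big)\big),$$

each block a pointwise expansion, a depthwise convolution (stride 2 on the
first block of a stage) and a linear pointwise projection, with
Conv → BatchNorm → ReLU ordering throughout and an identity shortcut
whenever stride and width permit.  There is no fully connected layer; a
global-average-pool head exists only as a utility.  Stages output widths
(128, 256, 512, 1024) with depthwise kernels (3, 3, 5, 5); the taps after
the stages at strides 8, 16 and 32 form the feature pyramid P3/P4/P5
(80x80, 40x40, 20x20 for a 640 input), responsible for small, medium and
large objects respectively.

The published description fixes the stage widths and kernel schedule but
not the per-stage depths or expansion factors, so those are calibrated
here against the model's stated complexity budget (about 5.86 M parameters
and 14.7 GFLOPs at 640x640, with FLOPs counted as multiply–accumulate
pairs over output maps).  The frozen configuration — stem width 48, depths
(2, 2, 2, 1), expansions (2, 2, 1, 1), neck width 256 with a 112-wide P3
path and 88-wide two-conv head towers — audits at 5.817 M parameters and
14.686 GFLOPs:

```{r audit}
model <- stageNet(stageNetConfig("full"), seed = 0)
rep <- auditModel(model, 640)
rep
```

A naive reading of "depths (2,3,4,3) with expansion 4" at these widths
would exceed 20 M parameters, so a calibrated configuration is the only
self-consistent choice; it is frozen in the package and snapshotted under
`inst/extdata/audit_snapshot.json`.

### Neck

The neck follows a PAN-style three-path layout.  The P5 path passes
through SPPELAN (pointwise reduction, three sequential 5x5 same-resolution
max pools, concatenation, pointwise fusion).  Deeper features are
upsampled by **DySample**: a zero-initialised linear (1x1) projection
predicts per-pixel offsets $O$, which are pixel-shuffled to output
resolution, scaled by a range factor of 0.25 and added to the regular
bilinear grid $G$; the output is the bilinear resampling of the input at
$S = G + O$ with border clamping and half-pixel centres, in 4 offset
groups.  With the offset head at zero this is exactly bilinear x2
upsampling, which anchors the unit tests.

Upsampled features concatenate with the lateral backbone tap and enter a
**dual-stream fusion**: stream A is a RepNCSPELAN4 aggregation block
(pointwise reduce, split, two cascaded reparameterizable 3x3+1x1(+identity)
convolutions, concatenate, pointwise fuse); stream B projects the input
pointwise and applies an **iRMB** — expanded-window multi-head
self-attention (query windows of 7, key/value windows extended by 2 pixels
per side, 4 heads) followed by a 3x3 depthwise convolution with an
inverted-residual shortcut.  The streams combine as

$$h(x) = \big(\lambda \odot h_\text{Rep}(x) + 1\big) + \big(\mu \odot h_\text{iRMB}(x) + 1\big)$$

with trainable per-channel weights $\lambda, \mu$ (initialised at 1), then
a confidence-gated pointwise refinement convolution applied when the mean
absolute activation exceeds a threshold $\tau$.  The gate condition is not
fully specified in the source description; we define it as mean absolute
activation $> \tau$ with $\tau = 0$, so refinement is always on and the
code path is exercised deterministically.  The "+1" is read literally as
an elementwise scalar; the separately mentioned "dot-product fusion" has
no printed formula, so it is realized only as this refinement stage.  The
two bottom-up return paths use AConv (stride-2 3x3 convolution with
normalization and ReLU) and plain RepNCSPELAN4 blocks; iRMB attention sits
on the P3 and P4 fusion paths where small-object sensitivity matters.

In deploy mode every reparameterizable block collapses its branches into a
single 3x3 kernel (smaller kernels centre-padded, identity added on the
diagonal); because normalization sits after the branch sum, the merge is
exact and train/deploy agreement is tested to 1e-5.

### Head and losses

Each pyramid level predicts per cell: 4 side distances discretized into 16
bins (decoded as the distribution mean, in units of the level's stride), 5
class logits and an objectness logit; boxes decode around the cell centre.
Separate two-convolution towers feed the regression and the
classification/objectness branches (the architecture names distinct
Conv-reg and Conv-cls layers; sharing one stem, or using single-conv
towers, measurably slows classification convergence at desk scale).

Target assignment is task-aligned: candidate cells lie inside the box and
within 5 cells of its centre (the anchor matching radius), are scored by
$\sqrt{p_\text{cls}} \cdot \text{IoU}^6$ against the current prediction,
filtered by a 0.2 minimum-IoU floor (with a best-candidate fallback so no
box goes unmatched), and the top 10 per box become positives, each cell
serving at most one box.

The box loss is the **Inner-IoU** loss: both boxes are rescaled about
their centres by a ratio (default 0.75, configurable; the source never
states its value) and the loss is one minus the IoU of the auxiliary
boxes.  The printed intersection formula uses only horizontal extents;
an area requires the vertical mirror term, so the implementation computes
both axes — a printing-gap correction, verified against a rasterized
overlap oracle.  With ratio 1 the loss reduces exactly to the standard
IoU complement (property-tested on 10^4 random pairs).  Shrunken auxiliary
boxes steepen the gradient once boxes overlap well, which is where the
faster convergence claim comes from; a small gradient-descent simulation
in the test suite records this as a soft property.

The classification term is the mean binary cross-entropy over positive
cells, with task-aligned soft targets: the assigned class is supervised
towards the cell's localization quality (the IoU of its decoded box with
the ground truth) so the decoded score concentrates on the best-localized
cell of each object.  A maximally uncertain classifier still contributes
exactly ln 2 per element, since binary cross-entropy at probability 0.5
is ln 2 for any target.  The objectness term uses the same quality as its
target and is a focal-weighted (alpha 0.25, gamma 2, weights detached)
cross-entropy summed over every cell and normalized by the number of
positives — the dense-detector convention.  Both choices address the same
desk-scale failure mode: with a plain cell-count mean, the gradient from
the one or two positive cells of a small object vanishes against
thousands of background cells, and objectness for rare small targets
never leaves its prior within a short training budget.  The distribution
term is the soft cross-entropy against the two bins adjacent to each
target distance.  The total is the weighted sum with the published
factors: box 7.5, classification 0.5, objectness 0.7, distribution 1.5.

Decoding emits every (cell, class) pair above the confidence threshold
(multi-label emission — a second-ranked class can still be detected, which
matters for minority classes), caps candidates per class and level, and
applies greedy per-class NMS.  Evaluation uses confidence 0.001 with NMS
IoU 0.7; interactive detection defaults to confidence 0.25.

### Training schedule

`trainConfig()` carries the published schedule: SGD, momentum 0.937,
initial and final learning rate 0.01, weight decay 0.0005 (applied to
convolution kernels only), 3 warmup epochs interpolating linearly from
(0.1 x initial learning rate, momentum 0.8) — the warmup learning rate is
read as a multiplier of the initial rate, the common convention — batch
16 at 640 input for the full model.  Warmup is interpolated per optimizer
step across the warmup epochs.  Batch normalization uses each map's own
spatial statistics during training (batches are processed image by image)
and running averages (momentum 0.1) at inference.  Training is fully
seeded: initialization, data order and batch composition derive from the
configured seeds, and two runs with the same seed produce identical loss
traces.

## The synthetic scene generator

The package's data are synthetic 640x640 scenes: 1-12 elliptical
fruit/flower objects on a textured green canopy background, with
stage-conditioned phenotypes keyed to the verbal stage descriptions —
flowering as a white disc with a yellow centre; young fruit small and
green with pronounced achene speckles; fruit expansion larger and pale;
colour turning pink to partial red; maturation large and saturated red —
plus a dark-green calyx wedge on fruit.  Boxes are tight around the drawn
geometry.  Rendering is a pure function of `(seed, stageMix, nObjects,
size)`.

The generator emulates the *composition* of greenhouse imagery (stage
phenotypes, size ranges, clutter, occlusion by later-drawn objects) but
not its photometric realism: no leaves or specular highlights, no blur,
no camera noise beyond Gaussian pixel noise, and axis-aligned ellipses
instead of real fruit silhouettes.  Passing tests therefore demonstrate
that the architecture, losses, optimizer and evaluation stack are
implemented correctly and can fit stage-discriminative colour/size/shape
cues — not that the trained weights transfer to photographs.

Augmentation mirrors the published catalogue: vertical flip, mirroring
(horizontal flip kept as its own catalogue entry), brightness (+s),
darkness (−s) and chroma (v + s·(v − mean)) adjustments, all clipped to
[0, 255] — the raw adjustment formulas are unclipped and would overflow
the 8-bit range — with defaults s = 40 intensity levels and chroma gain
0.4.  The published per-stage augmented counts imply a non-integer,
unstated expansion policy, so the augmenter instead exposes an explicit
operator catalogue (default: original + 5 operators = 6x).  Dataset splits
shuffle with a seed and use round-half-up counts with the remainder
assigned to training, which reproduces 7,528 → 6,022/753/753 and
660 → 528 training images exactly.

Annotation conventions, stated explicitly because the dialect names alone
do not fix them: YOLO txt is "class cx cy w h", normalized centre format,
six decimals; Pascal VOC XML uses 1-based inclusive integer corners with
`xmin = round(left_px) + 1`, `xmax = round(right_px)`, which round-trips
the normalized representation to within half a pixel.

## Desk-scale experiments

The test suite trains a `tiny` preset (stem 8, stage widths 16/32/48/64,
depth 1 per stage, neck width 32, 64-wide head towers, 2 attention heads)
at 320x320 on eight
generated scenes for 200 optimizer steps with batch 4 — about three
minutes on one CPU core per seed — and checks that the final-quarter mean
loss falls below the first quarter and that train-set mAP@0.5 reaches 0.9
(median over three seeds).  The full 640 configuration is retained for
the complexity audit, which is pure arithmetic over the architecture
graph and needs no forward pass.

```{r tiny, eval = FALSE}
imgs <- renderScenes(8, seed = 101, nObjects = c(2, 5), size = 320)
model <- stageNet(stageNetConfig("tiny"), seed = 1)
cfg <- trainConfig(imageSize = 320, batchSize = 4, seed = 1)
r <- trainModel(model, imgs, iterations = 200, cfg = cfg)
evaluateModel(model, imgs, cfg)
```

## Evaluation and audit

Precision, recall and F1 follow the usual contingency definitions with
0/0 defined as 0.  Average precision integrates the precision envelope of
the PR staircase over all points (the integral definition, not 11-point
sampling), and mAP@0.5 averages APs over the classes that have at least
one ground-truth instance.  Matching is greedy in score order against the
highest-IoU unmatched same-class box at threshold 0.5.

The audit walks the architecture graph: parameters as
$K_h K_w C_\text{in} C_\text{out}$ per convolution (+bias terms where a
bias exists), FLOPs as multiply–accumulate pairs
$K_h K_w C_\text{in} C_\text{out} H W$ over output maps with no factor of
two — the convention under which the 14.7 GFLOPs figure is coherent —
and normalization, fusion-weight and attention matrix-product terms
itemized as their own rows.  Because the depthwise-separable "conv layer"
counting convention is ambiguous, `convLayerCounts()` reports both the
per-convolution and the per-block count.

Grad-CAM++ heatmaps use the closed-form pixel-wise weights
$\alpha_{ij}^k = g_{ij}^2 / (2 g_{ij}^2 + \sum_{ab} A^k_{ab} g_{ab}^3)$
on the positive gradients of the class evidence (the sum over cells of
class probability times objectness), with the fused small-object level P3
as the default target layer.

## Numerical choices and degenerate inputs

* Convolution padding is zeros, "same" for stride 1; stride 2 uses
  symmetric `k %/% 2` padding so even inputs halve exactly.
* Batch-norm epsilon is 1e-5 with biased variance; running statistics
  update with momentum 0.1.
* Attention softmax subtracts the row maximum before exponentiation; edge
  windows gather only valid positions, so no masking is needed.
* Degenerate (zero-area) boxes yield IoU 0 with a warning; empty
  assignments give zero box/distribution terms; an all-zero Grad-CAM++
  gradient is flagged on the returned heatmap.
* `averagePrecision` with no ground truth returns 0 flagged "undefined";
  classes absent from the ground truth are excluded from macro averages.
* NMS ties (equal scores) keep first-seen order after the stable sort;
  assignment ties go to the lower box index.
* Training aborts with a diagnostic if any loss component becomes
  non-finite.

## Known limitations

* The synthetic scenes are caricatures; no claim is made about accuracy on
  real imagery, and the published detection metrics on the private field
  dataset are out of reach by construction.
* Batches are processed image by image, so batch normalization sees
  spatial statistics of one map at a time rather than cross-image batch
  statistics.
* The autodiff engine is single-threaded apart from BLAS matrix products;
  the full 640 configuration is practical for auditing and single-image
  inference, not for training, which is what the tiny preset is for.
* The exact mathematical form of the "dot-product fusion" mentioned in
  prose, the iRMB insertion points beyond the neck fusion paths, and the
  image-level "Multi-Stages" grouping (treated here as a dataset grouping,
  not a sixth detector class) remain interpretation decisions, each noted
  above where it is made.
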