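# stagenet

Lightweight growth-stage object detection for strawberry phenology images,
implemented entirely in R.

## The problem

Strawberry production management hinges on knowing which of five
phenological stages — Flowering, Young Fruit, Fruit Expansion, Color
Turning, Maturation — are present in a greenhouse scene, and where.
Detectors for this task must run on portable hardware, so parameter count
and floating-point cost matter as much as accuracy, and the hardest targets
are small, low-contrast ones (a young green fruit against green canopy).

`stagenet` implements a complete lightweight single-stage detector for this
problem and exercises it on synthetically rendered, stage-labelled scenes:

* **Backbone** — a mobile Universal Inverted Bottleneck (UIB) network: a
  3×3 stride-2 stem and four stages of
  `PW-expand → depthwise → PW-project` blocks (widths 128/256/512/1024,
  depthwise kernels 3/3/5/5, Conv→BN→ReLU, identity shortcuts, no fully
  connected layer), emitting a P3/P4/P5 pyramid at strides 8/16/32.
* **Neck** — SPPELAN spatial pyramid pooling on P5; DySample adaptive
  upsampling (bilinear resampling at `S = G + O`, with offsets `O` from a
  zero-initialised linear projection); dual-stream fusion
  `(λ⊙h_Rep + 1) + (μ⊙h_iRMB + 1)` combining a reparameterizable
  RepNCSPELAN4 aggregation stream with an iRMB stream (expanded-window
  multi-head self-attention + depthwise convolution), plus AConv/PAN
  return paths.
* **Head and loss** — anchor-free decoupled towers predicting discretized
  side distances (16 bins), 5 class logits and objectness per cell;
  task-aligned assignment; composite loss
  `7.5·L_box + 0.5·L_cls + 0.7·L_obj + 1.5·L_dfl` where `L_box` is the
  **Inner-IoU** loss `1 − IoU(b_inner, b^gt_inner)` computed on auxiliary
  boxes rescaled about their centres by a ratio (0.75 by default).
* **Evaluation & audit** — greedy matching at IoU 0.5, all-point PR
  integration for AP, mAP@0.5; a per-layer parameter/FLOP audit
  (`Params = ΣK_hK_wC_inC_out`, `FLOPs = ΣK_hK_wC_inC_outHW`,
  `GFLOPs = FLOPs/10⁹`); Grad-CAM++ heatmaps.
* **Synthetic data** — a deterministic generator of 640×640 scenes with
  1–12 stage-conditioned elliptical fruit/flower objects and tight boxes,
  annotation I/O in YOLO txt and Pascal VOC XML, photometric
  (brightness/darkness/chroma) and flip/mirror augmentation, and seeded
  train/test/val splits.

Everything — including training — runs on a plain CPU through an
in-package reverse-mode autodiff engine with compiled (RcppArmadillo)
convolution, pooling and resampling kernels.  The frozen full-size
configuration audits at **5.82 M parameters and 14.69 GFLOPs** at 640×640.

## Worked example

Render a scene, audit the full model, then train the desk-scale preset on
eight scenes and evaluate on them:

```r
library(stagenet)

img <- renderScene(seed = 7, nObjects = 4, size = 640)
img
#> LabeledImage 'scene_7': 640x640 RGB, 4 box(es)
#>   stages: Color Turning=1, Maturation=3

auditModel(stageNet(stageNetConfig("full")), 640)
#> AuditReport: 151 layers, 5.817 M params, 14.686 GFLOPs

imgs  <- renderScenes(8, seed = 101, nObjects = c(2, 5), size = 320)
model <- stageNet(stageNetConfig("tiny"), seed = 1)
cfg   <- trainConfig(imageSize = 320, batchSize = 4, seed = 1)
run   <- trainModel(model, imgs, iterations = 200, cfg = cfg)
tail(run$trace[, c("iter", "box", "cls", "obj", "dfl", "total")], 1)
#>     iter        box        cls        obj       dfl    total
#> 200  200 0.08439112 0.09783778 0.08073958 0.5881909 1.620656

evaluateModel(model, imgs, cfg)
#> MetricReport: mAP@0.5=0.9266 P=0.0036 R=0.9778 F1=0.0071
```

The per-step trace logs the unweighted loss components (box = Inner-IoU,
cls/obj = binary cross-entropies, dfl = distribution loss) and their
weighted total; mAP@0.5 is the
macro average over the stages present in the ground truth.  Precision is
tiny at the evaluation confidence threshold of 0.001 by construction — AP
integrates the full precision–recall staircase, so the threshold-level
precision is not the headline number.

Explanations for a trained model:

```r
heat <- gradCamPP(model, imgs[[1]], classId = 4, layer = "p3")
writeHeatmapPNG(imgs[[1]], heat, "maturation_heatmap.png")
```

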