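# Full detector assembly: backbone -> neck (SPPELAN / DySample / dual-stream
# fusion / PAN return paths) -> anchor-free heads at strides 8/16/32.

#' Architecture configuration presets
#'
#' `"full"` is the frozen full-size configuration used by the complexity
#' audit: Table-style stage widths (128, 256, 512, 1024), depthwise kernels
#' (3, 3, 5, 5) and a 256-wide neck, calibrated to approximately 5.86 M
#' parameters and 14.7 GFLOPs at 640 x 640.  `"tiny"` is a desk-scale preset
#' with the same topology used for training experiments and tests.
#'
#' @param preset `"full"` or `"tiny"`.
#' @return Configuration list (editable before passing to [stageNet()]).
#' @export
stageNetConfig <- function(preset = c("full", "tiny")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    list(
      preset = "full", nc = 5, regMax = 16, strides = c(8, 16, 32),
      backbone = list(stem = 48, widths = c(128, 256, 512, 1024),
                      depths = c(2, 2, 2, 1), expansions = c(2, 2, 1, 1),
                      kernels = c(3, 3, 5, 5)),
      neck = list(width = 256, widthP3 = 112, headWidth = 88,
                  cmidFraction = 0.5),
      irmb = list(heads = 4, window = 7, ext = 2),
      dysample = list(groups = 4, range = 0.25),
      fusion = list(tau = 0),
      innerIoURatio = 0.75
    )
  } else {
    list(
      preset = "tiny", nc = 5, regMax = 16, strides = c(8, 16, 32),
      backbone = list(stem = 8, widths = c(16, 32, 48, 64),
                      depths = c(1, 1, 1, 1), expansions = c(2, 2, 2, 2),
                      kernels = c(3, 3, 5, 5)),
      neck = list(width = 32, widthP3 = 32, headWidth = 64, cmidFraction = 1),
      irmb = list(heads = 2, window = 8, ext = 2),
      dysample = list(groups = 4, range = 0.25),
      fusion = list(tau = 0),
      innerIoURatio = 0.75
    )
  }
}

#' The growth-stage detector
#'
#' S4 wrapper around the mutable network state (parameters, running batch
#' norm statistics, architecture graph).
#'
#' @slot env environment holding parameters and configuration.
#' @export
setClass("StageNet", representation(env = "environment"))

#' Build a detector
#'
#' @param config a configuration list from [stageNetConfig()].
#' @param seed parameter initialization seed.
#' @return A [StageNet-class] model.
#' @export
stageNet <- function(config = stageNetConfig("full"), seed = 0) {
  m <- net_new(config, seed = seed)
  build_backbone(m)
  bk <- config$backbone
  nw <- config$neck$width
  nw3 <- config$neck$widthP3
  hw <- config$neck$headWidth
  nc <- config$nc; nb <- config$regMax
  cm <- function(w) max(16L, 2L * as.integer(round(w * (config$neck$cmidFraction %||% 1) / 2)))
  add_sppelan(m, "spp", bk$widths[4], cm(nw), nw, down = 32)
  add_dysample(m, "up4", nw, 2, down = 32)
  add_fuse(m, "fuse4", nw + bk$widths[3], nw, down = 16, cmid = cm(nw))
  add_dysample(m, "up3", nw, 2, down = 16)
  add_fuse(m, "fuse3", nw + bk$widths[2], nw3, down = 8, cmid = cm(nw3))
  add_conv(m, "down4", 3, 3, nw3, nw, stride = 2, down = 8)
  add_repncspelan4(m, "pan4", nw + nw, cm(nw), nw, down = 16)
  add_conv(m, "down5", 3, 3, nw, nw, stride = 2, down = 16)
  add_repncspelan4(m, "pan5", nw + nw, cm(nw), nw, down = 32)
  for (lv in c("3", "4", "5")) {
    cin <- if (lv == "3") nw3 else nw
    down <- c("3" = 8, "4" = 16, "5" = 32)[[lv]]
    # separate two-conv regression and classification towers
    # (Conv-reg / Conv-cls)
    add_conv(m, paste0("head", lv, ".rstem"), 3, 3, cin, hw, 1, down)
    add_conv(m, paste0("head", lv, ".rstem2"), 3, 3, hw, hw, 1, down)
    add_conv(m, paste0("head", lv, ".reg"), 1, 1, hw, 4 * nb, 1, down,
             bias = TRUE, bn = FALSE, act = "none")
    add_conv(m, paste0("head", lv, ".cstem"), 3, 3, cin, hw, 1, down)
    add_conv(m, paste0("head", lv, ".cstem2"), 3, 3, hw, hw, 1, down)
    add_conv(m, paste0("head", lv, ".cls"), 1, 1, hw, nc, 1, down,
             bias = TRUE, bn = FALSE, act = "none")
    add_conv(m, paste0("head", lv, ".obj"), 1, 1, hw, 1, 1, down,
             bias = TRUE, bn = FALSE, act = "none")
    # start classification/objectness near the background prior
    m$par[[paste0("head", lv, ".cls.b")]][] <- -4
    m$par[[paste0("head", lv, ".obj.b")]][] <- -4
  }
  new("StageNet", env = m)
}

model_env <- function(model) {
  if (is(model, "StageNet")) model@env else model
}

#' @describeIn stageNet configuration accessor
#' @param model a [StageNet-class].
#' @export
modelConfig <- function(model) model_env(model)$cfg

setMethod("show", "StageNet", function(object) {
  m <- object@env
  cat(sprintf("StageNet detector (preset '%s'): %.3f M parameters\n",
              m$cfg$preset %||% "custom", net_nparams(m) / 1e6))
  cat(sprintf("  backbone widths %s, neck width %d, %d classes\n",
              paste(m$cfg$backbone$widths, collapse = "/"),
              m$cfg$neck$width, m$cfg$nc))
})

# Full forward pass on a tape.  Returns node ids for the pyramid taps, the
# fused neck outputs and the per-level raw heads.
model_forward <- function(model, tp, x, train = FALSE, deploy = FALSE) {
  m <- model_env(model)
  taps <- fw_backbone(m, tp, x, train)
  c3 <- taps[[1]]; c4 <- taps[[2]]; c5 <- taps[[3]]
  p5in <- fw_sppelan(m, tp, c5, "spp", train)
  u4 <- fw_dysample(m, tp, p5in, "up4", 2, train)
  f4 <- fw_fuse(m, tp, ag_concat_c(tp, list(u4, c4)), "fuse4", train, deploy)
  u3 <- fw_dysample(m, tp, f4, "up3", 2, train)
  p3 <- fw_fuse(m, tp, ag_concat_c(tp, list(u3, c3)), "fuse3", train, deploy)
  d4 <- fw_conv(m, tp, p3, "down4", train)
  p4 <- fw_repncspelan4(m, tp, ag_concat_c(tp, list(d4, f4)), "pan4", train, deploy)
  d5 <- fw_conv(m, tp, p4, "down5", train)
  p5 <- fw_repncspelan4(m, tp, ag_concat_c(tp, list(d5, p5in)), "pan5", train, deploy)
  heads <- list()
  outs <- list(`3` = p3, `4` = p4, `5` = p5)
  for (lv in c("3", "4", "5")) {
    rs <- fw_conv(m, tp, outs[[lv]], paste0("head", lv, ".rstem"), train)
    rs <- fw_conv(m, tp, rs, paste0("head", lv, ".rstem2"), train)
    cs <- fw_conv(m, tp, outs[[lv]], paste0("head", lv, ".cstem"), train)
    cs <- fw_conv(m, tp, cs, paste0("head", lv, ".cstem2"), train)
    heads[[length(heads) + 1]] <- list(
      reg = fw_conv(m, tp, rs, paste0("head", lv, ".reg"), train),
      cls = fw_conv(m, tp, cs, paste0("head", lv, ".cls"), train),
      obj = fw_conv(m, tp, cs, paste0("head", lv, ".obj"), train),
      stride = c(`3` = 8, `4` = 16, `5` = 32)[[lv]])
  }
  list(heads = heads,
       nodes = list(c3 = c3, c4 = c4, c5 = c5, p3 = p3, p4 = p4, p5 = p5))
}

norm_input <- function(x) {
  if (is(x, "LabeledImage")) x <- pixels(x)
  if (max(x) > 1.5) x <- x / 255
  x
}

#' Raw per-level predictions for one image
#'
#' @param model a [StageNet-class].
#' @param x pixel array or [LabeledImage-class] with sides divisible by 32.
#' @param deploy use reparameterized (merged) convolutions.
#' @return list per level: `reg`, `cls`, `obj` arrays and `stride`.
#' @export
predictRaw <- function(model, x, deploy = FALSE) {
  x <- norm_input(x)
  tp <- tp_new()
  fwd <- model_forward(model, tp, tp_leaf(tp, x), train = FALSE, deploy = deploy)
  lapply(fwd$heads, function(h) {
    list(reg = tp_v(tp, h$reg), cls = tp_v(tp, h$cls), obj = tp_v(tp, h$obj),
         stride = h$stride)
  })
}

#' Detect objects in one image
#'
#' Runs the detector and returns decoded, NMS-filtered detections.
#'
#' @inheritParams predictRaw
#' @param confThr score threshold.
#' @param nmsIoU NMS IoU threshold.
#' @return data.frame of detections (absolute xyxy, score, class_id).
#' @export
detect <- function(model, x, confThr = 0.25, nmsIoU = 0.7) {
  img <- norm_input(x)
  preds <- predictRaw(model, img)
  decodeDetections(preds, confThr, nmsIoU, imgSize = dim(img)[1],
                   regMax = model_env(model)$cfg$regMax)
}
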