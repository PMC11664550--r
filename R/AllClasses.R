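#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail write.csv
#' @useDynLib stagenet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Five strawberry growth-stage class names
#'
#' Detector classes, indexed 0-4 in annotations: Flowering, Young Fruit,
#' Fruit Expansion, Color Turning, Maturation.
#'
#' @return Character vector of length 5.
#' @export
stageNames <- function() {
  c("Flowering", "Young Fruit", "Fruit Expansion", "Color Turning", "Maturation")
}

validateBoxes <- function(boxes, tol = 1e-6) {
  needed <- c("class_id", "cx", "cy", "w", "h")
  if (!is.data.frame(boxes) || !all(needed %in% names(boxes)))
    return("boxes must be a data.frame with columns class_id, cx, cy, w, h")
  if (nrow(boxes) == 0) return(TRUE)
  if (!all(boxes$class_id %in% 0:4)) return("class_id must be in 0..4")
  if (any(boxes$w <= 0 | boxes$h <= 0)) return("box width/height must be positive")
  lo <- pmin(boxes$cx - boxes$w / 2, boxes$cy - boxes$h / 2)
  hi <- pmax(boxes$cx + boxes$w / 2, boxes$cy + boxes$h / 2)
  if (any(lo < -tol) || any(hi > 1 + tol))
    return("boxes must lie inside the unit square")
  TRUE
}

#' An RGB image with its box annotations
#'
#' The central data container: a H x W x 3 pixel array with values in
#' [0, 255], a data.frame of normalized boxes (one row per object:
#' `class_id` in 0..4, center `cx`,`cy` and extent `w`,`h` in [0,1]),
#' an image id and the generator seed (NA for ingested images).
#'
#' @slot pixels numeric array, dim (H, W, 3), values in [0, 255].
#' @slot boxes data.frame of normalized annotations.
#' @slot imageId character scalar.
#' @slot seed integer scalar (NA if not generated).
#' @export
setClass("LabeledImage",
  representation(pixels = "array", boxes = "data.frame",
                 imageId = "character", seed = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3 || d[3] != 3) return("pixels must be an (H, W, 3) array")
    if (min(object@pixels) < 0 || max(object@pixels) > 255)
      return("pixel values must be in [0, 255]")
    validateBoxes(object@boxes)
  })

#' Construct a LabeledImage
#'
#' @param pixels (H, W, 3) array with values in [0, 255].
#' @param boxes data.frame with columns class_id, cx, cy, w, h (normalized).
#' @param imageId identifier string.
#' @param seed generator seed or NA.
#' @return A [LabeledImage-class] object.
#' @export
LabeledImage <- function(pixels, boxes = emptyBoxes(), imageId = "img", seed = NA_integer_) {
  new("LabeledImage", pixels = pixels, boxes = as.data.frame(boxes),
      imageId = as.character(imageId), seed = as.integer(seed))
}

#' Empty annotation table
#' @return Zero-row box data.frame.
#' @export
emptyBoxes <- function() {
  data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))
}

#' Deterministic train/test/val partition of image ids
#'
#' @slot train,test,val character id vectors (disjoint, exhaustive).
#' @slot fractions the three requested fractions (sum to 1).
#' @export
setClass("SplitManifest",
  representation(train = "character", test = "character", val = "character",
                 fractions = "numeric"),
  validity = function(object) {
    ids <- c(object@train, object@test, object@val)
    if (anyDuplicated(ids)) return("split lists must be disjoint")
    if (abs(sum(object@fractions) - 1) > 1e-9) return("fractions must sum to 1")
    TRUE
  })

#' Three-level feature pyramid
#'
#' Backbone/neck feature maps at strides 8, 16 and 32 (80x80, 40x40 and
#' 20x20 for a 640 input), responsible for small, medium and large objects.
#'
#' @slot p3,p4,p5 numeric (H, W, C) arrays.
#' @slot strides numeric, c(8, 16, 32).
#' @export
setClass("PyramidFeatures",
  representation(p3 = "array", p4 = "array", p5 = "array", strides = "numeric"),
  validity = function(object) {
    for (m in list(object@p3, object@p4, object@p5))
      if (length(dim(m)) != 3 || !all(is.finite(m)))
        return("feature maps must be finite (H, W, C) arrays")
    if (!identical(as.numeric(object@strides), c(8, 16, 32)))
      return("strides must be c(8, 16, 32)")
    TRUE
  })

#' Composite training loss, itemized
#'
#' Weighted sum of the Inner-IoU box term, classification and objectness
#' binary cross-entropies and the distribution (discretized side regression)
#' term.  Default weights follow the training configuration:
#' 7.5, 0.5, 0.7, 1.5.
#'
#' @slot box,cls,obj,dfl non-negative component values.
#' @slot weights numeric(4): box, cls, obj, dfl weights.
#' @slot total weighted sum.
#' @export
setClass("LossBreakdown",
  representation(box = "numeric", cls = "numeric", obj = "numeric",
                 dfl = "numeric", weights = "numeric", total = "numeric"),
  validity = function(object) {
    comp <- c(object@box, object@cls, object@obj, object@dfl)
    if (any(comp < -1e-9)) return("loss components must be non-negative")
    if (!is.finite(object@total)) return("total loss must be finite")
    expect <- sum(comp * object@weights)
    if (abs(expect - object@total) > 1e-6 * max(1, abs(expect)))
      return("total must equal the weighted component sum")
    TRUE
  })

LossBreakdown <- function(box, cls, obj, dfl, weights = c(7.5, 0.5, 0.7, 1.5)) {
  new("LossBreakdown", box = box, cls = cls, obj = obj, dfl = dfl,
      weights = weights, total = sum(c(box, cls, obj, dfl) * weights))
}

#' Detection metric report
#'
#' Per-class precision, recall, F1 and average precision at a 0.5 IoU match
#' threshold, plus their unweighted means over classes with at least one
#' ground-truth instance.
#'
#' @slot perClass data.frame: class, n_gt, tp, fp, fn, precision, recall, f1, ap.
#' @slot map50 mean average precision at IoU 0.5.
#' @slot precision,recall,f1 macro averages.
#' @export
setClass("MetricReport",
  representation(perClass = "data.frame", map50 = "numeric",
                 precision = "numeric", recall = "numeric", f1 = "numeric"),
  validity = function(object) {
    v <- c(object@map50, object@precision, object@recall, object@f1)
    if (any(v < -1e-12 | v > 1 + 1e-12)) return("metrics must be in [0, 1]")
    TRUE
  })

#' Model complexity audit
#'
#' Per-layer trainable parameter and FLOP counts obtained by walking the
#' architecture graph: convolution parameters are counted as
#' Kh*Kw*Cin*Cout (+Cout with bias), FLOPs as multiply-accumulate pairs
#' Kh*Kw*Cin*Cout*H*W over output maps; normalization and attention terms
#' are itemized separately.  GFLOPs = FLOPs / 1e9.
#'
#' @slot layers data.frame of per-layer records.
#' @slot totalParams,totalFlops totals over all layers.
#' @slot gflops totalFlops / 1e9.
#' @export
setClass("AuditReport",
  representation(layers = "data.frame", totalParams = "numeric",
                 totalFlops = "numeric", gflops = "numeric"),
  validity = function(object) {
    if (abs(sum(object@layers$params) - object@totalParams) > 0.5)
      return("totalParams must equal the sum of layer entries")
    if (abs(sum(object@layers$flops) - object@totalFlops) > 0.5)
      return("totalFlops must equal the sum of layer entries")
    if (abs(object@gflops - object@totalFlops / 1e9) > 1e-12 * max(1, object@gflops))
      return("gflops must equal totalFlops / 1e9")
    TRUE
  })

## ---- accessors and show methods ----

#' @describeIn LabeledImage-class pixel array accessor
#' @param x a LabeledImage
#' @export
pixels <- function(x) x@pixels

#' @describeIn LabeledImage-class annotation accessor
#' @export
boxes <- function(x) x@boxes

#' @describeIn LabeledImage-class id accessor
#' @export
imageId <- function(x) x@imageId

#' @describeIn SplitManifest-class id list accessor
#' @param x a SplitManifest
#' @param subset one of "train", "test", "val"
#' @export
splitIds <- function(x, subset = c("train", "test", "val")) {
  slot(x, match.arg(subset))
}

#' @describeIn PyramidFeatures-class feature map accessor
#' @param x a PyramidFeatures
#' @param level one of "p3", "p4", "p5"
#' @export
featureMap <- function(x, level = c("p3", "p4", "p5")) {
  slot(x, match.arg(level))
}

#' @describeIn AuditReport-class layer table accessor
#' @param x an AuditReport
#' @export
layerTable <- function(x) x@layers

#' @describeIn AuditReport-class total trainable parameters
#' @export
totalParams <- function(x) x@totalParams

#' @describeIn AuditReport-class total GFLOPs
#' @export
totalGFlops <- function(x) x@gflops

#' @describeIn MetricReport-class mAP at IoU 0.5
#' @param x a MetricReport
#' @export
mapAt50 <- function(x) x@map50

#' @describeIn MetricReport-class per-class metric table
#' @export
perClassMetrics <- function(x) x@perClass

#' @describeIn LossBreakdown-class weighted total loss
#' @param x a LossBreakdown
#' @export
totalLoss <- function(x) x@total

#' @describeIn LossBreakdown-class loss components as a named vector
#' @export
lossComponents <- function(x) {
  c(box = x@box, cls = x@cls, obj = x@obj, dfl = x@dfl)
}

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("LabeledImage '%s': %dx%d RGB, %d box(es)\n",
              object@imageId, d[2], d[1], nrow(object@boxes)))
  if (nrow(object@boxes)) {
    tab <- table(factor(object@boxes$class_id, levels = 0:4,
                        labels = stageNames()))
    cat("  stages:", paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
                           collapse = ", "), "\n")
  }
})

setMethod("show", "SplitManifest", function(object) {
  cat(sprintf("SplitManifest: train=%d test=%d val=%d (fractions %s)\n",
              length(object@train), length(object@test), length(object@val),
              paste(object@fractions, collapse = "/")))
})

setMethod("show", "PyramidFeatures", function(object) {
  for (lv in c("p3", "p4", "p5")) {
    d <- dim(slot(object, lv))
    cat(sprintf("  %s: %dx%dx%d (stride %d)\n", toupper(lv), d[1], d[2], d[3],
                c(p3 = 8, p4 = 16, p5 = 32)[[lv]]))
  }
})

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf("Loss: total=%.4f (box=%.4f cls=%.4f obj=%.4f dfl=%.4f)\n",
              object@total, object@box, object@cls, object@obj, object@dfl))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: mAP@0.5=%.4f P=%.4f R=%.4f F1=%.4f\n",
              object@map50, object@precision, object@recall, object@f1))
  print(object@perClass, row.names = FALSE)
})

setMethod("show", "AuditReport", function(object) {
  cat(sprintf("AuditReport: %d layers, %.3f M params, %.3f GFLOPs\n",
              nrow(object@layers), object@totalParams / 1e6, object@gflops))
})
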