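# Photometric and geometric augmentation, applied jointly to pixels and
# boxes.  The photometric operators act per pixel and channel and are clipped
# to the 8-bit range afterwards (the underlying adjustment formulas are
# unclipped and would overflow it):
#   brightness: v -> v + s          darkness: v -> v - s
#   chroma:     v -> v + s*(v - g)  with g the per-pixel channel mean.

#' Photometric augmentation operators
#'
#' `adjustBrightness` adds `s` to every channel value, `adjustDarkness`
#' subtracts it, and `adjustChroma` scales every channel's deviation from the
#' per-pixel channel mean by `1 + s` (saturation gain).  All outputs are
#' clipped to `[0, 255]`; boxes are untouched.
#'
#' @param img a [LabeledImage-class].
#' @param s adjustment intensity: non-negative for brightness/darkness
#'   (default 40 intensity levels), any real for chroma (default 0.4).
#' @return A [LabeledImage-class].
#' @export
adjustBrightness <- function(img, s = 40) {
  stopifnot(s >= 0)
  replacePixels(img, clip255(pixels(img) + s))
}

#' @rdname adjustBrightness
#' @export
adjustDarkness <- function(img, s = 40) {
  stopifnot(s >= 0)
  replacePixels(img, clip255(pixels(img) - s))
}

#' @rdname adjustBrightness
#' @export
adjustChroma <- function(img, s = 0.4) {
  px <- pixels(img)
  g <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  out <- px
  for (c in 1:3) out[, , c] <- px[, , c] + s * (px[, , c] - g)
  replacePixels(img, clip255(out))
}

replacePixels <- function(img, px) {
  LabeledImage(px, boxes(img), imageId = imageId(img), seed = img@seed)
}

#' Flip an image (and its boxes) about an axis
#'
#' Horizontal flips reflect left-right (`cx -> 1 - cx`), vertical flips
#' top-bottom (`cy -> 1 - cy`).  `mirrorImage` is the horizontal reflection
#' kept as an independent catalog entry so expansion counts stay
#' configurable.
#'
#' @param img a [LabeledImage-class].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return A [LabeledImage-class].
#' @export
flipImage <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  px <- pixels(img)
  b <- boxes(img)
  if (axis == "horizontal") {
    px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
    if (nrow(b)) b$cx <- 1 - b$cx
  } else {
    px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    if (nrow(b)) b$cy <- 1 - b$cy
  }
  LabeledImage(px, b, imageId = imageId(img), seed = img@seed)
}

#' @rdname flipImage
#' @export
mirrorImage <- function(img) flipImage(img, "horizontal")

#' Expand a dataset through the augmentation catalog
#'
#' Applies each operator in `operators` to each image and returns originals
#' plus augmented copies with suffixed ids (the default catalog of five
#' operators yields a 6x expansion).
#'
#' @param images list of [LabeledImage-class] objects.
#' @param operators subset of `c("flip", "mirror", "brightness", "darkness",
#'   "chroma")`; `"flip"` is the vertical flip, `"mirror"` the horizontal.
#' @param params list of operator intensities
#'   (`brightness`, `darkness`, `chroma`).
#' @return List of [LabeledImage-class] objects, originals first.
#' @export
augmentDataset <- function(images,
                           operators = c("flip", "mirror", "brightness",
                                         "darkness", "chroma"),
                           params = list(brightness = 40, darkness = 40,
                                         chroma = 0.4)) {
  operators <- match.arg(operators, several.ok = TRUE)
  out <- images
  for (op in operators) {
    out <- c(out, lapply(images, function(img) {
      aug <- switch(op,
        flip = flipImage(img, "vertical"),
        mirror = mirrorImage(img),
        brightness = adjustBrightness(img, params$brightness),
        darkness = adjustDarkness(img, params$darkness),
        chroma = adjustChroma(img, params$chroma))
      aug@imageId <- paste0(imageId(img), "_", op)
      aug
    }))
  }
  out
}
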