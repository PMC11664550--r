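# Grad-CAM++ class-activation heatmaps.
#
# The class score for a detector is taken as the total evidence for the
# class over all cells and levels: sum of sigmoid(cls_c) * sigmoid(obj).
# Weights use the published closed-form alpha built from elementwise powers
# of the first-order gradient:
#   alpha_ij^k = G_ij^2 / (2 G_ij^2 + sum_ab A_ab^k G_ab^3)
#   w_k = sum_ij alpha_ij^k ReLU(G_ij^k)
#   heatmap = ReLU(sum_k w_k A^k), min-max normalized, resized to the input.

#' Grad-CAM++ weights and heatmap from activations and gradients
#'
#' Pure computation used by [gradCamPP()]; exposed for direct verification
#' against analytic cases.
#'
#' @param A (H, W, K) activation maps of the chosen layer.
#' @param G (H, W, K) gradient of the class score w.r.t. `A`.
#' @return list: `weights` (length K), `heatmap` ((H, W), in [0, 1]),
#'   `zeroGradient` flag.
#' @export
gradCamWeights <- function(A, G) {
  d <- dim(A)
  K <- d[3]
  w <- numeric(K)
  for (k in seq_len(K)) {
    g <- G[, , k]
    denom <- 2 * g^2 + sum(A[, , k] * g^3)
    alpha <- ifelse(abs(denom) > 1e-12, g^2 / denom, 0)
    w[k] <- sum(alpha * pmax(g, 0))
  }
  h <- array(0, d[1:2])
  for (k in seq_len(K)) h <- h + w[k] * A[, , k]
  h <- pmax(h, 0)
  zero <- max(h) <= 0
  if (!zero) h <- (h - min(h)) / (max(h) - min(h))
  list(weights = w, heatmap = h, zeroGradient = zero)
}

#' Grad-CAM++ explanation for one image and class
#'
#' @param model a [StageNet-class].
#' @param x pixel array or [LabeledImage-class].
#' @param classId stage class index 0-4.
#' @param layer which feature map to explain (default the fused small-object
#'   level `"p3"`).
#' @return (H, W) heatmap in [0, 1] at input resolution, with attribute
#'   `"zeroGradient"` set when the class score had no gradient.
#' @export
gradCamPP <- function(model, x, classId, layer = c("p3", "p4", "p5",
                                                   "c3", "c4", "c5")) {
  layer <- match.arg(layer)
  xv <- norm_input(x)
  tp <- tp_new()
  fwd <- model_forward(model, tp, tp_leaf(tp, xv), train = FALSE)
  score <- NULL
  for (h in fwd$heads) {
    s <- ag_sum(tp, ag_mul(tp, ag_sigmoid(tp, ag_slice_c(tp, h$cls, classId + 1)),
                           ag_sigmoid(tp, h$obj)))
    score <- if (is.null(score)) s else ag_add(tp, score, s)
  }
  node <- fwd$nodes[[layer]]
  grads <- tp_backward(tp, score)
  G <- grads[[node]]
  A <- tp_v(tp, node)
  if (is.null(G)) G <- array(0, dim(A))
  res <- gradCamWeights(A, G)
  out <- bilinear_resize(array(res$heatmap, c(dim(A)[1:2], 1)),
                         dim(xv)[1], dim(xv)[2])[, , 1]
  attr(out, "zeroGradient") <- res$zeroGradient
  out
}

#' Save a heatmap as a PNG overlay
#'
#' @param img the explained [LabeledImage-class] (or pixel array).
#' @param heat (H, W) heatmap in [0, 1].
#' @param path output PNG.
#' @param alpha overlay strength.
#' @return `path`, invisibly.
#' @export
writeHeatmapPNG <- function(img, heat, path, alpha = 0.5) {
  px <- norm_input(img)
  ov <- px
  ov[, , 1] <- (1 - alpha) * px[, , 1] + alpha * heat
  ov[, , 2] <- (1 - alpha) * px[, , 2] + alpha * (1 - abs(2 * heat - 1))
  ov[, , 3] <- (1 - alpha) * px[, , 3] + alpha * (1 - heat)
  png::writePNG(pmin(pmax(ov, 0), 1), path)
  invisible(path)
}
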