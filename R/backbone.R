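# The lightweight mobile backbone: a 3x3 stride-2 stem followed by four
# Universal Inverted Bottleneck stages (strides 2 each, widths per config),
# with feature taps at strides 8/16/32 feeding the pyramid.  No fully
# connected layer; a global-average-pool head exists only as a utility.

#' Standard 2-D convolution (cross-correlation)
#'
#' Zero padding, "same" for stride 1; stride-2 convolutions use symmetric
#' `k %/% 2` padding so the output is `ceiling(input / stride)` for even
#' inputs.
#'
#' @param x numeric (H, W, Cin) array.
#' @param kernel numeric (kh, kw, Cin, Cout) array.
#' @param bias optional length-Cout vector.
#' @param stride positive integer stride.
#' @return (Hout, Wout, Cout) array.
#' @export
conv2d <- function(x, kernel, bias = NULL, stride = 1) {
  kd <- dim(kernel)
  if (length(kd) != 4) stop("kernel must be a 4-D (kh, kw, cin, cout) array")
  if (dim(x)[3] != kd[3])
    stop(sprintf("channel mismatch: input has %d, kernel expects %d",
                 dim(x)[3], kd[3]))
  wm <- matrix(kernel, kd[1] * kd[2] * kd[3], kd[4])
  cpp_conv2d_fw(x, dim(x), wm, kd[1], kd[2], stride, kd[1] %/% 2,
                if (is.null(bias)) numeric(0) else bias)
}

#' Depthwise 2-D convolution
#'
#' One spatial kernel per channel; channels never mix.
#'
#' @param x numeric (H, W, C) array.
#' @param kernel numeric (kh, kw, C) array, one kernel per input channel.
#' @inheritParams conv2d
#' @return (Hout, Wout, C) array.
#' @export
depthwiseConv <- function(x, kernel, stride = 1) {
  kd <- dim(kernel)
  if (length(kd) != 3) stop("kernel must be a 3-D (kh, kw, C) array")
  if (dim(x)[3] != kd[3])
    stop(sprintf("kernel/channel count mismatch: %d channels, %d kernels",
                 dim(x)[3], kd[3]))
  wm <- matrix(kernel, kd[1] * kd[2], kd[3])
  cpp_dwconv_fw(x, dim(x), wm, kd[1], kd[2], stride, kd[1] %/% 2)
}

#' Batch normalization (inference form)
#'
#' `y = gamma * (x - mean) / sqrt(var + eps) + beta`, per channel.  When
#' `mean`/`var` are omitted they are computed from the map itself (the
#' training-mode statistics over the spatial extent).
#'
#' @param x numeric (H, W, C) array.
#' @param gamma,beta trainable scale and shift (recycled to C).
#' @param mean,var per-channel statistics; NULL to use the map's own.
#' @param eps small positive constant preventing division by zero.
#' @return array shaped like `x`.
#' @export
batchNorm <- function(x, gamma = 1, beta = 0, mean = NULL, var = NULL,
                      eps = 1e-5) {
  stopifnot(eps > 0)
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  if (is.null(mean)) mean <- colMeans(m)
  if (is.null(var)) var <- colMeans(m^2) - colMeans(m)^2
  if (any(var < 0)) stop("variance must be non-negative")
  y <- sweep(sweep(m, 2, rep_len(mean, d[3]), `-`), 2,
             sqrt(rep_len(var, d[3]) + eps), `/`)
  y <- sweep(sweep(y, 2, rep_len(gamma, d[3]), `*`), 2, rep_len(beta, d[3]), `+`)
  array(y, d)
}

#' Rectified linear activation
#' @param x numeric array.
#' @return `pmax(x, 0)` with shape preserved.
#' @export
relu <- function(x) {
  y <- pmax(x, 0)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

#' Global average pooling
#' @param x numeric (H, W, C) array.
#' @return length-C vector of per-channel spatial means.
#' @export
globalAvgPool <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

#' Universal Inverted Bottleneck block (functional form)
#'
#' Pointwise expand -> BN -> ReLU -> depthwise (stride) -> BN -> ReLU ->
#' pointwise project -> BN, plus an identity shortcut when `stride == 1` and
#' the channel count is preserved.  Weights are drawn from a seeded He
#' initialization, or all zeros with `zeroWeights = TRUE` (useful for
#' verifying the shortcut identity).  The trainable parameter count of the
#' block is attached as attribute `"nparams"`.
#'
#' @param x numeric (H, W, Cin) array.
#' @param cout output channels.
#' @param expansion width multiplier of the expanded representation.
#' @param kernel depthwise kernel size (3 or 5).
#' @param stride 1 or 2.
#' @param zeroWeights use all-zero convolution weights.
#' @param seed init seed.
#' @return (Hout, Wout, cout) array with attribute `nparams`.
#' @export
uibBlock <- function(x, cout, expansion = 4, kernel = 3, stride = 1,
                     zeroWeights = FALSE, seed = 0) {
  cin <- dim(x)[3]
  m <- net_new(list(), seed = seed)
  add_uib(m, "uib", cin, cout, expansion, kernel, stride, down = 1)
  if (zeroWeights) {
    for (nm in grep("\\.w$", ls(m$par), value = TRUE)) m$par[[nm]][] <- 0
  }
  tp <- tp_new()
  y <- fw_uib(m, tp, tp_leaf(tp, x), "uib", train = TRUE)
  out <- tp_v(tp, y)
  attr(out, "nparams") <- net_nparams(m)
  out
}

## ---- backbone assembly ----

build_backbone <- function(model) {
  bk <- model$cfg$backbone
  down <- add_conv(model, "stem", 3, 3, 3, bk$stem, stride = 2, down = 1)
  cin <- bk$stem
  for (s in 1:4) {
    for (b in seq_len(bk$depths[s])) {
      name <- sprintf("s%d.b%d", s, b)
      stride <- if (b == 1) 2 else 1
      cout <- bk$widths[s]
      down <- add_uib(model, name, cin, cout, bk$expansions[s], bk$kernels[s],
                      stride, down)
      cin <- cout
    }
  }
  invisible(model)
}

# Forward through the backbone on an existing tape; returns node ids of the
# three pyramid taps (strides 8, 16, 32).
fw_backbone <- function(model, tp, x, train = FALSE) {
  bk <- model$cfg$backbone
  y <- fw_conv(model, tp, x, "stem", train)
  taps <- list()
  for (s in 1:4) {
    for (b in seq_len(bk$depths[s])) {
      y <- fw_uib(model, tp, y, sprintf("s%d.b%d", s, b), train)
    }
    if (s >= 2) taps[[s - 1]] <- y   # stages 2..4 sit at strides 8/16/32
  }
  taps
}

#' Run the backbone and return the three-level feature pyramid
#'
#' @param model a detector built by [stageNet()].
#' @param x an (H, W, 3) pixel array (0-255 or 0-1) or a
#'   [LabeledImage-class]; H and W must be divisible by 32.
#' @return A [PyramidFeatures-class] with maps at strides 8, 16 and 32.
#' @export
backboneForward <- function(model, x) {
  m <- model_env(model)
  if (is(x, "LabeledImage")) x <- pixels(x)
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("input spatial dims must be divisible by 32")
  if (max(x) > 1.5) x <- x / 255
  tp <- tp_new()
  taps <- fw_backbone(m, tp, tp_leaf(tp, x), train = FALSE)
  new("PyramidFeatures", p3 = tp_v(tp, taps[[1]]), p4 = tp_v(tp, taps[[2]]),
      p5 = tp_v(tp, taps[[3]]), strides = c(8, 16, 32))
}
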