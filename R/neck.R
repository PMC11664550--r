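# Neck blocks: DySample adaptive upsampling, SPPELAN spatial pyramid pooling,
# AConv downsampling, reparameterizable RepNCSPELAN4 aggregation, iRMB
# windowed attention and the dual-stream fusion combining the RepNCSPELAN4
# and iRMB streams.

## ---- DySample ----

# Pixel-shuffle index: maps the (2H, 2W, 2G) offset field to the offset-head
# output (H, W, 2G*scale^2).  Channel layout of the head output:
# ch = ((f-1)*scale^2) + (dy*scale + dx) + 1 for field f in 1..2G.
dysample_shuffle_idx <- function(H, W, G, scale) {
  Ho <- H * scale; Wo <- W * scale
  oy <- rep(seq_len(Ho), times = Wo * 2 * G)
  ox <- rep(rep(seq_len(Wo), each = Ho), times = 2 * G)
  f <- rep(seq_len(2 * G), each = Ho * Wo)
  iy <- (oy - 1) %/% scale + 1
  ix <- (ox - 1) %/% scale + 1
  sub <- ((oy - 1) %% scale) * scale + (ox - 1) %% scale
  ch <- (f - 1) * scale^2 + sub + 1
  iy + H * (ix - 1) + H * W * (ch - 1)
}

# DySample on the tape: offsets from a zero-initialised 1x1 projection,
# pixel-shuffled to output resolution, scaled by the range factor and added
# to the regular bilinear grid (half-pixel centres); bilinear resampling with
# border clamping.
fw_dysample <- function(model, tp, x, name, scale = 2, train = FALSE) {
  cfg <- model$cfg$dysample
  G <- cfg$groups
  off <- fw_conv(model, tp, x, paste0(name, ".off"), train)
  d <- dim(tp_v(tp, x))
  H <- d[1]; W <- d[2]
  Ho <- H * scale; Wo <- W * scale
  idx <- dysample_shuffle_idx(H, W, G, scale)
  offs <- ag_gather(tp, off, idx, c(Ho, Wo, 2 * G))
  ox <- ag_slice_c(tp, offs, seq_len(G))
  oy <- ag_slice_c(tp, offs, G + seq_len(G))
  basex <- array(rep((seq_len(Wo) - 0.5) / scale - 0.5, each = Ho), c(Ho, Wo, G))
  basey <- array(rep((seq_len(Ho) - 0.5) / scale - 0.5, times = Wo), c(Ho, Wo, G))
  sx <- ag_add(tp, ag_smul(tp, ox, cfg$range), tp_leaf(tp, basex))
  sy <- ag_add(tp, ag_smul(tp, oy, cfg$range), tp_leaf(tp, basey))
  ag_gridsample(tp, x, sx, sy)
}

add_dysample <- function(model, name, cin, scale, down) {
  cfg <- model$cfg$dysample
  add_conv(model, paste0(name, ".off"), 1, 1, cin, 2 * cfg$groups * scale^2,
           stride = 1, down = down, bias = TRUE, bn = FALSE, act = "none",
           zero_init = TRUE)
  invisible(down / scale)
}

#' DySample adaptive upsampling (functional form)
#'
#' Treats upsampling as point-based resampling: a linear (1x1) projection of
#' the input predicts per-pixel offsets `O` which, scaled by `rangeFactor`,
#' perturb the regular upsampling grid `G`; the output is the bilinear
#' resampling of the input at `S = G + O`.  With a zero offset head this is
#' exactly plain bilinear upsampling.
#'
#' @param x numeric (H, W, C) array.
#' @param scale integer upsampling factor (>= 2).
#' @param groups number of offset groups sharing a coordinate field.
#' @param rangeFactor scale applied to raw offsets (input pixel units).
#' @param offsetWeight (1, 1, C, 2*groups*scale^2) projection kernel;
#'   NULL for zeros.
#' @param offsetBias length 2*groups*scale^2 bias; NULL for zeros.
#' @return (scale*H, scale*W, C) array.
#' @export
dySample <- function(x, scale = 2, groups = 4, rangeFactor = 0.25,
                     offsetWeight = NULL, offsetBias = NULL) {
  stopifnot(scale >= 2, scale == round(scale))
  cin <- dim(x)[3]
  if (cin %% groups != 0) groups <- 1
  m <- net_new(list(dysample = list(groups = groups, range = rangeFactor)))
  add_dysample(m, "dy", cin, scale, down = 1)
  if (!is.null(offsetWeight))
    m$par[["dy.off.w"]] <- matrix(offsetWeight, cin, 2 * groups * scale^2)
  if (!is.null(offsetBias)) m$par[["dy.off.b"]] <- offsetBias
  tp <- tp_new()
  tp_v(tp, fw_dysample(m, tp, tp_leaf(tp, x), "dy", scale))
}

## ---- SPPELAN ----

add_sppelan <- function(model, name, cin, cmid, cout, down) {
  add_conv(model, paste0(name, ".cv1"), 1, 1, cin, cmid, 1, down)
  add_conv(model, paste0(name, ".cv2"), 1, 1, 4 * cmid, cout, 1, down)
  model$layers[[name]] <- list(kind = "sppelan", cin = cin, cmid = cmid,
                               cout = cout)
  invisible(down)
}

fw_sppelan <- function(model, tp, x, name, train = FALSE, poolSizes = c(5, 5, 5)) {
  y <- fw_conv(model, tp, x, paste0(name, ".cv1"), train)
  pools <- list(y)
  for (k in poolSizes) {
    pools[[length(pools) + 1]] <- ag_maxpool(tp, pools[[length(pools)]], k, 1, k %/% 2)
  }
  fw_conv(model, tp, ag_concat_c(tp, pools), paste0(name, ".cv2"), train)
}

#' SPPELAN spatial pyramid pooling block (functional form)
#'
#' A pointwise reduction followed by sequential same-resolution max pools
#' (default sizes 5, 5, 5) whose outputs are concatenated with the reduction
#' and fused by a pointwise convolution.
#'
#' @param x numeric (H, W, C) array.
#' @param cout output channels.
#' @param cmid internal width (default `cout`).
#' @param poolSizes max-pool window sizes applied sequentially.
#' @param seed weight init seed.
#' @return (H, W, cout) array.
#' @export
sppELAN <- function(x, cout, cmid = cout, poolSizes = c(5, 5, 5), seed = 0) {
  m <- net_new(list(), seed = seed)
  add_sppelan(m, "spp", dim(x)[3], cmid, cout, 1)
  tp <- tp_new()
  tp_v(tp, fw_sppelan(m, tp, tp_leaf(tp, x), "spp", train = TRUE,
                      poolSizes = poolSizes))
}

#' Concatenate feature maps along channels
#' @param ... numeric (H, W, Ci) arrays sharing spatial dims.
#' @return (H, W, sum Ci) array.
#' @export
concatFeatures <- function(...) {
  maps <- list(...)
  d1 <- dim(maps[[1]])
  for (m in maps)
    if (!all(dim(m)[1:2] == d1[1:2])) stop("spatial dims must match for concat")
  tp <- tp_new()
  tp_v(tp, ag_concat_c(tp, lapply(maps, tp_leaf, tp = tp)))
}

#' AConv downsampling convolution (functional form)
#'
#' A stride-2 3x3 convolution with normalization and ReLU, used on the
#' bottom-up return paths of the neck.
#'
#' @param x numeric (H, W, C) array.
#' @param cout output channels.
#' @param seed weight init seed.
#' @return (ceiling(H/2), ceiling(W/2), cout) array.
#' @export
aConv <- function(x, cout, seed = 0) {
  m <- net_new(list(), seed = seed)
  add_conv(m, "ac", 3, 3, dim(x)[3], cout, stride = 2, down = 1)
  tp <- tp_new()
  tp_v(tp, fw_conv(m, tp, tp_leaf(tp, x), "ac", train = TRUE))
}

## ---- RepNCSPELAN4 ----

add_repncspelan4 <- function(model, name, cin, cmid, cout, down) {
  add_conv(model, paste0(name, ".cv1"), 1, 1, cin, cmid, 1, down)
  half <- cmid %/% 2
  add_repconv(model, paste0(name, ".r1"), half, half, down)
  add_repconv(model, paste0(name, ".r2"), half, half, down)
  add_conv(model, paste0(name, ".cv2"), 1, 1, half * 3, cout, 1, down)
  model$layers[[name]] <- list(kind = "repncspelan4", cin = cin, cmid = cmid,
                               cout = cout)
  invisible(down)
}

fw_repncspelan4 <- function(model, tp, x, name, train = FALSE, deploy = FALSE) {
  sp <- model$layers[[name]]
  half <- sp$cmid %/% 2
  y <- fw_conv(model, tp, x, paste0(name, ".cv1"), train)
  a <- ag_slice_c(tp, y, seq_len(half))
  b <- ag_slice_c(tp, y, half + seq_len(half))
  r1 <- fw_repconv(model, tp, b, paste0(name, ".r1"), train, deploy)
  r2 <- fw_repconv(model, tp, r1, paste0(name, ".r2"), train, deploy)
  fw_conv(model, tp, ag_concat_c(tp, list(a, r1, r2)), paste0(name, ".cv2"), train)
}

#' Multi-branch reparameterizable convolution (functional form)
#'
#' Training mode evaluates the sum of the branch convolutions (plus an
#' optional identity branch); deploy mode evaluates the single convolution
#' whose kernel merges all branches (smaller kernels centre-padded into the
#' largest).  Both modes are mathematically identical.
#'
#' @param x numeric (H, W, Cin) array.
#' @param branches list of (kh, kw, Cin, Cout) kernels with odd kh = kw.
#' @param identity include an identity branch (requires Cin == Cout).
#' @param bias optional length-Cout bias added once.
#' @param mode `"train"` (multi-branch sum) or `"deploy"` (merged kernel).
#' @return (H, W, Cout) array.
#' @export
repConvBlock <- function(x, branches, identity = FALSE, bias = NULL,
                         mode = c("train", "deploy")) {
  mode <- match.arg(mode)
  ks <- vapply(branches, function(b) dim(b)[1], numeric(1))
  cin <- dim(branches[[1]])[3]; cout <- dim(branches[[1]])[4]
  if (identity && cin != cout)
    stop("identity branch requires matching channel counts")
  if (any(vapply(branches, function(b) any(dim(b)[3:4] != c(cin, cout)), logical(1))))
    stop("branches must share channel geometry")
  if (mode == "train") {
    y <- 0
    for (b in branches) y <- y + conv2d(x, b, stride = 1)
    if (identity) y <- y + x
    if (!is.null(bias)) y <- sweep(y, 3, bias, `+`)
    y
  } else {
    conv2d(x, mergeRepBranches(branches, identity), bias = bias, stride = 1)
  }
}

#' @rdname repConvBlock
#' @return `mergeRepBranches`: the single merged (k, k, Cin, Cout) kernel.
#' @export
mergeRepBranches <- function(branches, identity = FALSE) {
  ks <- vapply(branches, function(b) dim(b)[1], numeric(1))
  k <- max(ks)
  cin <- dim(branches[[1]])[3]; cout <- dim(branches[[1]])[4]
  merged <- array(0, c(k, k, cin, cout))
  for (b in branches) {
    kb <- dim(b)[1]
    r <- (k - kb) %/% 2 + seq_len(kb)
    merged[r, r, , ] <- merged[r, r, , ] + as.vector(b)
  }
  if (identity) {
    c0 <- (k + 1) %/% 2
    for (c in seq_len(cin)) merged[c0, c0, c, c] <- merged[c0, c0, c, c] + 1
  }
  merged
}

## ---- iRMB (EW-MHSA + depthwise conv, inverted-residual shortcut) ----

# Window index plan for expanded-window attention: for each query window the
# key/value window extends `ext` pixels on every side.  Only valid positions
# are gathered, so no masking is needed.
irmb_window_plan <- function(H, W, window, ext) {
  key <- sprintf("%d_%d_%d_%d", H, W, window, ext)
  cache <- irmb_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  plan <- list()
  for (wi in seq_len(ceiling(H / window))) {
    for (wj in seq_len(ceiling(W / window))) {
      qh <- ((wi - 1) * window + 1):min(wi * window, H)
      qw <- ((wj - 1) * window + 1):min(wj * window, W)
      kh <- max(1, qh[1] - ext):min(H, qh[length(qh)] + ext)
      kw <- max(1, qw[1] - ext):min(W, qw[length(qw)] + ext)
      qpos <- as.vector(outer(qh, (qw - 1) * H, `+`))
      kpos <- as.vector(outer(kh, (kw - 1) * H, `+`))
      plan[[length(plan) + 1]] <- list(q = qpos, k = kpos)
    }
  }
  cache[[key]] <- plan
  plan
}

irmb_cache <- new.env(parent = emptyenv())

add_irmb <- function(model, name, c, down) {
  cfg <- model$cfg$irmb
  add_conv(model, paste0(name, ".q"), 1, 1, c, c, 1, down, bn = FALSE, act = "none")
  add_conv(model, paste0(name, ".k"), 1, 1, c, c, 1, down, bn = FALSE, act = "none")
  add_conv(model, paste0(name, ".v"), 1, 1, c, c, 1, down, bn = FALSE, act = "none")
  add_attn_audit(model, paste0(name, ".attn"), c, cfg$window, cfg$ext, down)
  add_dwconv(model, paste0(name, ".dw"), 3, c, 1, down)
  model$layers[[name]] <- list(kind = "irmb", c = c)
  invisible(down)
}

fw_irmb <- function(model, tp, x, name, train = FALSE, diag = NULL) {
  cfg <- model$cfg$irmb
  d <- dim(tp_v(tp, x))
  H <- d[1]; W <- d[2]; C <- d[3]
  heads <- cfg$heads
  if (C %% heads != 0) stop("channels must be divisible by heads")
  dh <- C %/% heads
  q <- fw_conv(model, tp, x, paste0(name, ".q"), train)
  k <- fw_conv(model, tp, x, paste0(name, ".k"), train)
  v <- fw_conv(model, tp, x, paste0(name, ".v"), train)
  plan <- irmb_window_plan(H, W, cfg$window, cfg$ext)
  attn <- ag_ewmhsa(tp, q, k, v, plan, heads)
  if (!is.null(diag)) {
    # softmax row sums recomputed for diagnostics (attention is one node)
    qv <- tp_v(tp, q); kv <- tp_v(tp, k)
    HW <- H * W
    qm <- matrix(qv, HW, C); km <- matrix(kv, HW, C)
    dhh <- C %/% heads
    for (i in seq_along(plan)) {
      for (h in seq_len(heads)) {
        cols <- (h - 1) * dhh + seq_len(dhh)
        A <- tcrossprod(qm[plan[[i]]$q, cols, drop = FALSE],
                        km[plan[[i]]$k, cols, drop = FALSE]) / sqrt(dhh)
        P <- exp(A - apply(A, 1, max))
        diag$rowsums <- c(diag$rowsums, rowSums(P / rowSums(P)))
      }
    }
  }
  y <- fw_conv(model, tp, attn, paste0(name, ".dw"), train)
  ag_add(tp, x, y)
}

#' iRMB: expanded-window multi-head self-attention + depthwise convolution
#'
#' Windowed multi-head self-attention in which key/value windows extend
#' `ext` pixels beyond each query window (overlapping receptive fields),
#' followed by a 3x3 depthwise convolution, with an inverted-residual
#' shortcut from the input.  Shape is preserved.
#'
#' @param x numeric (H, W, C) array; C must be divisible by `heads`.
#' @param heads number of attention heads.
#' @param window query window side length.
#' @param ext key/value window expansion in pixels per side.
#' @param seed projection init seed.
#' @param identityValue use an identity value projection and a delta
#'   depthwise kernel with no normalization (degenerate configuration used
#'   to verify the attention path).
#' @return (H, W, C) array; attribute `"attnRowSums"` carries the softmax
#'   row sums of every attention matrix.
#' @export
irmb <- function(x, heads = 4, window = 7, ext = 2, seed = 0,
                 identityValue = FALSE) {
  C <- dim(x)[3]
  if (C %% heads != 0) stop("channels must be divisible by heads")
  m <- net_new(list(irmb = list(heads = heads, window = window, ext = ext)),
               seed = seed)
  add_irmb(m, "ir", C, 1)
  if (identityValue) {
    m$par[["ir.v.w"]] <- diag(C)
    m$par[["ir.dw.w"]] <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 9, C)
    m$layers[["ir.dw"]]$bn <- FALSE
    m$layers[["ir.dw"]]$act <- "none"
  }
  diag <- new.env(); diag$rowsums <- numeric(0)
  tp <- tp_new()
  out <- tp_v(tp, fw_irmb(m, tp, tp_leaf(tp, x), "ir",
                          train = !identityValue, diag = diag))
  attr(out, "attnRowSums") <- diag$rowsums
  out
}

## ---- dual-stream fusion ----

add_fuse <- function(model, name, cin, cout, down, cmid = cout) {
  add_repncspelan4(model, paste0(name, ".rep"), cin, cmid, cout, down)
  add_conv(model, paste0(name, ".proj"), 1, 1, cin, cout, 1, down)
  add_irmb(model, paste0(name, ".irmb"), cout, down)
  add_vector_param(model, paste0(name, ".lambda"), cout, 1, "fusion_weights", down)
  add_vector_param(model, paste0(name, ".mu"), cout, 1, "fusion_weights", down)
  add_conv(model, paste0(name, ".refine"), 1, 1, cout, cout, 1, down)
  model$layers[[name]] <- list(kind = "fuse", cin = cin, cout = cout)
  invisible(down)
}

# Dual-stream fusion: stream A = RepNCSPELAN4(x), stream B = iRMB(proj(x));
# fused = (lambda.A + 1) + (mu.B + 1), then a confidence-gated pointwise
# refinement convolution applied when the mean absolute activation exceeds
# the configured threshold (default 0, i.e. always on).
fw_fuse <- function(model, tp, x, name, train = FALSE, deploy = FALSE) {
  a <- fw_repncspelan4(model, tp, x, paste0(name, ".rep"), train, deploy)
  b <- fw_conv(model, tp, x, paste0(name, ".proj"), train)
  b <- fw_irmb(model, tp, b, paste0(name, ".irmb"), train)
  lam <- tp_leaf(tp, model$par[[paste0(name, ".lambda")]], paste0(name, ".lambda"))
  mu <- tp_leaf(tp, model$par[[paste0(name, ".mu")]], paste0(name, ".mu"))
  fused <- ag_add(tp, ag_addc(tp, ag_mul_chan(tp, a, lam), 1),
                  ag_addc(tp, ag_mul_chan(tp, b, mu), 1))
  if (mean(abs(tp_v(tp, fused))) > model$cfg$fusion$tau) {
    fused <- fw_conv(model, tp, fused, paste0(name, ".refine"), train)
  }
  fused
}

#' Dual-stream feature fusion combine
#'
#' Combines a RepNCSPELAN4 stream `A` and an iRMB stream `B` as
#' `(lambda * A + 1) + (mu * B + 1)` with per-channel trainable weights,
#' optionally followed by a confidence-gated pointwise refinement
#' convolution applied when the mean absolute activation exceeds `tau`.
#'
#' @param A,B numeric (H, W, C) stream outputs of identical shape.
#' @param lambda,mu per-channel weights (recycled to C).
#' @param refineKernel optional (1, 1, C, C) refinement kernel; NULL skips
#'   refinement (the pre-refinement fusion).
#' @param tau confidence threshold on mean absolute fused activation.
#' @return (H, W, C) array.
#' @export
dualStreamFuse <- function(A, B, lambda = 1, mu = 1, refineKernel = NULL,
                           tau = 0) {
  if (!all(dim(A) == dim(B))) stop("stream shapes must match")
  C <- dim(A)[3]
  fused <- sweep(A, 3, rep_len(lambda, C), `*`) + 1 +
    sweep(B, 3, rep_len(mu, C), `*`) + 1
  if (!is.null(refineKernel) && mean(abs(fused)) > tau) {
    fused <- conv2d(fused, refineKernel)
  }
  fused
}
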