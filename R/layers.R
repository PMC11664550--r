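# Network builder and tape-level layer primitives.
#
# A model is an environment holding
#   $par    environment of named parameter arrays
#   $bn     environment of running batch-norm statistics (list(mean, var))
#   $layers named list of layer specs (kind, kernel, channels, stride, ...)
#   $graph  ordered audit rows: params exactly, FLOPs as MACs over the output
#           map at a reference input size (down = cumulative downsampling of
#           the layer output, so H = W = input / down)
#   $cfg    architecture configuration
# Convolution weights are stored as (kh*kw*cin) x cout matrices whose row
# order equals the column-major order of a (kh, kw, cin) array.

net_new <- function(cfg, seed = 0) {
  m <- new.env(parent = emptyenv())
  m$par <- new.env(parent = emptyenv())
  m$bn <- new.env(parent = emptyenv())
  m$layers <- list()
  m$graph <- list()
  m$cfg <- cfg
  m$rng <- seed
  m
}

net_params <- function(model) {
  nms <- sort(ls(model$par))
  setNames(lapply(nms, function(n) model$par[[n]]), nms)
}

net_nparams <- function(model) {
  sum(vapply(net_params(model), length, numeric(1)))
}

# He-style init, deterministic given the builder seed and parameter name.
he_init <- function(model, n, fanin) {
  model$rng <- model$rng + 1L
  with_seed(model$rng, rnorm(n, 0, sqrt(2 / fanin)))
}

audit_row <- function(name, kind, kh, kw, cin, cout, stride, down, params,
                      macs_per_px = kh * kw * cin * cout) {
  list(name = name, kind = kind, kh = kh, kw = kw, cin = cin, cout = cout,
       stride = stride, down = down, params = params, macs_per_px = macs_per_px)
}

# Register a convolution (+ optional BN) layer.  `down` is the cumulative
# downsampling factor of the layer INPUT; returns the output down factor.
add_conv <- function(model, name, kh, kw, cin, cout, stride = 1, down = 1,
                     bias = FALSE, bn = TRUE, act = "relu", zero_init = FALSE) {
  w <- matrix(if (zero_init) 0 else he_init(model, kh * kw * cin * cout, kh * kw * cin),
              kh * kw * cin, cout)
  model$par[[paste0(name, ".w")]] <- w
  if (bias) model$par[[paste0(name, ".b")]] <- numeric(cout)
  dout <- down * stride
  model$graph[[length(model$graph) + 1]] <-
    audit_row(name, "conv", kh, kw, cin, cout, stride, dout,
              kh * kw * cin * cout + if (bias) cout else 0)
  if (bn) {
    model$par[[paste0(name, ".g")]] <- rep(1, cout)
    model$par[[paste0(name, ".beta")]] <- numeric(cout)
    model$bn[[name]] <- list(mean = numeric(cout), var = rep(1, cout))
    model$graph[[length(model$graph) + 1]] <-
      audit_row(paste0(name, ".bn"), "bn", 1, 1, cout, 1, 1, dout, 2 * cout, 2 * cout)
  }
  model$layers[[name]] <- list(kind = "conv", kh = kh, kw = kw, cin = cin,
                               cout = cout, stride = stride, bias = bias,
                               bn = bn, act = act)
  invisible(dout)
}

add_dwconv <- function(model, name, k, c, stride = 1, down = 1, bn = TRUE,
                       act = "relu") {
  model$par[[paste0(name, ".w")]] <-
    matrix(he_init(model, k * k * c, k * k), k * k, c)
  dout <- down * stride
  model$graph[[length(model$graph) + 1]] <-
    audit_row(name, "dwconv", k, k, 1, c, stride, dout, k * k * c, k * k * c)
  if (bn) {
    model$par[[paste0(name, ".g")]] <- rep(1, c)
    model$par[[paste0(name, ".beta")]] <- numeric(c)
    model$bn[[name]] <- list(mean = numeric(c), var = rep(1, c))
    model$graph[[length(model$graph) + 1]] <-
      audit_row(paste0(name, ".bn"), "bn", 1, 1, c, 1, 1, dout, 2 * c, 2 * c)
  }
  model$layers[[name]] <- list(kind = "dwconv", kh = k, kw = k, cin = c,
                               cout = c, stride = stride, bn = bn, act = act)
  invisible(dout)
}

add_vector_param <- function(model, name, n, value = 1, kind = "weights",
                             down = 1) {
  model$par[[name]] <- rep(value, n)
  model$graph[[length(model$graph) + 1]] <-
    audit_row(name, kind, 1, 1, n, 1, 1, down, n, n)
  invisible(NULL)
}

# Attention audit entry: QK^T and PV matrix-product MACs per query pixel.
add_attn_audit <- function(model, name, c, window, ext, down) {
  keys <- (window + 2 * ext)^2
  model$graph[[length(model$graph) + 1]] <-
    audit_row(name, "attn_matmul", 1, 1, c, 1, 1, down, 0, 2 * keys * c)
  invisible(NULL)
}

## ---- forward primitives ----

bn_eps <- 1e-5
bn_momentum <- 0.1

# Conv -> (BN) -> (activation).  In training mode BN uses the map's own
# spatial statistics and running averages are updated; in inference mode the
# stored running statistics are folded into a fixed per-channel affine.
fw_conv <- function(model, tp, x, name, train = FALSE) {
  sp <- model$layers[[name]]
  w <- tp_leaf(tp, model$par[[paste0(name, ".w")]], paste0(name, ".w"))
  b <- if (isTRUE(sp$bias)) tp_leaf(tp, model$par[[paste0(name, ".b")]], paste0(name, ".b"))
  y <- if (sp$kind == "dwconv") {
    ag_dwconv(tp, x, w, sp$kh, sp$kw, sp$stride, sp$kh %/% 2)
  } else {
    ag_conv2d(tp, x, w, b, sp$kh, sp$kw, sp$stride, sp$kh %/% 2)
  }
  if (isTRUE(sp$bn)) y <- fw_bn(model, tp, y, name, train)
  if (identical(sp$act, "relu")) y <- ag_relu(tp, y)
  y
}

# Normalization uses the map's own per-channel spatial statistics in both
# training and inference (batch-free normalization: batches are processed
# image by image, so the map statistics ARE the batch statistics).  This
# keeps inference consistent with the statistics the weights were trained
# under; running averages are still maintained as a diagnostic.
fw_bn <- function(model, tp, x, name, train) {
  g <- tp_leaf(tp, model$par[[paste0(name, ".g")]], paste0(name, ".g"))
  be <- tp_leaf(tp, model$par[[paste0(name, ".beta")]], paste0(name, ".beta"))
  y <- ag_bn_train(tp, x, g, be, bn_eps)
  if (train) {
    rs <- model$bn[[name]]
    model$bn[[name]] <- list(
      mean = (1 - bn_momentum) * rs$mean + bn_momentum * attr(y, "mean"),
      var = (1 - bn_momentum) * rs$var + bn_momentum * attr(y, "var"))
  }
  as.integer(y)
}

## ---- UIB block ----

# Universal Inverted Bottleneck: pointwise expand -> depthwise (stride) ->
# pointwise project, BN throughout, ReLU on expand/depthwise, linear
# projection, with an identity shortcut when stride 1 and cin == cout.
add_uib <- function(model, name, cin, cout, expansion, k, stride, down) {
  ce <- round(cin * expansion)
  add_conv(model, paste0(name, ".exp"), 1, 1, cin, ce, 1, down)
  d2 <- add_dwconv(model, paste0(name, ".dw"), k, ce, stride, down)
  add_conv(model, paste0(name, ".proj"), 1, 1, ce, cout, 1, d2, act = "none")
  model$layers[[name]] <- list(kind = "uib", cin = cin, cout = cout,
                               stride = stride,
                               shortcut = stride == 1 && cin == cout)
  invisible(d2)
}

fw_uib <- function(model, tp, x, name, train = FALSE) {
  sp <- model$layers[[name]]
  y <- fw_conv(model, tp, x, paste0(name, ".exp"), train)
  y <- fw_conv(model, tp, y, paste0(name, ".dw"), train)
  y <- fw_conv(model, tp, y, paste0(name, ".proj"), train)
  if (sp$shortcut) y <- ag_add(tp, y, x)
  y
}

## ---- reparameterizable conv (RepConv) ----

# Parallel 3x3 + 1x1 (+ identity when shapes allow) branches summed, then
# BN + ReLU.  Because normalization sits after the sum, deploy mode can merge
# the branches into a single 3x3 kernel exactly.
add_repconv <- function(model, name, cin, cout, down) {
  add_conv(model, paste0(name, ".k3"), 3, 3, cin, cout, 1, down, bn = FALSE, act = "none")
  add_conv(model, paste0(name, ".k1"), 1, 1, cin, cout, 1, down, bn = FALSE, act = "none")
  model$par[[paste0(name, ".g")]] <- rep(1, cout)
  model$par[[paste0(name, ".beta")]] <- numeric(cout)
  model$bn[[name]] <- list(mean = numeric(cout), var = rep(1, cout))
  model$graph[[length(model$graph) + 1]] <-
    audit_row(paste0(name, ".bn"), "bn", 1, 1, cout, 1, 1, down, 2 * cout, 2 * cout)
  model$layers[[name]] <- list(kind = "repconv", cin = cin, cout = cout,
                               identity = cin == cout)
  invisible(down)
}

# Merge rep branches into one (3*3*cin) x cout kernel matrix.
merge_rep_kernel <- function(w3, w1, cin, cout, identity = FALSE) {
  k <- array(w3, c(3, 3, cin, cout))
  k1 <- array(w1, c(1, 1, cin, cout))
  k[2, 2, , ] <- k[2, 2, , ] + k1[1, 1, , ]
  if (identity) for (c in seq_len(cin)) k[2, 2, c, c] <- k[2, 2, c, c] + 1
  matrix(k, 9 * cin, cout)
}

fw_repconv <- function(model, tp, x, name, train = FALSE, deploy = FALSE) {
  sp <- model$layers[[name]]
  if (deploy) {
    wm <- merge_rep_kernel(model$par[[paste0(name, ".k3.w")]],
                           model$par[[paste0(name, ".k1.w")]],
                           sp$cin, sp$cout, sp$identity)
    w <- tp_leaf(tp, wm)
    y <- ag_conv2d(tp, x, w, NULL, 3, 3, 1, 1)
  } else {
    w3 <- tp_leaf(tp, model$par[[paste0(name, ".k3.w")]], paste0(name, ".k3.w"))
    w1 <- tp_leaf(tp, model$par[[paste0(name, ".k1.w")]], paste0(name, ".k1.w"))
    y <- ag_add(tp, ag_conv2d(tp, x, w3, NULL, 3, 3, 1, 1),
                ag_conv2d(tp, x, w1, NULL, 1, 1, 1, 0))
    if (sp$identity) y <- ag_add(tp, y, x)
  }
  y <- fw_bn(model, tp, y, name, train)
  ag_relu(tp, y)
}
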