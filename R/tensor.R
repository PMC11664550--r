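# Internal reverse-mode autodiff tape.
#
# Feature maps are plain numeric arrays of dim (H, W, C); a node on the tape is
# identified by an integer id.  Backward functions are closures returning one
# gradient per parent.  The tape is rebuilt for every forward pass (define-by-
# run), which keeps control flow (window partitioning, per-scale heads, the
# confidence gate of the fusion block) ordinary R code.

tp_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$val <- vector("list", 256L)
  tp$parents <- vector("list", 256L)
  tp$back <- vector("list", 256L)
  tp$leaf <- list()
  tp
}

tp_push <- function(tp, value, parents = integer(0), backfn = NULL) {
  # Force promises first: evaluating them may create parent nodes, and ids
  # must stay topologically ordered.
  force(value)
  parents <- as.integer(parents)
  force(backfn)

  id <- tp$n + 1L
  if (id > length(tp$val)) {       # grow by doubling
    length(tp$val) <- 2L * length(tp$val)
    length(tp$parents) <- 2L * length(tp$parents)
    length(tp$back) <- 2L * length(tp$back)
  }
  tp$n <- id
  tp$val[[id]] <- value
  tp$parents[[id]] <- parents
  tp$back[[id]] <- backfn
  id
}

tp_leaf <- function(tp, value, name = NULL) {
  id <- tp_push(tp, value)
  if (!is.null(name)) tp$leaf[[name]] <- id
  id
}

tp_v <- function(tp, id) {
  force(id)  # node-creating promises must run before tp$val is fetched
  tp$val[[id]]
}

#' Run backpropagation from a scalar node.
#'
#' Returns the full list of gradients (NULL where a node does not influence
#' the seed node); leaf gradients are looked up through `tp$leaf`.
#' @noRd
tp_backward <- function(tp, id, seed = 1) {
  grads <- vector("list", tp$n)
  v <- tp$val[[id]]
  g0 <- if (length(seed) == 1L && length(v) > 1L) array(seed, dim(v) %||% length(v)) else seed
  grads[[id]] <- g0
  for (i in seq(id, 1L)) {
    gi <- grads[[i]]
    if (is.null(gi)) next
    bf <- tp$back[[i]]
    if (is.null(bf)) next
    pg <- bf(gi)
    ps <- tp$parents[[i]]
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      p <- ps[j]
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
  }
  grads
}

tp_leaf_grads <- function(tp, grads) {
  out <- list()
  for (nm in names(tp$leaf)) {
    g <- grads[[tp$leaf[[nm]]]]
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast per-channel broadcast over an (H, W, C) array (avoids sweep/aperm)
bcast_c <- function(v, d) rep(v, each = d[1] * d[2])

## ---- elementwise ----

ag_relu <- function(tp, x) {
  v <- tp_v(tp, x)
  tp_push(tp, cpp_relu_fw(v), x, function(g) list(cpp_relu_bw(v, g)))
}

ag_sigmoid <- function(tp, x) {
  v <- tp_v(tp, x)
  s <- 1 / (1 + exp(-v))
  if (!is.null(dim(v))) dim(s) <- dim(v)
  tp_push(tp, s, x, function(g) list(g * s * (1 - s)))
}

ag_add <- function(tp, a, b) {
  tp_push(tp, tp_v(tp, a) + tp_v(tp, b), c(a, b), function(g) list(g, g))
}

ag_sub <- function(tp, a, b) {
  tp_push(tp, tp_v(tp, a) - tp_v(tp, b), c(a, b), function(g) list(g, -g))
}

ag_mul <- function(tp, a, b) {
  va <- tp_v(tp, a); vb <- tp_v(tp, b)
  tp_push(tp, va * vb, c(a, b), function(g) list(g * vb, g * va))
}

# x + scalar constant
ag_addc <- function(tp, x, const) {
  tp_push(tp, tp_v(tp, x) + const, x, function(g) list(g))
}

# x * scalar constant
ag_smul <- function(tp, x, const) {
  tp_push(tp, tp_v(tp, x) * const, x, function(g) list(g * const))
}

# Multiply a (H,W,C) map by a trainable length-C vector, broadcast over space.
ag_mul_chan <- function(tp, x, w) {
  v <- tp_v(tp, x); wv <- tp_v(tp, w)
  d <- dim(v)
  y <- v * bcast_c(wv, d)
  dim(y) <- d
  tp_push(tp, y, c(x, w), function(g) {
    gw <- colSums(matrix(g * v, d[1] * d[2], d[3]))
    gx <- g * bcast_c(wv, d)
    dim(gx) <- d
    list(gx, gw)
  })
}

# Fixed (non-trainable) per-channel affine, used for inference-mode batch norm.
ag_scale_shift_c <- function(tp, x, scale, shift) {
  v <- tp_v(tp, x)
  d <- dim(v)
  tp_push(tp, cpp_scale_shift(v, d, scale, shift), x,
          function(g) list(cpp_scale_mul(g, d, scale)))
}

## ---- conv / pooling / sampling ----

ag_conv2d <- function(tp, x, w, b = NULL, kh, kw, stride = 1L, pad = kh %/% 2L) {
  xv <- tp_v(tp, x); wv <- tp_v(tp, w)
  bv <- if (is.null(b)) numeric(0) else tp_v(tp, b)
  y <- cpp_conv2d_fw(xv, dim(xv), wv, kh, kw, stride, pad, bv)
  parents <- c(x, w, if (!is.null(b)) b)
  tp_push(tp, y, parents, function(g) {
    r <- cpp_conv2d_bw(xv, dim(xv), wv, kh, kw, stride, pad, g, !is.null(b))
    if (is.null(b)) list(r$gx, r$gw) else list(r$gx, r$gw, r$gb)
  })
}

ag_dwconv <- function(tp, x, w, kh, kw, stride = 1L, pad = kh %/% 2L) {
  xv <- tp_v(tp, x); wv <- tp_v(tp, w)
  y <- cpp_dwconv_fw(xv, dim(xv), wv, kh, kw, stride, pad)
  tp_push(tp, y, c(x, w), function(g) {
    r <- cpp_dwconv_bw(xv, dim(xv), wv, kh, kw, stride, pad, g)
    list(r$gx, r$gw)
  })
}

ag_maxpool <- function(tp, x, k, stride = 1L, pad = k %/% 2L) {
  xv <- tp_v(tp, x)
  r <- cpp_maxpool_fw(xv, dim(xv), k, stride, pad)
  xd <- dim(xv)
  tp_push(tp, r$y, x, function(g) list(cpp_maxpool_bw(xd, r$argmax, g)))
}

# Bilinear resampling of x at coordinates (sx, sy); sx/sy are tape nodes of dim
# (Hout, Wout, G) in 0-based input pixel units, G offset groups over channels.
ag_gridsample <- function(tp, x, sx, sy) {
  xv <- tp_v(tp, x); sxv <- tp_v(tp, sx); syv <- tp_v(tp, sy)
  y <- cpp_gridsample_fw(xv, dim(xv), sxv, syv, dim(sxv))
  tp_push(tp, y, c(x, sx, sy), function(g) {
    r <- cpp_gridsample_bw(xv, dim(xv), sxv, syv, dim(sxv), g)
    list(r$gx, r$gsx, r$gsy)
  })
}

## ---- batch normalization ----

# Training-mode batch norm over the spatial extent of one map (per-channel
# statistics over H*W samples, biased variance).  Batch statistics are attached
# so the caller can maintain running averages.
ag_bn_train <- function(tp, x, gamma, beta, eps = 1e-5) {
  v <- tp_v(tp, x); gv <- tp_v(tp, gamma); bv <- tp_v(tp, beta)
  d <- dim(v)
  r <- cpp_bn_fw(v, d, gv, bv, eps)
  id <- tp_push(tp, r$y, c(x, gamma, beta), function(g) {
    b <- cpp_bn_bw(v, d, r$mean, r$inv, gv, g)
    list(b$gx, b$ggamma, b$gbeta)
  })
  attr(id, "mean") <- r$mean
  attr(id, "var") <- r$var
  id
}

## ---- shape ops ----

# Gather arbitrary positions (1-based, NA = zero fill) into a new array.
ag_gather <- function(tp, x, idx, outdim) {
  v <- tp_v(tp, x)
  idx <- as.integer(idx)
  if (anyNA(idx)) {
    y <- numeric(length(idx))
    ok <- !is.na(idx)
    y[ok] <- v[idx[ok]]
  } else {
    y <- v[idx]
  }
  dim(y) <- outdim
  xd <- dim(v) %||% length(v)
  tp_push(tp, y, x, function(g) {
    gx <- cpp_scatter_add(prod(xd), idx, as.numeric(g))
    dim(gx) <- xd
    list(gx)
  })
}

# Concatenate (H,W,Ci) maps along channels.
ag_concat_c <- function(tp, ids) {
  vals <- lapply(ids, tp_v, tp = tp)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  y <- array(0, c(d1[1], d1[2], sum(cs)))
  off <- 0
  for (v in vals) { y[, , off + seq_len(dim(v)[3])] <- v; off <- off + dim(v)[3] }
  tp_push(tp, y, unlist(ids), function(g) {
    out <- vector("list", length(ids)); off <- 0
    for (i in seq_along(ids)) {
      out[[i]] <- g[, , off + seq_len(cs[i]), drop = FALSE]
      off <- off + cs[i]
    }
    out
  })
}

ag_slice_c <- function(tp, x, channels) {
  v <- tp_v(tp, x)
  d <- dim(v)
  y <- v[, , channels, drop = FALSE]
  tp_push(tp, y, x, function(g) {
    gx <- array(0, d)
    gx[, , channels] <- g
    list(gx)
  })
}

# Concatenate the flattened values of several nodes into one vector.
ag_concat_flat <- function(tp, ids) {
  vals <- lapply(ids, tp_v, tp = tp)
  lens <- vapply(vals, length, numeric(1))
  dims <- lapply(vals, function(v) dim(v) %||% length(v))
  y <- unlist(lapply(vals, as.numeric), use.names = FALSE)
  tp_push(tp, y, unlist(ids), function(g) {
    out <- vector("list", length(ids)); off <- 0
    for (i in seq_along(ids)) {
      gi <- g[off + seq_len(lens[i])]
      dim(gi) <- dims[[i]]
      out[[i]] <- gi
      off <- off + lens[i]
    }
    out
  })
}

## ---- matrix ops (attention) ----

ag_matmul <- function(tp, a, b) {
  va <- tp_v(tp, a); vb <- tp_v(tp, b)
  tp_push(tp, va %*% vb, c(a, b), function(g) {
    list(g %*% t(vb), t(va) %*% g)
  })
}

ag_transpose <- function(tp, x) {
  tp_push(tp, t(tp_v(tp, x)), x, function(g) list(t(g)))
}

ag_softmax_rows <- function(tp, x) {
  v <- tp_v(tp, x)
  mx <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  e <- exp(v - mx)
  p <- e / rowSums(e)
  tp_push(tp, p, x, function(g) {
    s <- rowSums(g * p)
    list(p * (g - s))
  })
}

ag_cbind <- function(tp, ids) {
  vals <- lapply(ids, tp_v, tp = tp)
  cs <- vapply(vals, ncol, numeric(1))
  y <- do.call(cbind, vals)
  tp_push(tp, y, unlist(ids), function(g) {
    out <- vector("list", length(ids)); off <- 0
    for (i in seq_along(ids)) {
      out[[i]] <- g[, off + seq_len(cs[i]), drop = FALSE]
      off <- off + cs[i]
    }
    out
  })
}

## ---- reductions ----

ag_mean <- function(tp, x) {
  v <- tp_v(tp, x)
  n <- length(v)
  d <- dim(v) %||% n
  tp_push(tp, mean(v), x, function(g) {
    gx <- array(g / n, d)
    list(gx)
  })
}

ag_sum <- function(tp, x) {
  v <- tp_v(tp, x)
  d <- dim(v) %||% length(v)
  tp_push(tp, sum(v), x, function(g) list(array(g, d)))
}

# Global average pooling: (H,W,C) -> length-C vector.
ag_gap <- function(tp, x) {
  v <- tp_v(tp, x)
  d <- dim(v); n <- d[1] * d[2]
  y <- colMeans(matrix(v, n, d[3]))
  tp_push(tp, y, x, function(g) {
    gx <- array(rep(g / n, each = n), d)
    list(gx)
  })
}

# Weighted binary cross-entropy on logits: sum(w * bce) / denom, with the
# denominator defaulting to the total weight (an ordinary weighted mean).
# `target` and `weight` are plain arrays shaped like the logits.
ag_bce_logits <- function(tp, x, target, weight = NULL, denom = NULL) {
  v <- tp_v(tp, x)
  w <- if (is.null(weight)) array(1, dim(v) %||% length(v)) else weight
  denom <- if (is.null(denom)) max(sum(w), 1e-12) else denom
  p <- 1 / (1 + exp(-v))
  l <- -(target * log(pmax(p, 1e-12)) + (1 - target) * log(pmax(1 - p, 1e-12)))
  val <- sum(w * l) / denom
  tp_push(tp, val, x, function(g) list(g * w * (p - target) / denom))
}


# Expanded-window multi-head self-attention as a single tape node.  q, k, v
# are (H, W, C) projection outputs; `plan` lists, per window, the linear
# query/key positions (1-based into the H*W spatial grid).  The closure
# performs the full attention forward and its exact backward with plain
# matrix algebra, which keeps the tape small.
ag_ewmhsa <- function(tp, q, k, v, plan, heads) {
  qv <- tp_v(tp, q); kv <- tp_v(tp, k); vv <- tp_v(tp, v)
  d <- dim(qv)
  planq <- lapply(plan, function(p) p$q)
  plank <- lapply(plan, function(p) p$k)
  r <- cpp_ewmhsa_fw(qv, kv, vv, d, planq, plank, heads)
  tp_push(tp, r$y, c(q, k, v), function(g) {
    b <- cpp_ewmhsa_bw(qv, kv, vv, d, planq, plank, heads, r$P, g)
    list(b$gq, b$gk, b$gv)
  })
}
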