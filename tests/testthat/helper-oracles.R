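# Independent brute-force oracles used to verify the fast implementations.
# These are deliberately naive (nested loops, rasterization, exhaustive
# enumeration) and share no code with the package internals they check.

# Direct evaluation of the convolution sum, generalized across channels:
# y(i,j,o) = sum_{m,n,c} x(i*s+m-p, j*s+n-p, c) * w(m,n,c,o) + b(o)
oracle_conv <- function(x, kernel, bias = NULL, stride = 1) {
  kd <- dim(kernel)
  kh <- kd[1]; kw <- kd[2]; cin <- kd[3]; cout <- kd[4]
  pad <- kh %/% 2
  d <- dim(x)
  Hout <- (d[1] + 2 * pad - kh) %/% stride + 1
  Wout <- (d[2] + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Hout, Wout, cout))
  for (o in seq_len(cout)) {
    for (i in seq_len(Hout)) {
      for (j in seq_len(Wout)) {
        acc <- if (is.null(bias)) 0 else bias[o]
        for (m in seq_len(kh)) {
          for (n in seq_len(kw)) {
            hi <- (i - 1) * stride + m - pad
            wi <- (j - 1) * stride + n - pad
            if (hi < 1 || hi > d[1] || wi < 1 || wi > d[2]) next
            for (c in seq_len(cin)) {
              acc <- acc + x[hi, wi, c] * kernel[m, n, c, o]
            }
          }
        }
        y[i, j, o] <- acc
      }
    }
  }
  y
}

# Naive per-pixel bilinear x2 upsampling with half-pixel centres and border
# clamping.
oracle_bilinear_up2 <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  y <- array(0, c(2 * H, 2 * W, C))
  for (c in seq_len(C)) {
    for (i in seq_len(2 * H)) {
      for (j in seq_len(2 * W)) {
        sy <- min(max((i - 0.5) / 2 - 0.5, 0), H - 1)
        sx <- min(max((j - 0.5) / 2 - 0.5, 0), W - 1)
        y0 <- min(floor(sy), H - 2 + (H == 1)); x0 <- min(floor(sx), W - 2 + (W == 1))
        ty <- sy - y0; tx <- sx - x0
        y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
        y[i, j, c] <-
          (1 - ty) * ((1 - tx) * x[y0 + 1, x0 + 1, c] + tx * x[y0 + 1, x1 + 1, c]) +
          ty * ((1 - tx) * x[y1 + 1, x0 + 1, c] + tx * x[y1 + 1, x1 + 1, c])
      }
    }
  }
  y
}

# Rasterized-overlap IoU of two (optionally centre-rescaled) boxes: count
# subpixel samples inside each box.
oracle_raster_iou <- function(a, b, ratio = 1, res = 800) {
  shrink <- function(v) {
    cx <- (v[1] + v[3]) / 2; cy <- (v[2] + v[4]) / 2
    w <- (v[3] - v[1]) * ratio / 2; h <- (v[4] - v[2]) * ratio / 2
    c(cx - w, cy - h, cx + w, cy + h)
  }
  a <- shrink(a); b <- shrink(b)
  lo <- pmin(a[1:2], b[1:2]) - 0.01
  hi <- pmax(a[3:4], b[3:4]) + 0.01
  xs <- seq(lo[1], hi[1], length.out = res)
  ys <- seq(lo[2], hi[2], length.out = res)
  px <- (xs[2] - xs[1]) * (ys[2] - ys[1])
  X <- matrix(xs, res, res, byrow = TRUE)
  Y <- matrix(ys, res, res)
  inA <- X >= a[1] & X <= a[3] & Y >= a[2] & Y <= a[4]
  inB <- X >= b[1] & X <= b[3] & Y >= b[2] & Y <= b[4]
  inter <- sum(inA & inB) * px
  union <- sum(inA | inB) * px
  if (union == 0) 0 else inter / union
}

# Independent standard IoU (corner arithmetic written separately from the
# package's shrink-based route).
oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (un <= 0) 0 else inter / un
}

# Brute-force AP: walk every score threshold of the sorted outcome sequence
# and accumulate the area under the enveloped PR staircase rectangle by
# rectangle.
oracle_ap <- function(scores, tp, nGt) {
  if (nGt == 0 || !length(scores)) return(0)
  o <- order(-scores)
  tp <- tp[o]
  n <- length(tp)
  prec <- numeric(n); rec <- numeric(n)
  for (i in seq_len(n)) {
    prec[i] <- sum(tp[1:i]) / i
    rec[i] <- sum(tp[1:i]) / nGt
  }
  env <- numeric(n)
  for (i in seq_len(n)) env[i] <- max(prec[i:n])
  ap <- 0
  prev <- 0
  for (i in seq_len(n)) {
    ap <- ap + (rec[i] - prev) * env[i]
    prev <- rec[i]
  }
  ap
}

# O(n^2) all-pairs greedy NMS.
oracle_nms <- function(dets, iouThr) {
  dets <- dets[order(-dets$score), , drop = FALSE]
  n <- nrow(dets)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (j <= i || !keep[j] || dets$class_id[j] != dets$class_id[i]) next
      if (oracle_iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                     as.numeric(dets[j, c("x1", "y1", "x2", "y2")])) > iouThr)
        keep[j] <- FALSE
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Independent greedy matcher (score order, best unmatched same-class gt).
oracle_match <- function(dets, gts, iouThr) {
  dets <- dets[order(-dets$score), , drop = FALSE]
  used <- logical(nrow(gts))
  tp <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j] || gts$class_id[j] != dets$class_id[i]) next
      v <- oracle_iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                      as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= iouThr) { tp[i] <- TRUE; used[bj] <- TRUE }
  }
  list(tp = tp, fn = sum(!used))
}

# Central-difference numeric gradient of a scalar function of one array.
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small deterministic random boxes (absolute xyxy inside [0, s]^2).
random_boxes <- function(n, s = 100) {
  cx <- runif(n, 10, s - 10); cy <- runif(n, 10, s - 10)
  w <- runif(n, 4, 40); h <- runif(n, 4, 40)
  cbind(pmax(0, cx - w / 2), pmax(0, cy - h / 2),
        pmin(s, cx + w / 2), pmin(s, cy + h / 2))
}
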