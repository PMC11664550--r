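# Anchor-free detection head, Inner-IoU box loss, task-aligned target
# assignment, composite loss, decoding and NMS.
#
# Each pyramid level predicts, per cell: 4 discretized side distances
# (reg_max bins each, decoded as the distribution mean, in cell units), 5
# class logits and 1 objectness logit.  Boxes decode around the cell centre
# c = (j - 0.5) * stride as x1 = cx - l*s, y1 = cy - t*s, x2 = cx + r*s,
# y2 = cy + b*s.

#' Inner-IoU between two boxes
#'
#' Both boxes are rescaled about their centres by `ratio` (auxiliary "inner"
#' boxes, shrunk for ratio < 1, grown for ratio > 1) and the ordinary
#' intersection-over-union of the auxiliary boxes is returned.  `ratio = 1`
#' reduces exactly to standard IoU.  Inputs are absolute xyxy corners,
#' either length-4 vectors or n x 4 matrices (vectorized row-wise).
#'
#' @param pred,gt numeric(4) `(x1, y1, x2, y2)` or n x 4 matrices.
#' @param ratio auxiliary box scale factor in (0, 1.5].
#' @return IoU value(s) in [0, 1]; degenerate zero-area inputs give 0 with a
#'   warning.
#' @export
innerIoU <- function(pred, gt, ratio = 1) {
  stopifnot(ratio > 0)
  p <- rbind_box(pred); g <- rbind_box(gt)
  if (any(p[, 3] - p[, 1] <= 0 | p[, 4] - p[, 2] <= 0 |
          g[, 3] - g[, 1] <= 0 | g[, 4] - g[, 2] <= 0))
    warning("degenerate (zero-area) box; IoU defined as 0")
  pi <- shrink_box(p, ratio); gi <- shrink_box(g, ratio)
  ox <- pmax(0, pmin(pi[, 3], gi[, 3]) - pmax(pi[, 1], gi[, 1]))
  oy <- pmax(0, pmin(pi[, 4], gi[, 4]) - pmax(pi[, 2], gi[, 2]))
  inter <- ox * oy
  un <- pmax(0, (pi[, 3] - pi[, 1])) * pmax(0, (pi[, 4] - pi[, 2])) +
    pmax(0, (gi[, 3] - gi[, 1])) * pmax(0, (gi[, 4] - gi[, 2])) - inter
  ifelse(un > 0, inter / un, 0)
}

rbind_box <- function(b) {
  if (is.null(dim(b))) matrix(b, 1, 4) else as.matrix(b)
}

shrink_box <- function(b, ratio) {
  cx <- (b[, 1] + b[, 3]) / 2; cy <- (b[, 2] + b[, 4]) / 2
  w <- (b[, 3] - b[, 1]) * ratio / 2; h <- (b[, 4] - b[, 2]) * ratio / 2
  cbind(cx - w, cy - h, cx + w, cy + h)
}

#' Inner-IoU regression loss
#'
#' `1 - innerIoU(pred, gt, ratio)`; differentiable almost everywhere in the
#' predicted corners.
#'
#' @inheritParams innerIoU
#' @return loss value(s) in [0, 1].
#' @export
innerIoULoss <- function(pred, gt, ratio = 0.75) {
  1 - innerIoU(pred, gt, ratio)
}

# Analytic gradient of innerIoULoss w.r.t. the predicted corners (n x 4).
inner_iou_loss_grad <- function(p, g, ratio) {
  pi <- shrink_box(p, ratio); gi <- shrink_box(g, ratio)
  ox <- pmin(pi[, 3], gi[, 3]) - pmax(pi[, 1], gi[, 1])
  oy <- pmin(pi[, 4], gi[, 4]) - pmax(pi[, 2], gi[, 2])
  pos <- ox > 0 & oy > 0
  inter <- ifelse(pos, ox * oy, 0)
  Ap <- (pi[, 3] - pi[, 1]) * (pi[, 4] - pi[, 2])
  Ag <- (gi[, 3] - gi[, 1]) * (gi[, 4] - gi[, 2])
  un <- Ap + Ag - inter
  # partials of inter and Ap w.r.t. inner corners
  dI <- cbind(ifelse(pos & pi[, 1] > gi[, 1], -oy, 0),
              ifelse(pos & pi[, 2] > gi[, 2], -ox, 0),
              ifelse(pos & pi[, 3] < gi[, 3], oy, 0),
              ifelse(pos & pi[, 4] < gi[, 4], ox, 0))
  dA <- cbind(-(pi[, 4] - pi[, 2]), -(pi[, 3] - pi[, 1]),
              (pi[, 4] - pi[, 2]), (pi[, 3] - pi[, 1]))
  ok <- un > 0
  # d(IoU)/d inner = (dI*U - I*(dA - dI)) / U^2 ; dLoss = -dIoU
  dInner <- matrix(0, nrow(p), 4)
  dInner[ok, ] <- -(dI[ok, , drop = FALSE] * un[ok] -
                      inter[ok] * (dA[ok, , drop = FALSE] - dI[ok, , drop = FALSE])) /
    un[ok]^2
  # chain inner corners -> outer corners
  a <- 0.5 + ratio / 2; b <- 0.5 - ratio / 2
  cbind(dInner[, 1] * a + dInner[, 3] * b,
        dInner[, 2] * a + dInner[, 4] * b,
        dInner[, 1] * b + dInner[, 3] * a,
        dInner[, 2] * b + dInner[, 4] * a)
}

## ---- distribution (DFL) decode ----

# Softmax over reg_max bins and distribution mean, row-wise.
# x: (n, 4*nb) matrix -> list(dist (n,4), prob (n,4,nb))
dfl_decode <- function(x, nb) {
  n <- nrow(x)
  pr <- array(0, c(n, 4, nb))
  dist <- matrix(0, n, 4)
  for (s in 1:4) {
    z <- x[, (s - 1) * nb + seq_len(nb), drop = FALSE]
    z <- exp(z - z[cbind(seq_len(n), max.col(z, ties.method = "first"))])
    p <- z / rowSums(z)
    pr[, s, ] <- p
    dist[, s] <- p %*% (seq_len(nb) - 1)
  }
  list(dist = dist, prob = pr)
}

# Tape node: mean Inner-IoU loss over positives, from gathered reg logits.
# centers: (n,2) cell centres (px); gt: (n,4) matched boxes (px); stride: n.
ag_inner_box_loss <- function(tp, x, centers, gtb, stride, ratio, nb) {
  xv <- tp_v(tp, x)
  n <- nrow(xv)
  dec <- dfl_decode(xv, nb)
  pb <- cbind(centers[, 1] - dec$dist[, 1] * stride,
              centers[, 2] - dec$dist[, 2] * stride,
              centers[, 1] + dec$dist[, 3] * stride,
              centers[, 2] + dec$dist[, 4] * stride)
  val <- mean(innerIoULoss(pb, gtb, ratio))
  tp_push(tp, val, x, function(g) {
    gc <- inner_iou_loss_grad(pb, gtb, ratio) / n  # d mean loss / d corners
    # corners -> distances (sign and stride), distances -> logits via softmax
    gd <- cbind(-gc[, 1], -gc[, 2], gc[, 3], gc[, 4]) * stride
    gx <- matrix(0, n, 4 * nb)
    bins <- seq_len(nb) - 1
    for (s in 1:4) {
      p <- matrix(dec$prob[, s, ], n, nb)
      # d dist/d logit_j = p_j * (j - dist)
      gx[, (s - 1) * nb + seq_len(nb)] <-
        (g * gd[, s]) * p * (matrix(bins, n, nb, byrow = TRUE) - dec$dist[, s])
    }
    list(gx)
  })
}

# Tape node: distribution focal loss (soft cross-entropy against the two bins
# adjacent to the target distance), mean over positives and sides.
ag_dfl_loss <- function(tp, x, target, nb) {
  xv <- tp_v(tp, x)
  n <- nrow(xv)
  t <- pmin(pmax(target, 0), nb - 1 - 1e-3)
  lo <- floor(t); hi <- lo + 1; wl <- hi - t; wh <- t - lo
  dec <- dfl_decode(xv, nb)
  val <- 0
  soft <- array(0, c(n, 4, nb))
  for (s in 1:4) {
    p <- matrix(dec$prob[, s, ], n, nb)
    il <- cbind(seq_len(n), lo[, s] + 1); ih <- cbind(seq_len(n), hi[, s] + 1)
    val <- val - sum(wl[, s] * log(pmax(p[il], 1e-12)) +
                       wh[, s] * log(pmax(p[ih], 1e-12)))
    sf <- matrix(0, n, nb)
    sf[il] <- wl[, s]; sf[ih] <- sf[ih] + wh[, s]
    soft[, s, ] <- sf
  }
  val <- val / (4 * n)
  tp_push(tp, val, x, function(g) {
    gx <- matrix(0, n, 4 * nb)
    for (s in 1:4) {
      gx[, (s - 1) * nb + seq_len(nb)] <-
        g * (matrix(dec$prob[, s, ], n, nb) - matrix(soft[, s, ], n, nb)) / (4 * n)
    }
    list(gx)
  })
}

## ---- target assignment ----

#' Task-aligned target assignment
#'
#' Candidate cells for a ground-truth box are those (on any level) whose
#' centre lies inside the box and within the anchor matching radius (5
#' cells) of its centre.  Candidates are scored by the alignment
#' `cls_prob^0.5 * IoU^6` between the cell's current prediction and the box;
#' candidates below the minimum-IoU floor (0.2) are dropped unless a box
#' would otherwise be unmatched, in which case its single best candidate is
#' kept.  The top 10 candidates per box become positives and every cell
#' serves at most one box (highest alignment wins, ties to the lower box
#' index).
#'
#' @param preds per-level raw predictions: list with elements `reg`
#'   (H, W, 4*regMax), `cls` (H, W, nc), `obj` (H, W, 1), `stride`.
#' @param gts data.frame of normalized boxes (class_id, cx, cy, w, h).
#' @param imgSize input image side in pixels.
#' @param topk positives kept per ground-truth box.
#' @param radius anchor matching radius in cells.
#' @param iouFloor minimum prediction/box IoU for a regular positive.
#' @param regMax number of distance bins per side.
#' @return list with one element per level: `pos` (linear cell index),
#'   `gt` (matched box row), `cls` (class id), `dist` (n x 4 target
#'   distances, cell units), `gtbox` (n x 4 absolute corners), `centers`.
#' @export
assignTargets <- function(preds, gts, imgSize, topk = 10, radius = 5,
                          iouFloor = 0.2, regMax = 16) {
  if (!length(preds)) stop("at least one prediction level is required")
  ng <- nrow(gts)
  empty <- lapply(preds, function(p) {
    list(pos = integer(0), gt = integer(0), cls = integer(0),
         dist = matrix(0, 0, 4), gtbox = matrix(0, 0, 4),
         centers = matrix(0, 0, 2))
  })
  if (ng == 0) return(empty)
  gb <- cbind((gts$cx - gts$w / 2), (gts$cy - gts$h / 2),
              (gts$cx + gts$w / 2), (gts$cy + gts$h / 2)) * imgSize
  cand <- list()
  for (li in seq_along(preds)) {
    p <- preds[[li]]
    s <- p$stride
    d <- dim(p$reg)
    H <- d[1]; W <- d[2]
    xc <- rep((seq_len(W) - 0.5) * s, each = H)
    yc <- rep((seq_len(H) - 0.5) * s, times = W)
    dec <- dfl_decode(matrix(p$reg, H * W, 4 * regMax), regMax)
    pb <- cbind(xc - dec$dist[, 1] * s, yc - dec$dist[, 2] * s,
                xc + dec$dist[, 3] * s, yc + dec$dist[, 4] * s)
    clsp <- 1 / (1 + exp(-matrix(p$cls, H * W, dim(p$cls)[3])))
    for (g in seq_len(ng)) {
      inside <- xc > gb[g, 1] & xc < gb[g, 3] & yc > gb[g, 2] & yc < gb[g, 4]
      near <- abs(xc - (gb[g, 1] + gb[g, 3]) / 2) <= radius * s &
        abs(yc - (gb[g, 2] + gb[g, 4]) / 2) <= radius * s
      idx <- which(inside & near)
      if (!length(idx)) next
      iou <- innerIoU(pb[idx, , drop = FALSE],
                      matrix(gb[g, ], length(idx), 4, byrow = TRUE), 1)
      score <- sqrt(clsp[idx, gts$class_id[g] + 1]) * iou^6
      cand[[length(cand) + 1]] <- data.frame(
        level = li, cell = idx, gt = g, iou = iou, score = score)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  keep <- list()
  for (g in seq_len(ng)) {
    cg <- cand[cand$gt == g, , drop = FALSE]
    if (!nrow(cg)) next
    ok <- cg[cg$iou >= iouFloor, , drop = FALSE]
    if (!nrow(ok)) ok <- cg[which.max(cg$score), , drop = FALSE]
    ok <- ok[order(-ok$score), , drop = FALSE]
    keep[[g]] <- head(ok, topk)
  }
  keep <- do.call(rbind, keep)
  # one gt per cell: highest score wins, ties to the lower gt index
  keep <- keep[order(keep$level, keep$cell, -keep$score, keep$gt), , drop = FALSE]
  keep <- keep[!duplicated(keep[, c("level", "cell")]), , drop = FALSE]
  out <- empty
  for (li in seq_along(preds)) {
    k <- keep[keep$level == li, , drop = FALSE]
    if (!nrow(k)) next
    p <- preds[[li]]
    s <- p$stride
    H <- dim(p$reg)[1]
    xc <- ((k$cell - 1) %/% H + 0.5) * s
    yc <- ((k$cell - 1) %% H + 0.5) * s
    gbx <- gb[k$gt, , drop = FALSE]
    out[[li]] <- list(
      pos = k$cell, gt = k$gt, cls = gts$class_id[k$gt],
      dist = cbind(xc - gbx[, 1], yc - gbx[, 2], gbx[, 3] - xc, gbx[, 4] - yc) / s,
      gtbox = gbx, centers = cbind(xc, yc))
  }
  out
}

## ---- composite loss ----

# Tape version used by both the trainer and the public wrapper.
# heads: per level list(reg=, cls=, obj= node ids, stride); assignment from
# assignTargets computed on the detached values.
loss_on_tape <- function(tp, heads, assignment, nc, regMax, ratio,
                         weights = c(7.5, 0.5, 0.7, 1.5)) {
  box_nodes <- list(); dfl_nodes <- list(); cls_nodes <- list()
  obj_sums <- list()
  npos_tot <- sum(vapply(assignment, function(a) length(a$pos), numeric(1)))
  for (li in seq_along(heads)) {
    h <- heads[[li]]
    a <- assignment[[li]]
    d <- dim(tp_v(tp, h$reg))
    H <- d[1]; W <- d[2]
    objt <- array(0, c(H, W, 1))
    if (length(a$pos)) {
      npos <- length(a$pos)
      # quality-aware objectness target: IoU of the currently decoded box
      # with the assigned ground truth (detached), so the score ranks cells
      # by localization quality
      regv <- matrix(tp_v(tp, h$reg), H * W, 4 * regMax)[a$pos, , drop = FALSE]
      decq <- dfl_decode(regv, regMax)
      pbq <- cbind(a$centers[, 1] - decq$dist[, 1] * h$stride,
                   a$centers[, 2] - decq$dist[, 2] * h$stride,
                   a$centers[, 1] + decq$dist[, 3] * h$stride,
                   a$centers[, 2] + decq$dist[, 4] * h$stride)
      qual <- pmin(1, pmax(0.05, innerIoU(pbq, a$gtbox, 1)))
      objt[a$pos] <- qual
      idx <- outer(a$pos, (seq_len(4 * regMax) - 1) * H * W, `+`)
      regp <- ag_gather(tp, h$reg, idx, c(npos, 4 * regMax))
      box_nodes[[length(box_nodes) + 1]] <-
        list(node = ag_inner_box_loss(tp, regp, a$centers, a$gtbox, h$stride,
                                      ratio, regMax), n = npos)
      dfl_nodes[[length(dfl_nodes) + 1]] <-
        list(node = ag_dfl_loss(tp, regp, a$dist, regMax), n = npos)
      idxc <- outer(a$pos, (seq_len(nc) - 1) * H * W, `+`)
      clsp <- ag_gather(tp, h$cls, idxc, c(npos, nc))
      # task-aligned soft targets: the assigned class is supervised towards
      # the localization quality, so the decoded score concentrates on the
      # best-localized cell of each object
      tgt <- matrix(0, npos, nc)
      tgt[cbind(seq_len(npos), a$cls + 1)] <- qual
      cls_nodes[[length(cls_nodes) + 1]] <-
        list(node = ag_bce_logits(tp, clsp, tgt), n = npos)
    }
    # objectness: focal-weighted BCE summed over every cell and normalized
    # by the positive count (dense-detector convention).  The focal factor
    # alpha_t * (1 - p_t)^2 (alpha = 0.25) is computed from the current
    # probabilities and treated as a constant weight, which keeps easy
    # background cells from drowning the handful of positives.
    pobj <- 1 / (1 + exp(-tp_v(tp, h$obj)))
    pt <- ifelse(objt > 0.5, pobj, 1 - pobj)
    alpha <- ifelse(objt > 0.5, 0.25, 0.75)
    fw <- alpha * (1 - pt)^2
    obj_sums[[length(obj_sums) + 1]] <-
      ag_bce_logits(tp, h$obj, objt, weight = fw, denom = max(1, npos_tot))
  }
  wmean <- function(nodes) {
    if (!length(nodes)) return(tp_push(tp, 0))
    tot <- sum(vapply(nodes, function(x) x$n, numeric(1)))
    acc <- NULL
    for (x in nodes) {
      term <- ag_smul(tp, x$node, x$n / tot)
      acc <- if (is.null(acc)) term else ag_add(tp, acc, term)
    }
    acc
  }
  box <- wmean(box_nodes)
  dfl <- wmean(dfl_nodes)
  cls <- wmean(cls_nodes)
  obj <- NULL
  for (o in obj_sums) obj <- if (is.null(obj)) o else ag_add(tp, obj, o)
  total <- ag_add(tp, ag_add(tp, ag_smul(tp, box, weights[1]),
                             ag_smul(tp, cls, weights[2])),
                  ag_add(tp, ag_smul(tp, obj, weights[3]),
                         ag_smul(tp, dfl, weights[4])))
  list(box = box, cls = cls, obj = obj, dfl = dfl, total = total,
       npos = npos_tot)
}

#' Composite detection loss
#'
#' The classification term is the mean binary cross-entropy over the
#' assigned (positive) cells' class targets; the objectness term is the
#' binary cross-entropy summed over every cell with quality-aware targets
#' and normalized by the number of positives (dense-detector convention);
#' the box term is the mean Inner-IoU loss over positives; the distribution
#' term is the soft cross-entropy of the discretized side distances.  The
#' total is the weighted sum with weights
#' `(box, cls, obj, dfl) = (7.5, 0.5, 0.7, 1.5)`.
#'
#' @param preds per-level raw predictions (`reg`, `cls`, `obj`, `stride`).
#' @param assignment output of [assignTargets()] for the same predictions.
#' @param weights the four loss weights.
#' @param ratio Inner-IoU auxiliary box scale.
#' @param regMax distance bins per side.
#' @return A [LossBreakdown-class].
#' @export
compositeLoss <- function(preds, assignment, weights = c(7.5, 0.5, 0.7, 1.5),
                          ratio = 0.75, regMax = 16) {
  nc <- dim(preds[[1]]$cls)[3]
  tp <- tp_new()
  heads <- lapply(preds, function(p) {
    list(reg = tp_leaf(tp, p$reg), cls = tp_leaf(tp, p$cls),
         obj = tp_leaf(tp, p$obj), stride = p$stride)
  })
  l <- loss_on_tape(tp, heads, assignment, nc, regMax, ratio, weights)
  LossBreakdown(tp_v(tp, l$box), tp_v(tp, l$cls), tp_v(tp, l$obj),
                tp_v(tp, l$dfl), weights)
}

## ---- decode and NMS ----

#' Decode raw predictions into scored detections
#'
#' Every (cell, class) pair whose score (`sigmoid(cls) * sigmoid(obj)`)
#' exceeds `confThr` is decoded to an absolute xyxy box through the stride
#' arithmetic and the distribution mean (multi-label emission, so a
#' second-ranked class can still be detected), then filtered by greedy
#' per-class NMS and returned sorted by descending score.  At most
#' `maxDets` candidates per level (by score) enter the suppression.
#'
#' @param preds per-level raw predictions (`reg`, `cls`, `obj`, `stride`).
#' @param confThr score threshold (0.001 for evaluation, 0.25 for demos).
#' @param nmsIoU IoU threshold of the greedy suppression.
#' @param imgSize image side in pixels, for clipping.
#' @param regMax distance bins per side.
#' @param maxDets per-class, per-level cap on candidates entering NMS.
#' @return data.frame: x1, y1, x2, y2, score, class_id.
#' @export
decodeDetections <- function(preds, confThr = 0.001, nmsIoU = 0.7,
                             imgSize = 640, regMax = 16, maxDets = 300) {
  rows <- list()
  for (p in preds) {
    d <- dim(p$reg)
    H <- d[1]; W <- d[2]; s <- p$stride
    nc <- dim(p$cls)[3]
    clsp <- 1 / (1 + exp(-matrix(p$cls, H * W, nc)))
    objp <- 1 / (1 + exp(-as.numeric(p$obj)))
    sc <- clsp * objp
    hits <- which(sc >= confThr, arr.ind = TRUE)
    if (!nrow(hits)) next
    scores <- sc[hits]
    keep <- unlist(lapply(split(seq_len(nrow(hits)), hits[, 2]), function(ix) {
      ix[order(-scores[ix])[seq_len(min(length(ix), maxDets))]]
    }), use.names = FALSE)
    hits <- hits[keep, , drop = FALSE]
    scores <- scores[keep]
    cells <- unique(hits[, 1])
    dec <- dfl_decode(matrix(p$reg, H * W, 4 * regMax)[cells, , drop = FALSE], regMax)
    row_of <- match(hits[, 1], cells)
    xc <- ((cells - 1) %/% H + 0.5) * s
    yc <- ((cells - 1) %% H + 0.5) * s
    rows[[length(rows) + 1]] <- data.frame(
      x1 = pmax(0, xc[row_of] - dec$dist[row_of, 1] * s),
      y1 = pmax(0, yc[row_of] - dec$dist[row_of, 2] * s),
      x2 = pmin(imgSize, xc[row_of] + dec$dist[row_of, 3] * s),
      y2 = pmin(imgSize, yc[row_of] + dec$dist[row_of, 4] * s),
      score = scores, class_id = as.integer(hits[, 2] - 1L))
  }
  if (!length(rows))
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), score = numeric(0), class_id = integer(0)))
  dets <- do.call(rbind, rows)
  nonMaxSuppression(dets, nmsIoU)
}

#' Greedy per-class non-maximum suppression
#'
#' @param dets data.frame with x1, y1, x2, y2, score, class_id.
#' @param iouThr suppression IoU threshold.
#' @return the surviving detections, sorted by descending score.
#' @export
nonMaxSuppression <- function(dets, iouThr = 0.7) {
  dets <- dets[order(-dets$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(dets))
  b <- as.matrix(dets[, c("x1", "y1", "x2", "y2")])
  for (i in seq_len(nrow(dets))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(dets)) > i & dets$class_id == dets$class_id[i])
    if (!length(j)) next
    iou <- innerIoU(matrix(b[i, ], length(j), 4, byrow = TRUE),
                    b[j, , drop = FALSE], 1)
    keep[j[iou > iouThr]] <- FALSE
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
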