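# Detection metrics: greedy matching at an IoU threshold, precision /
# recall / F1, average precision by all-point (precision envelope)
# integration of the PR curve, and mAP@0.5 over classes.

#' Match detections to ground truth
#'
#' Greedy matching in score order: each detection matches the highest-IoU
#' unmatched ground-truth box of its own class with IoU >= `iouThr` (a true
#' positive), otherwise it is a false positive; unmatched ground-truth boxes
#' are false negatives.
#'
#' @param dets data.frame (x1, y1, x2, y2, score, class_id), any order.
#' @param gts data.frame of ground-truth boxes (x1, y1, x2, y2, class_id).
#' @param iouThr match threshold (0.5 for mAP@0.5).
#' @return list: `det` data.frame with a logical `tp` column (score-sorted),
#'   `fn` count of unmatched ground truth.
#' @export
matchDetections <- function(dets, gts, iouThr = 0.5) {
  dets <- dets[order(-dets$score), , drop = FALSE]
  nd <- nrow(dets)
  tp <- logical(nd)
  used <- logical(nrow(gts))
  for (i in seq_len(nd)) {
    j <- which(!used & gts$class_id == dets$class_id[i])
    if (!length(j)) next
    iou <- innerIoU(matrix(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                           length(j), 4, byrow = TRUE),
                    as.matrix(gts[j, c("x1", "y1", "x2", "y2")]), 1)
    best <- which.max(iou)
    if (iou[best] >= iouThr) {
      tp[i] <- TRUE
      used[j[best]] <- TRUE
    }
  }
  dets$tp <- tp
  list(det = dets, fn = sum(!used))
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; 0/0 is defined
#' as 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return named numeric vector (precision, recall, f1).
#' @export
precisionRecallF1 <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Average precision of a scored outcome sequence
#'
#' Sorts outcomes by descending score, accumulates the PR staircase and
#' integrates with all-point interpolation (the precision envelope), i.e.
#' the exact area under the interpolated P(R) curve.
#'
#' @param scores detection scores.
#' @param tp logical TP/FP outcome per detection.
#' @param nGt number of ground-truth instances (recall denominator).
#' @return AP in [0, 1]; `nGt = 0` returns 0 with attribute
#'   `"undefined" = TRUE` when there are also no detections to score.
#' @export
averagePrecision <- function(scores, tp, nGt) {
  if (nGt == 0) {
    out <- 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (!length(scores)) return(0)
  o <- order(-scores)
  tp <- tp[o]
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(tp)
  rec <- ctp / nGt
  # precision envelope: running maximum from the right
  env <- rev(cummax(rev(prec)))
  r0 <- c(0, rec)
  sum((rec - head(r0, -1)) * env)
}

#' Dataset-level detection evaluation (mAP@0.5)
#'
#' Pools detections over the dataset per class, computes per-class AP at a
#' 0.5 IoU match threshold plus precision/recall/F1 of the thresholded
#' detections, and averages over the classes that have at least one
#' ground-truth instance.
#'
#' @param detsByImage list of detection data.frames (one per image).
#' @param gtsByImage list of ground-truth data.frames (x1..y2, class_id).
#' @param classes class id universe (default 0:4).
#' @param iouThr match threshold.
#' @return A [MetricReport-class].
#' @export
evaluateDetections <- function(detsByImage, gtsByImage, classes = 0:4,
                               iouThr = 0.5) {
  stopifnot(length(detsByImage) == length(gtsByImage))
  rows <- list()
  for (cl in classes) {
    scores <- numeric(0); tp <- logical(0)
    ngt <- 0; fn <- 0
    for (i in seq_along(detsByImage)) {
      d <- detsByImage[[i]]
      d <- d[d$class_id == cl, , drop = FALSE]
      g <- gtsByImage[[i]]
      g <- g[g$class_id == cl, , drop = FALSE]
      ngt <- ngt + nrow(g)
      m <- matchDetections(d, g, iouThr)
      scores <- c(scores, m$det$score)
      tp <- c(tp, m$det$tp)
      fn <- fn + m$fn
    }
    ap <- averagePrecision(scores, tp, ngt)
    prf <- precisionRecallF1(sum(tp), sum(!tp), fn)
    rows[[length(rows) + 1]] <- data.frame(
      class = stageNames()[cl + 1], class_id = cl, n_gt = ngt,
      tp = sum(tp), fp = sum(!tp), fn = fn,
      precision = prf["precision"], recall = prf["recall"], f1 = prf["f1"],
      ap = as.numeric(ap))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  present <- tab$n_gt > 0
  macro <- function(v) if (any(present)) mean(v[present]) else 0
  new("MetricReport", perClass = tab, map50 = macro(tab$ap),
      precision = macro(tab$precision), recall = macro(tab$recall),
      f1 = macro(tab$f1))
}

#' Write a metric report as per-class CSV (+ optional JSON summary)
#'
#' @param report a [MetricReport-class].
#' @param csvPath per-class CSV path.
#' @param jsonPath summary JSON path (NULL to skip).
#' @return `csvPath`, invisibly.
#' @export
writeMetricReport <- function(report, csvPath, jsonPath = NULL) {
  write.csv(perClassMetrics(report), csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(map50 = report@map50, precision = report@precision,
           recall = report@recall, f1 = report@f1),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(csvPath)
}

# Normalized boxes -> absolute corner data.frame at a given image size.
boxes_to_xyxy <- function(b, imgSize) {
  data.frame(x1 = (b$cx - b$w / 2) * imgSize, y1 = (b$cy - b$h / 2) * imgSize,
             x2 = (b$cx + b$w / 2) * imgSize, y2 = (b$cy + b$h / 2) * imgSize,
             class_id = b$class_id)
}
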