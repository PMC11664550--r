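test_that("Inner-IoU reproduces worked geometry and the rasterized oracle", {
  expect_equal(innerIoU(c(0, 0, 2, 2), c(0, 0, 2, 2), 1), 1)
  expect_equal(innerIoU(c(0, 0, 2, 2), c(0, 0, 2, 2), 0.5), 1)
  # overlapping unit-offset squares: inter 1, union 7
  expect_equal(innerIoU(c(0, 0, 2, 2), c(1, 1, 3, 3), 1), 1 / 7)
  expect_equal(oracle_raster_iou(c(0, 0, 2, 2), c(1, 1, 3, 3), 1), 1 / 7,
               tolerance = 5e-3)
  # ratio 0.5 shrinks them to [0.5,1.5]^2 and [1.5,2.5]^2: point contact
  expect_equal(innerIoU(c(0, 0, 2, 2), c(1, 1, 3, 3), 0.5), 0)
  expect_equal(oracle_raster_iou(c(0, 0, 2, 2), c(1, 1, 3, 3), 0.5), 0,
               tolerance = 5e-3)
  # growing the auxiliary boxes (ratio > 1) raises the overlap
  expect_gt(innerIoU(c(0, 0, 2, 2), c(1, 1, 3, 3), 1.25), 1 / 7)
  expect_warning(innerIoU(c(0, 0, 0, 2), c(1, 1, 3, 3), 1), "degenerate")
  expect_equal(suppressWarnings(innerIoU(c(0, 0, 0, 2), c(1, 1, 3, 3), 1)), 0)
})

test_that("Inner-IoU is symmetric, bounded and monotone under separation", {
  set.seed(11)
  for (ratio in c(0.5, 0.75, 1, 1.25)) {
    a <- random_boxes(200); b <- random_boxes(200)
    v <- innerIoU(a, b, ratio)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(v, innerIoU(b, a, ratio))
  }
  # translating one box away along x never increases the value
  gt <- c(10, 10, 30, 30)
  shifts <- seq(0, 40, by = 2)
  vals <- vapply(shifts, function(s)
    innerIoU(c(10 + s, 10, 30 + s, 30), gt, 0.75), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("Inner-IoU loss complements the IoU and its gradient is exact", {
  expect_equal(innerIoULoss(c(0, 0, 2, 2), c(0, 0, 2, 2), 0.75), 0)
  expect_equal(innerIoULoss(c(0, 0, 1, 1), c(5, 5, 6, 6), 0.75), 1)
  set.seed(12)
  p <- random_boxes(40); g <- random_boxes(40)
  an <- stagenet:::inner_iou_loss_grad(p, g, 0.75)
  for (i in c(1, 7, 19)) {
    fd <- num_grad(function(v) innerIoULoss(v, g[i, ], 0.75), p[i, ], eps = 1e-6)
    expect_equal(as.numeric(an[i, ]), as.numeric(fd), tolerance = 1e-4)
  }
})

toy_preds <- function(H, W, stride, regMax = 16, nc = 5, dist = NULL) {
  reg <- array(0, c(H, W, 4 * regMax))
  if (!is.null(dist)) {
    # concentrate every side's distribution near `dist` (cell units)
    lo <- floor(dist); fr <- dist - lo
    for (s in 1:4) {
      reg[, , (s - 1) * regMax + lo + 1] <- 20 * (1 - fr)
      reg[, , (s - 1) * regMax + lo + 2] <- 20 * fr
    }
  }
  list(reg = reg, cls = array(0, c(H, W, nc)), obj = array(0, c(H, W, 1)),
       stride = stride)
}

test_that("target assignment places a cell-sized box on its own level", {
  # 64 px image; P5 grid is 2x2.  The gt covers exactly P5 cell (row 1, col 1)
  # and the P5 prediction decodes to that very box, while coarse default
  # predictions elsewhere stay under the IoU floor.
  gt <- data.frame(class_id = 2L, cx = 16 / 64, cy = 16 / 64, w = 0.5, h = 0.5)
  preds <- list(toy_preds(8, 8, 8), toy_preds(4, 4, 16), toy_preds(2, 2, 32, dist = 0.5))
  asg <- assignTargets(preds, gt, 64)
  expect_equal(asg[[3]]$pos, 1)            # linear index of cell (1, 1)
  expect_equal(asg[[3]]$cls, 2)
  expect_equal(as.numeric(asg[[3]]$dist), rep(0.5, 4))
  expect_equal(length(asg[[1]]$pos) + length(asg[[2]]$pos), 0)
  # no ground truth: all-negative assignment is valid
  asg0 <- assignTargets(preds, emptyBoxes(), 64)
  expect_true(all(vapply(asg0, function(a) length(a$pos), numeric(1)) == 0))
})

test_that("duplicate ground truths share cells one-to-one with index ties", {
  # two identical boxes on a 4x4 single-level toy grid
  gts <- data.frame(class_id = c(1L, 1L), cx = 0.5, cy = 0.5, w = 0.6, h = 0.6)
  preds <- list(toy_preds(4, 4, 16, dist = 2))
  asg <- assignTargets(preds, gts, 64)
  expect_equal(anyDuplicated(asg[[1]]$pos), 0)
  # identical boxes produce identical scores everywhere, so every contested
  # cell goes to the lower box index
  expect_true(all(asg[[1]]$gt == 1))
  expect_gt(length(asg[[1]]$pos), 0)
})

test_that("composite loss matches hand-computed values and scales linearly", {
  # one positive cell on a 4x4 stride-16 grid: the box (8,8,40,40) px sits
  # exactly one cell from the centre of cell (2,2), so the distance targets
  # are integral and the decoded box is exact
  gt <- data.frame(class_id = 2L, cx = 24 / 64, cy = 24 / 64, w = 0.5, h = 0.5)
  preds <- list(toy_preds(4, 4, 16, dist = 1))
  asg <- assignTargets(preds, gt, 64)
  expect_equal(asg[[1]]$pos, 6)  # linear index of cell (2,2)
  lb <- compositeLoss(preds, asg)
  comp <- lossComponents(lb)
  # maximally uncertain classifier logits: BCE = ln 2 per element
  expect_equal(as.numeric(comp["cls"]), log(2), tolerance = 1e-9)
  # objectness: focal-weighted sum over the 16 cells (each ln 2 at logit 0,
  # weight alpha_t * (1 - 0.5)^2) normalized by the single positive
  expect_equal(as.numeric(comp["obj"]),
               (15 * 0.75 + 1 * 0.25) * 0.25 * log(2), tolerance = 1e-9)
  expect_lt(comp[["box"]], 1e-6)   # decoded box equals the gt
  expect_equal(totalLoss(lb), sum(comp * c(7.5, 0.5, 0.7, 1.5)))
  # doubling the box weight doubles the box contribution exactly
  lb2 <- compositeLoss(preds, asg, weights = c(15, 0.5, 0.7, 1.5))
  expect_equal(totalLoss(lb2) - totalLoss(lb), 7.5 * comp[["box"]])
  # near-perfect predictions drive the total towards zero
  pr <- preds
  pr[[1]]$cls[] <- -40; pr[[1]]$cls[2, 2, 3] <- 40
  pr[[1]]$obj[] <- -40; pr[[1]]$obj[2, 2, 1] <- 40
  pr[[1]]$reg <- pr[[1]]$reg * 2  # sharper distance bins
  asgp <- assignTargets(pr, gt, 64)
  lp <- compositeLoss(pr, asgp)
  expect_lt(totalLoss(lp), 0.02)
  expect_true(validObject(lp))
})

test_that("decoding and NMS keep the right survivors", {
  d <- data.frame(x1 = c(10, 10, 60), y1 = c(10, 10, 60),
                  x2 = c(30, 30, 80), y2 = c(30, 30, 80),
                  score = c(0.9, 0.8, 0.7), class_id = c(1L, 1L, 1L))
  out <- nonMaxSuppression(d, 0.5)
  expect_equal(nrow(out), 2)
  expect_equal(out$score, c(0.9, 0.7))
  # disjoint boxes both survive; different classes are never suppressed
  d2 <- d; d2$class_id <- c(1L, 2L, 1L)
  expect_equal(nrow(nonMaxSuppression(d2, 0.5)), 3)
  # 50 random boxes vs the O(n^2) oracle
  set.seed(13)
  rb <- random_boxes(50)
  dets <- data.frame(x1 = rb[, 1], y1 = rb[, 2], x2 = rb[, 3], y2 = rb[, 4],
                     score = runif(50), class_id = sample(0:2, 50, TRUE))
  a <- nonMaxSuppression(dets, 0.45)
  b <- oracle_nms(dets, 0.45)
  expect_equal(a, b)
})

test_that("decoded detections recover a planted box", {
  gt <- data.frame(class_id = 3L, cx = 0.25, cy = 0.25, w = 0.5, h = 0.5)
  preds <- list(toy_preds(2, 2, 32, dist = 0.5))
  preds[[1]]$cls[] <- -8
  preds[[1]]$cls[1, 1, 4] <- 8
  preds[[1]]$obj[] <- -8
  preds[[1]]$obj[1, 1, 1] <- 8
  dets <- decodeDetections(preds, confThr = 0.25, imgSize = 64)
  expect_equal(nrow(dets), 1)
  expect_equal(dets$class_id, 3L)
  # the distribution tail contributes a sub-decipixel bias at finite logits
  expect_equal(as.numeric(dets[1, 1:4]), c(0, 0, 32, 32), tolerance = 0.005)
})
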