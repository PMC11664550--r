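test_that("detection matching is greedy, class-aware and one-to-one", {
  gt1 <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10, class_id = 0L)
  d1 <- data.frame(x1 = 2, y1 = 0, x2 = 12, y2 = 10, score = 0.8, class_id = 0L)
  m <- matchDetections(d1, gt1, 0.5)   # IoU = 8/12 = 0.667
  expect_equal(sum(m$det$tp), 1)
  expect_equal(m$fn, 0)
  # two detections on one gt: exactly one TP
  d2 <- rbind(d1, transform(d1, score = 0.7))
  m2 <- matchDetections(d2, gt1, 0.5)
  expect_equal(sum(m2$det$tp), 1)
  expect_equal(sum(!m2$det$tp), 1)
  # class mismatch never matches
  d3 <- transform(d1, class_id = 1L)
  expect_equal(sum(matchDetections(d3, gt1, 0.5)$det$tp), 0)
  # random instance equals the exhaustive oracle
  set.seed(14)
  rb <- random_boxes(20); gb <- random_boxes(10)
  dets <- data.frame(x1 = rb[, 1], y1 = rb[, 2], x2 = rb[, 3], y2 = rb[, 4],
                     score = runif(20), class_id = sample(0:1, 20, TRUE))
  gts <- data.frame(x1 = gb[, 1], y1 = gb[, 2], x2 = gb[, 3], y2 = gb[, 4],
                    class_id = sample(0:1, 10, TRUE))
  mine <- matchDetections(dets, gts, 0.3)
  orac <- oracle_match(dets, gts, 0.3)
  expect_equal(mine$det$tp, orac$tp)
  expect_equal(mine$fn, orac$fn)
})

test_that("precision, recall and F1 follow their formulas with 0/0 = 0", {
  v <- precisionRecallF1(2, 1, 0)
  expect_equal(as.numeric(v), c(2 / 3, 1, 0.8))
  expect_equal(as.numeric(precisionRecallF1(0, 0, 5)), c(0, 0, 0))
  # P = R implies F1 = P (harmonic-mean identity)
  v2 <- precisionRecallF1(3, 1, 1)
  expect_equal(v2[["f1"]], v2[["precision"]])
})

test_that("average precision integrates the enveloped PR staircase", {
  expect_equal(averagePrecision(0.9, TRUE, 1), 1)
  expect_equal(averagePrecision(c(0.9, 0.8), c(TRUE, FALSE), 1), 1)
  expect_equal(averagePrecision(c(0.9, 0.8), c(FALSE, TRUE), 1), 0.5)
  und <- averagePrecision(numeric(0), logical(0), 0)
  expect_equal(as.numeric(und), 0)
  expect_true(attr(und, "undefined"))
  # 30 random scored outcomes vs the brute-force integration
  set.seed(15)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    sc <- runif(n); tp <- runif(n) < 0.5
    ng <- sum(tp) + sample(0:3, 1)
    if (ng == 0) next
    expect_equal(averagePrecision(sc, tp, ng), oracle_ap(sc, tp, ng),
                 tolerance = 1e-12)
  }
  # adding an FP below all TP scores never increases AP
  sc <- c(0.9, 0.7, 0.5); tp <- c(TRUE, TRUE, FALSE)
  base <- averagePrecision(sc, tp, 3)
  worse <- averagePrecision(c(sc, 0.1), c(tp, FALSE), 3)
  expect_lte(worse, base)
})

test_that("dataset mAP matches a hand-computed toy example", {
  # 2 images, 2 classes.  Class 0: 2 gts, detections [TP .9, FP .8, TP .7]
  # -> AP = 1*0.5 + (2/3)*0.5 = 5/6.  Class 1: 1 gt, detection misses -> 0.
  gts <- list(
    data.frame(x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 60), y2 = c(10, 60),
               class_id = c(0L, 0L)),
    data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10, class_id = 1L))
  dets <- list(
    data.frame(x1 = c(0, 20, 50), y1 = c(0, 20, 50), x2 = c(10, 30, 60),
               y2 = c(10, 30, 60), score = c(0.9, 0.8, 0.7),
               class_id = c(0L, 0L, 0L)),
    data.frame(x1 = 40, y1 = 40, x2 = 50, y2 = 50, score = 0.9, class_id = 1L))
  rep <- evaluateDetections(dets, gts, classes = 0:1)
  pc <- perClassMetrics(rep)
  expect_equal(pc$ap[pc$class_id == 0], 5 / 6)
  expect_equal(pc$ap[pc$class_id == 1], 0)
  expect_equal(mapAt50(rep), 5 / 12)
  # a detector echoing the ground truth scores mAP exactly 1
  echo <- lapply(gts, function(g) transform(g, score = 1))
  expect_equal(mapAt50(evaluateDetections(echo, gts, classes = 0:1)), 1)
  # a silent detector scores 0
  none <- lapply(gts, function(g) g[0, c("x1", "y1", "x2", "y2", "class_id")])
  none <- lapply(none, function(g) transform(g, score = numeric(0)))
  expect_equal(mapAt50(evaluateDetections(none, gts, classes = 0:1)), 0)
  # classes with no gt instances are excluded from the macro average
  rep5 <- evaluateDetections(dets, gts, classes = 0:4)
  expect_equal(mapAt50(rep5), 5 / 12)
})

test_that("the audit counts parameters and FLOPs per the stated rules", {
  m <- stagenet:::net_new(list(), seed = 0)
  stagenet:::add_conv(m, "c1", 3, 3, 3, 16, stride = 2, down = 1,
                      bias = FALSE, bn = FALSE, act = "none")
  rep <- auditModel(m, 640)
  expect_equal(totalParams(rep), 3 * 3 * 3 * 16)            # 432
  expect_equal(layerTable(rep)$hout[1], 320)
  expect_equal(totalGFlops(rep) * 1e9, 432 * 320 * 320)     # 44,236,800
  expect_equal(totalGFlops(rep), 0.0442368)
  # totals always equal the sum of itemized rows (order-independent)
  full <- auditModel(stageNet(stageNetConfig("tiny"), 3), 320)
  lt <- layerTable(full)
  expect_equal(sum(lt$params), totalParams(full))
  expect_equal(sum(lt$flops) / 1e9, totalGFlops(full))
  perm <- lt[sample(nrow(lt)), ]
  expect_equal(sum(perm$params), totalParams(full))
  expect_error(auditModel(stageNet(stageNetConfig("tiny")), 100), "divisible")
})

test_that("audit reports write CSV and JSON artifacts", {
  rep <- auditModel(stageNet(stageNetConfig("tiny"), 1), 320)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  writeAuditReport(rep, csv, js)
  back <- read.csv(csv)
  expect_equal(sum(back$params), totalParams(rep))
  j <- jsonlite::read_json(js)
  expect_equal(j$gflops, totalGFlops(rep))
  cnt <- convLayerCounts(stageNet(stageNetConfig("tiny"), 1))
  expect_true(cnt$all > cnt$merged)
})
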