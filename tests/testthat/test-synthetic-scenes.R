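test_that("scene rendering is a pure function of seed and arguments", {
  a <- renderScene(7, nObjects = 4, size = 640)
  b <- renderScene(7, nObjects = 4, size = 640)
  expect_identical(pixels(a), pixels(b))
  expect_identical(boxes(a), boxes(b))
  expect_false(identical(pixels(a), pixels(renderScene(8, nObjects = 4))))
  # the caller's RNG stream is untouched
  set.seed(99); r1 <- runif(1)
  set.seed(99); invisible(renderScene(3, nObjects = 2, size = 128)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("stage conditioning and box invariants hold", {
  img <- renderScene(7, stageMix = c(0, 0, 0, 0, 1), nObjects = 3, size = 640)
  b <- boxes(img)
  expect_equal(nrow(b), 3)
  expect_true(all(b$class_id == 4))
  expect_true(all(b$cx - b$w / 2 >= -1e-9 & b$cx + b$w / 2 <= 1 + 1e-9))
  expect_true(all(b$cy - b$h / 2 >= -1e-9 & b$cy + b$h / 2 <= 1 + 1e-9))
  expect_error(renderScene(1, nObjects = 0), "positive")
  expect_error(renderScene(1, nObjects = 2, size = 32), "size")
})

test_that("uniform stage mix produces near-uniform class frequencies", {
  cls <- unlist(lapply(1:100, function(s) {
    boxes(renderScene(s, nObjects = 6, size = 96))$class_id
  }))
  freq <- table(factor(cls, levels = 0:4)) / length(cls)
  expect_true(all(abs(freq - 0.2) < 0.05))
})

test_that("YOLO txt annotations round-trip and validate", {
  img <- renderScene(11, nObjects = 5, size = 640)
  f <- tempfile(fileext = ".txt")
  writeAnnotations(img, "yolo_txt", f)
  b2 <- readAnnotations(f, "yolo_txt")
  b1 <- boxes(img)
  expect_equal(b2$class_id, b1$class_id)
  expect_true(max(abs(as.matrix(b2[2:5]) - as.matrix(b1[2:5]))) <= 1 / 640)
  # exact formatting of a known box
  box <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.25, h = 0.25)
  img2 <- LabeledImage(array(0, c(640, 640, 3)), box)
  writeAnnotations(img2, "yolo_txt", f)
  expect_identical(readLines(f), "0 0.500000 0.500000 0.250000 0.250000")
  # malformed / invalid content
  writeLines("5 0.5 0.5 0.1 0.1", f)
  expect_error(readAnnotations(f, "yolo_txt"), "range")
  writeLines("0 0.5 0.5 0.1", f)
  expect_error(readAnnotations(f, "yolo_txt"), "line")
  writeLines("0 1.5 0.5 0.1 0.1", f)
  expect_error(readAnnotations(f, "yolo_txt"), "normalized")
  writeLines(character(0), f)
  expect_equal(nrow(readAnnotations(f, "yolo_txt")), 0)
})

test_that("VOC XML uses 1-based inclusive corners and round-trips", {
  box <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.25, h = 0.25)
  img <- LabeledImage(array(0, c(640, 640, 3)), box)
  f <- tempfile(fileext = ".xml")
  writeAnnotations(img, "voc_xml", f)
  doc <- xml2::read_xml(f)
  g <- function(x) as.numeric(xml2::xml_text(xml2::xml_find_first(doc, x)))
  # left edge 0.375*640 = 240 -> first covered pixel 241; right edge 400
  expect_equal(g(".//xmin"), 241)
  expect_equal(g(".//ymin"), 241)
  expect_equal(g(".//xmax"), 400)
  expect_equal(g(".//ymax"), 400)
  b2 <- readAnnotations(f, "voc_xml")
  expect_true(max(abs(as.matrix(b2[2:5]) - as.matrix(box[2:5]))) <= 1 / 640)
  # full-scene round trip within one pixel after denormalization
  sc <- renderScene(13, nObjects = 6, size = 640)
  writeAnnotations(sc, "voc_xml", f)
  b3 <- readAnnotations(f, "voc_xml")
  expect_equal(b3$class_id, boxes(sc)$class_id)
  expect_true(max(abs(as.matrix(b3[2:5]) - as.matrix(boxes(sc)[2:5]))) * 640 <= 1)
})

test_that("dataset splits reproduce the published arithmetic", {
  s <- splitDataset(sprintf("im%05d", 1:7528), c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(length(splitIds(s, "train")), 6022)
  expect_equal(length(splitIds(s, "test")), 753)
  expect_equal(length(splitIds(s, "val")), 753)
  expect_equal(length(splitIds(splitDataset(as.character(1:660), seed = 2), "train")), 528)
  s10 <- splitDataset(as.character(1:10), seed = 3)
  expect_equal(vapply(c("train", "test", "val"), function(k) length(splitIds(s10, k)),
                      numeric(1)),
               c(train = 8, test = 1, val = 1))
  expect_error(splitDataset(character(0)), "non-empty")
  expect_error(splitDataset(as.character(1:5), c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("splits conserve and partition the id set for every n", {
  for (n in c(1:50, 511, 997, 4999, 10000)) {
    s <- splitDataset(as.character(seq_len(n)), seed = n)
    ids <- c(splitIds(s, "train"), splitIds(s, "test"), splitIds(s, "val"))
    expect_equal(length(ids), n)
    expect_equal(sort(as.integer(ids)), seq_len(n))
  }
  # manifest files round-trip
  s <- splitDataset(sprintf("s%03d", 1:40), seed = 5)
  d <- tempfile(); writeManifest(s, d)
  s2 <- readManifest(d)
  expect_identical(splitIds(s, "train"), splitIds(s2, "train"))
  expect_identical(splitIds(s, "val"), splitIds(s2, "val"))
})

test_that("letterbox resize preserves aspect and remaps boxes", {
  img <- renderScene(5, nObjects = 2, size = 640)
  out <- resizeLetterbox(img, 640)
  expect_equal(dim(pixels(out)), c(640, 640, 3))
  expect_true(max(abs(as.matrix(boxes(out)[2:5]) - as.matrix(boxes(img)[2:5]))) < 1e-9)
  # 2:1 letterboxing geometry: H=320, W=640, centred half-size box
  px <- array(100, c(320, 640, 3))
  b <- data.frame(class_id = 1L, cx = 0.5, cy = 0.5, w = 0.5, h = 0.5)
  lb <- resizeLetterbox(LabeledImage(px, b), 640)
  expect_equal(dim(pixels(lb)), c(640, 640, 3))
  expect_equal(boxes(lb)$w, 0.5)
  expect_equal(boxes(lb)$h, 0.25)
  expect_equal(boxes(lb)$cy, 0.5)
  expect_equal(boxes(lb)$cx, 0.5)
  # padding rows are gray
  expect_true(all(pixels(lb)[1:160, , ] == 114))
  # any input size lands on the target shape
  odd <- LabeledImage(array(10, c(123, 77, 3)))
  expect_equal(dim(pixels(resizeLetterbox(odd, 640))), c(640, 640, 3))
})

test_that("PNG image I/O round-trips pixel data", {
  img <- renderScene(21, nObjects = 2, size = 96)
  f <- tempfile(fileext = ".png")
  writeImagePNG(img, f)
  back <- readImagePNG(f)
  expect_equal(dim(pixels(back)), dim(pixels(img)))
  expect_true(max(abs(pixels(back) - round(pixels(img)))) <= 1)
})
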