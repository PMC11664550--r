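# Annotation dialects and dataset bookkeeping.
#
# Two dialects are supported, mirroring common labelling tools:
#   * YOLO txt — one line per box, "class cx cy w h", normalized centre
#     format, space separated, 6-decimal fixed point.
#   * Pascal VOC XML — 1-based inclusive integer pixel corners.  The corner
#     rule is xmin = round(left_px) + 1, xmax = round(right_px) (and likewise
#     vertically), which round-trips the normalized representation to within
#     half a pixel.

#' Write box annotations for an image
#'
#' @param img a [LabeledImage-class].
#' @param dialect `"yolo_txt"` or `"voc_xml"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(img, dialect = c("yolo_txt", "voc_xml"), path) {
  dialect <- match.arg(dialect)
  b <- boxes(img)
  if (dialect == "yolo_txt") {
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", b$class_id, b$cx, b$cy, b$w, b$h)
    writeLines(lines, path)
  } else {
    d <- dim(pixels(img))
    H <- d[1]; W <- d[2]
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", paste0(imageId(img), ".png"))
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", as.character(W))
    xml2::xml_add_child(sz, "height", as.character(H))
    xml2::xml_add_child(sz, "depth", "3")
    for (i in seq_len(nrow(b))) {
      ob <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(ob, "name", stageNames()[b$class_id[i] + 1])
      bb <- xml2::xml_add_child(ob, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(round_half_up((b$cx[i] - b$w[i] / 2) * W) + 1))
      xml2::xml_add_child(bb, "ymin", as.character(round_half_up((b$cy[i] - b$h[i] / 2) * H) + 1))
      xml2::xml_add_child(bb, "xmax", as.character(round_half_up((b$cx[i] + b$w[i] / 2) * W)))
      xml2::xml_add_child(bb, "ymax", as.character(round_half_up((b$cy[i] + b$h[i] / 2) * H)))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

round_half_up <- function(x) floor(x + 0.5)

#' Read box annotations
#'
#' Inverse of [writeAnnotations()] up to coordinate quantization.  Malformed
#' YOLO lines are reported with their line numbers; class tokens outside the
#' stage taxonomy and YOLO coordinates outside `[0, 1]` raise errors.
#'
#' @param path annotation file.
#' @param dialect `"yolo_txt"` or `"voc_xml"`.
#' @return data.frame of normalized boxes (class_id, cx, cy, w, h).
#' @export
readAnnotations <- function(path, dialect = c("yolo_txt", "voc_xml")) {
  dialect <- match.arg(dialect)
  if (dialect == "yolo_txt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(emptyBoxes())
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) != 5)
    if (length(bad))
      stop(sprintf("malformed YOLO line(s): %s", paste(bad, collapse = ", ")))
    m <- do.call(rbind, lapply(parts, as.numeric))
    if (anyNA(m)) {
      bad <- which(apply(m, 1, anyNA))
      stop(sprintf("non-numeric YOLO line(s): %s", paste(bad, collapse = ", ")))
    }
    cls <- as.integer(m[, 1])
    if (any(cls < 0 | cls > 4))
      stop("class token out of range 0..4: ", paste(cls[cls < 0 | cls > 4], collapse = ", "))
    if (any(m[, 2:5] < 0 | m[, 2:5] > 1))
      stop("YOLO coordinates must be normalized to [0, 1]")
    data.frame(class_id = cls, cx = m[, 2], cy = m[, 3], w = m[, 4], h = m[, 5])
  } else {
    doc <- xml2::read_xml(path)
    W <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
    H <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
    obs <- xml2::xml_find_all(doc, ".//object")
    if (!length(obs)) return(emptyBoxes())
    rows <- lapply(obs, function(ob) {
      nm <- xml2::xml_text(xml2::xml_find_first(ob, "./name"))
      cls <- match(nm, stageNames()) - 1L
      if (is.na(cls)) stop("unknown class token: ", nm)
      g <- function(tag) as.numeric(xml2::xml_text(xml2::xml_find_first(ob, paste0("./bndbox/", tag))))
      xmin <- g("xmin"); ymin <- g("ymin"); xmax <- g("xmax"); ymax <- g("ymax")
      x1 <- (xmin - 1) / W; x2 <- xmax / W
      y1 <- (ymin - 1) / H; y2 <- ymax / H
      data.frame(class_id = cls, cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                 w = x2 - x1, h = y2 - y1)
    })
    do.call(rbind, rows)
  }
}

#' Deterministic train/test/val split
#'
#' Shuffles the ids with `seed` and assigns round-half-up counts per
#' fraction, handing any rounding remainder to the training set, so e.g.
#' 7528 ids at (0.8, 0.1, 0.1) give 6022/753/753 and 660 give 528/66/66.
#'
#' @param ids character (or coercible) vector of image ids.
#' @param fractions train/test/val fractions summing to 1.
#' @param seed shuffle seed.
#' @return A [SplitManifest-class].
#' @export
splitDataset <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 0) {
  ids <- as.character(ids)
  if (!length(ids)) stop("ids must be non-empty")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(ids)
  counts <- round_half_up(n * fractions)
  counts[1] <- counts[1] + (n - sum(counts))
  if (any(counts < 0)) stop("fractions produce a negative split size")
  perm <- with_seed(seed, sample.int(n))
  sh <- ids[perm]
  new("SplitManifest",
      train = sh[seq_len(counts[1])],
      test = sh[counts[1] + seq_len(counts[2])],
      val = sh[counts[1] + counts[2] + seq_len(counts[3])],
      fractions = as.numeric(fractions))
}

#' Write / read a split manifest as train.txt / test.txt / val.txt
#' @param manifest a [SplitManifest-class].
#' @param dir directory for the three id-per-line files.
#' @return the directory (write) or a SplitManifest (read), invisibly/visibly.
#' @export
writeManifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(manifest@train, file.path(dir, "train.txt"))
  writeLines(manifest@test, file.path(dir, "test.txt"))
  writeLines(manifest@val, file.path(dir, "val.txt"))
  invisible(dir)
}

#' @rdname writeManifest
#' @export
readManifest <- function(dir) {
  rd <- function(f) {
    x <- readLines(file.path(dir, f)); x[nzchar(x)]
  }
  tr <- rd("train.txt"); te <- rd("test.txt"); va <- rd("val.txt")
  n <- length(tr) + length(te) + length(va)
  new("SplitManifest", train = tr, test = te, val = va,
      fractions = c(length(tr), length(te), length(va)) / n)
}

#' Aspect-preserving resize with gray letterbox padding
#'
#' Resizes the longer side to `target`, pads the shorter side symmetrically
#' with neutral gray (114), and remaps the normalized boxes accordingly.
#'
#' @param img a [LabeledImage-class].
#' @param target output side length (default 640).
#' @return A [LabeledImage-class] of size `target` x `target`.
#' @export
resizeLetterbox <- function(img, target = 640) {
  px <- pixels(img)
  d <- dim(px)
  H <- d[1]; W <- d[2]
  s <- target / max(H, W)
  newH <- max(1L, as.integer(round(H * s)))
  newW <- max(1L, as.integer(round(W * s)))
  res <- bilinear_resize(px, newH, newW)
  padT <- (target - newH) %/% 2
  padL <- (target - newW) %/% 2
  out <- array(114, c(target, target, 3))
  out[padT + seq_len(newH), padL + seq_len(newW), ] <- res
  b <- boxes(img)
  if (nrow(b)) {
    b$cx <- (b$cx * newW + padL) / target
    b$cy <- (b$cy * newH + padT) / target
    b$w <- b$w * newW / target
    b$h <- b$h * newH / target
  }
  LabeledImage(out, b, imageId = imageId(img), seed = img@seed)
}

# Plain bilinear resize of an (H, W, C) array (half-pixel centre convention).
bilinear_resize <- function(x, newH, newW) {
  d <- dim(x)
  sy <- (seq_len(newH) - 0.5) * d[1] / newH - 0.5
  sx <- (seq_len(newW) - 0.5) * d[2] / newW - 0.5
  SX <- array(rep(sx, each = newH), c(newH, newW, 1))
  SY <- array(rep(sy, times = newW), c(newH, newW, 1))
  cpp_gridsample_fw(x, dim(x), SX, SY, dim(SX))
}
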