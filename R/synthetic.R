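# Synthetic stage-labelled strawberry scenes.
#
# The generator renders caricature phenotypes keyed to the five growth stages:
# flowering (white petal disc, yellow centre), young fruit (small green berry),
# fruit expansion (larger pale fruit), colour turning (pink / partially red)
# and maturation (saturated red), each as an axis-aligned ellipse with achene
# speckles and a calyx wedge on a textured green canopy background.  It is a
# test harness emulating the look of greenhouse imagery, not a biological
# claim; tight ground-truth boxes come for free from the geometry.

stagePalette <- function() {
  list(
    list(body = c(246, 244, 238), accent = c(250, 208, 60),  rmin = 16, rmax = 30),  # Flowering
    list(body = c(112, 158, 74),  accent = c(196, 186, 90),  rmin = 9,  rmax = 18),  # Young Fruit
    list(body = c(214, 216, 190), accent = c(180, 170, 90),  rmin = 22, rmax = 38),  # Fruit Expansion
    list(body = c(232, 120, 128), accent = c(240, 220, 150), rmin = 26, rmax = 42),  # Color Turning
    list(body = c(198, 32, 40),   accent = c(245, 222, 130), rmin = 28, rmax = 50)   # Maturation
  )
}

# Evaluate an expression with a private, seeded RNG stream; the caller's RNG
# state is untouched, so identical (seed, arguments) give identical output.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render one synthetic growth-stage scene
#'
#' Draws `nObjects` stage-conditioned fruit/flower ellipses on a textured
#' green background and returns the image together with one tight normalized
#' box per object.  The function is a pure function of its arguments:
#' identical `(seed, stageMix, nObjects, size)` give byte-identical pixels
#' and boxes.
#'
#' @param seed integer seed for the private RNG stream.
#' @param stageMix probability weights over the five stages (recycled and
#'   normalized); default uniform.
#' @param nObjects number of objects, 1-12 in typical scenes.
#' @param size square image side in pixels (>= 64); scenes are generated at
#'   their native size, see [resizeLetterbox()] for the 640 network input.
#' @return A [LabeledImage-class].
#' @examples
#' img <- renderScene(seed = 7, nObjects = 3)
#' boxes(img)
#' @export
renderScene <- function(seed, stageMix = rep(1, 5), nObjects = 6, size = 640) {
  if (length(nObjects) != 1 || nObjects < 1)
    stop("nObjects must be a positive integer")
  if (size < 64) stop("size must be >= 64")
  stageMix <- rep_len(as.numeric(stageMix), 5)
  if (any(stageMix < 0) || sum(stageMix) <= 0)
    stop("stageMix must be non-negative with positive sum")
  stageMix <- stageMix / sum(stageMix)
  with_seed(seed, {
    px <- scene_background(size)
    pal <- stagePalette()
    sc <- size / 640
    rows <- vector("list", nObjects)
    for (i in seq_len(nObjects)) {
      cls <- sample.int(5, 1, prob = stageMix) - 1L
      p <- pal[[cls + 1]]
      r <- runif(1, p$rmin, p$rmax) * sc
      asp <- runif(1, 0.8, 1.25)
      rx <- max(3, r * sqrt(asp))
      ry <- max(3, r / sqrt(asp))
      cx <- runif(1, rx + 2, size - rx - 2)
      cy <- runif(1, ry + 2, size - ry - 2)
      px <- draw_object(px, cls, cx, cy, rx, ry, p, size)
      # tight box: ellipse plus the calyx wedge overhanging the top
      calyx <- if (cls >= 1) 0.25 * ry else 0
      x1 <- max(0, cx - rx); x2 <- min(size, cx + rx)
      y1 <- max(0, cy - ry - calyx); y2 <- min(size, cy + ry)
      rows[[i]] <- data.frame(class_id = cls,
                              cx = (x1 + x2) / 2 / size, cy = (y1 + y2) / 2 / size,
                              w = (x2 - x1) / size, h = (y2 - y1) / size)
    }
    LabeledImage(px, do.call(rbind, rows),
                 imageId = sprintf("scene_%d", seed), seed = seed)
  })
}

scene_background <- function(size) {
  base <- c(72, 118, 62)
  xs <- seq_len(size); ys <- seq_len(size)
  # smooth leaf-like luminance field from a few random sinusoids
  f <- matrix(0, size, size)
  for (k in 1:3) {
    fr <- runif(2, 1.5, 5) * 2 * pi / size
    ph <- runif(2, 0, 2 * pi)
    f <- f + outer(sin(ys * fr[1] + ph[1]), cos(xs * fr[2] + ph[2]))
  }
  f <- f / 3
  noise <- matrix(rnorm(size * size, 0, 6), size, size)
  px <- array(0, c(size, size, 3))
  for (c in 1:3) px[, , c] <- base[c] + 18 * f + noise
  clip255(px)
}

draw_object <- function(px, cls, cx, cy, rx, ry, p, size) {
  x1 <- max(1, floor(cx - rx - ry)); x2 <- min(size, ceiling(cx + rx + ry))
  y1 <- max(1, floor(cy - 1.4 * ry)); y2 <- min(size, ceiling(cy + ry + 2))
  xs <- x1:x2; ys <- y1:y2
  X <- matrix(xs - 0.5, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys - 0.5, length(ys), length(xs))
  body <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
  jit <- runif(3, -14, 14)
  shade <- 1 - 0.25 * pmax(0, ((X - cx) / rx + (Y - cy) / ry)) # simple light falloff
  for (c in 1:3) {
    ch <- px[ys, xs, c]
    ch[body] <- ((p$body[c] + jit[c]) * shade)[body]
    px[ys, xs, c] <- ch
  }
  if (cls == 0L) {
    # flower: yellow centre disc
    cent <- ((X - cx) / (0.35 * rx))^2 + ((Y - cy) / (0.35 * ry))^2 <= 1
    for (c in 1:3) {
      ch <- px[ys, xs, c]; ch[cent] <- p$accent[c]; px[ys, xs, c] <- ch
    }
  } else {
    # achene speckles inside the berry
    nsp <- max(4L, round(rx * ry / 18))
    u <- runif(nsp, 0, 2 * pi); v <- sqrt(runif(nsp, 0.05, 0.92))
    sx <- cx + v * rx * cos(u); sy <- cy + v * ry * sin(u)
    for (j in seq_len(nsp)) {
      dot <- (X - sx[j])^2 + (Y - sy[j])^2 <= max(1, 0.02 * rx * ry)
      for (c in 1:3) {
        ch <- px[ys, xs, c]; ch[dot] <- p$accent[c]; px[ys, xs, c] <- ch
      }
    }
    # calyx wedge: small dark-green ellipse overhanging the top
    gx <- 0.45 * rx; gy <- 0.35 * ry
    cal <- (((X - cx) / gx)^2 + ((Y - (cy - ry)) / gy)^2 <= 1) & (Y <= cy - 0.6 * ry)
    for (c in 1:3) {
      ch <- px[ys, xs, c]; ch[cal] <- c(60, 110, 50)[c]; px[ys, xs, c] <- ch
    }
  }
  clip255(px)
}

clip255 <- function(x) {
  x[x < 0] <- 0; x[x > 255] <- 255
  x
}

#' Render a batch of scenes
#'
#' Convenience wrapper drawing per-scene seeds from `seed` so a whole dataset
#' is reproducible from one integer.
#'
#' @param n number of scenes.
#' @param seed master seed.
#' @param nObjects either a single count or the range (min, max) sampled per
#'   scene; default 1-12 objects.
#' @inheritParams renderScene
#' @return List of [LabeledImage-class] objects.
#' @export
renderScenes <- function(n, seed = 1, stageMix = rep(1, 5),
                         nObjects = c(1, 12), size = 640) {
  plan <- with_seed(seed, {
    data.frame(seed = sample.int(2^30, n),
               n = if (length(nObjects) == 1) rep(nObjects, n)
                   else sample(seq(nObjects[1], nObjects[2]), n, replace = TRUE))
  })
  lapply(seq_len(n), function(i) {
    img <- renderScene(plan$seed[i], stageMix, plan$n[i], size)
    img@imageId <- sprintf("scene_%03d", i)
    img
  })
}

#' Write a LabeledImage to a PNG file
#' @param img a [LabeledImage-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  arr <- pixels(img) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a PNG/JPEG image as a LabeledImage with no annotations
#' @param path image file (PNG).
#' @param imageId id to assign; defaults to the file name.
#' @return A [LabeledImage-class] with empty boxes.
#' @export
readImagePNG <- function(path, imageId = sub("\\.[^.]+$", "", basename(path))) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  LabeledImage(round(arr * 255), imageId = imageId)
}
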