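# Deterministic desk-scale training loop: SGD with momentum, weight decay
# and a linear warmup of learning rate and momentum over the first epochs.

#' Training configuration
#'
#' Defaults follow the published schedule: SGD, momentum 0.937, initial and
#' final learning rate 0.01, weight decay 0.0005, 3 warmup epochs starting
#' from momentum 0.8 and a 0.1x learning-rate multiplier, 640 input, batch
#' 16, loss weights (7.5, 0.5, 0.7, 1.5), anchor matching radius 5 cells and
#' a 0.2 minimum-IoU floor for positives.  `imageSize`/`batchSize` are
#' typically lowered for desk-scale experiments.
#'
#' @param ... overrides of any default field.
#' @return named list of training hyperparameters.
#' @export
trainConfig <- function(...) {
  cfg <- list(
    momentum = 0.937,
    initial_lr = 0.01,
    final_lr = 0.01,
    weight_decay = 0.0005,
    warmup_epochs = 3.0,
    warmup_momentum = 0.8,
    warmup_lr = 0.1,
    imageSize = 640,
    batchSize = 16,
    optimizer = "SGD",
    iou_train_threshold = 0.2,
    anchor_match_threshold = 5.0,
    box_loss_factor = 7.5,
    cls_loss_factor = 0.5,
    cls_loss_weight = 1.0,
    obj_loss_factor = 0.7,
    obj_loss_weight = 1.0,
    dfl_loss_factor = 1.5,
    seed = 0
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

loss_weights <- function(cfg) {
  c(cfg$box_loss_factor, cfg$cls_loss_factor * cfg$cls_loss_weight,
    cfg$obj_loss_factor * cfg$obj_loss_weight, cfg$dfl_loss_factor)
}

#' Warmup schedule for learning rate and momentum
#'
#' Linear interpolation from `(warmup_lr * initial_lr, warmup_momentum)` at
#' step 0 to `(initial_lr, momentum)` at the end of warmup; constant at the
#' final learning rate afterwards.
#'
#' @param step 0-based optimizer step.
#' @param totalWarmupSteps number of warmup steps (>= 1).
#' @param cfg a [trainConfig()].
#' @return named numeric vector (lr, momentum).
#' @export
warmupSchedule <- function(step, totalWarmupSteps, cfg = trainConfig()) {
  stopifnot(totalWarmupSteps >= 1)
  if (step >= totalWarmupSteps)
    return(c(lr = cfg$final_lr, momentum = cfg$momentum))
  f <- step / totalWarmupSteps
  c(lr = (1 - f) * cfg$warmup_lr * cfg$initial_lr + f * cfg$initial_lr,
    momentum = (1 - f) * cfg$warmup_momentum + f * cfg$momentum)
}

#' Train a detector on a set of labelled images
#'
#' Plain SGD over the composite loss, fully seeded (data order and batch
#' composition derive from `cfg$seed`); batch statistics of every
#' normalization layer update running averages used at inference.  Images
#' are letterboxed to `cfg$imageSize` if needed.  Aborts with a diagnostic
#' if the loss becomes non-finite.
#'
#' @param model a [StageNet-class]; updated in place and returned.
#' @param images list of [LabeledImage-class] training images.
#' @param iterations number of optimizer steps.
#' @param cfg a [trainConfig()].
#' @return list: `model`, `trace` (one row per step: components, weighted
#'   total, lr, momentum, positives).
#' @export
trainModel <- function(model, images, iterations, cfg = trainConfig()) {
  m <- model_env(model)
  stopifnot(length(images) > 0)
  images <- lapply(images, function(im) {
    if (!all(dim(pixels(im))[1:2] == cfg$imageSize))
      resizeLetterbox(im, cfg$imageSize) else im
  })
  xs <- lapply(images, function(im) norm_input(im))
  bs <- lapply(images, boxes)
  n <- length(images)
  batch <- min(cfg$batchSize, n)
  steps_per_epoch <- max(1, ceiling(n / batch))
  warm <- max(1, round(cfg$warmup_epochs * steps_per_epoch))
  vel <- new.env(parent = emptyenv())
  trace <- vector("list", iterations)
  wts <- loss_weights(cfg)
  with_seed(cfg$seed, {
    order_pool <- integer(0)
    for (it in seq_len(iterations)) {
      if (length(order_pool) < batch) order_pool <- c(order_pool, sample.int(n))
      idx <- order_pool[seq_len(batch)]
      order_pool <- order_pool[-seq_len(batch)]
      sched <- warmupSchedule(it - 1, warm, cfg)
      acc <- list()
      comp <- c(box = 0, cls = 0, obj = 0, dfl = 0, total = 0)
      npos <- 0
      for (i in idx) {
        tp <- tp_new()
        fwd <- model_forward(m, tp, tp_leaf(tp, xs[[i]]), train = TRUE)
        predsV <- lapply(fwd$heads, function(h) {
          list(reg = tp_v(tp, h$reg), cls = tp_v(tp, h$cls),
               obj = tp_v(tp, h$obj), stride = h$stride)
        })
        asg <- assignTargets(predsV, bs[[i]], cfg$imageSize,
                             radius = cfg$anchor_match_threshold,
                             iouFloor = cfg$iou_train_threshold,
                             regMax = m$cfg$regMax)
        l <- loss_on_tape(tp, fwd$heads, asg, m$cfg$nc, m$cfg$regMax,
                          m$cfg$innerIoURatio, wts)
        if (!is.finite(tp_v(tp, l$total)))
          stop(sprintf("non-finite loss at iteration %d (image %s)",
                       it, imageId(images[[i]])))
        comp <- comp + c(tp_v(tp, l$box), tp_v(tp, l$cls), tp_v(tp, l$obj),
                         tp_v(tp, l$dfl), tp_v(tp, l$total)) / batch
        npos <- npos + l$npos
        g <- tp_leaf_grads(tp, tp_backward(tp, l$total))
        for (nm in names(g)) {
          acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
        }
      }
      for (nm in names(acc)) {
        gr <- acc[[nm]] / batch
        if (grepl("\\.w$", nm)) gr <- gr + cfg$weight_decay * m$par[[nm]]
        v <- if (is.null(vel[[nm]])) 0 else vel[[nm]]
        v <- sched["momentum"] * v + gr
        vel[[nm]] <- v
        m$par[[nm]] <- m$par[[nm]] - sched["lr"] * v
      }
      trace[[it]] <- data.frame(iter = it, box = comp["box"], cls = comp["cls"],
                                obj = comp["obj"], dfl = comp["dfl"],
                                total = comp["total"], lr = sched["lr"],
                                momentum = sched["momentum"], npos = npos)
    }
  })
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  list(model = model, trace = trace)
}

#' Evaluate a detector on a labelled dataset
#'
#' Runs inference with evaluation thresholds (confidence 0.001, NMS IoU
#' 0.7 by default), matches against the ground truth at IoU 0.5 and returns
#' the metric report.
#'
#' @param model a [StageNet-class].
#' @param images list of [LabeledImage-class] with annotations.
#' @param cfg a [trainConfig()] (for the image size).
#' @param confThr,nmsIoU decoding thresholds.
#' @return A [MetricReport-class].
#' @export
evaluateModel <- function(model, images, cfg = trainConfig(),
                          confThr = 0.001, nmsIoU = 0.7) {
  stopifnot(length(images) > 0)
  images <- lapply(images, function(im) {
    if (!all(dim(pixels(im))[1:2] == cfg$imageSize))
      resizeLetterbox(im, cfg$imageSize) else im
  })
  dets <- lapply(images, function(im) detect(model, im, confThr, nmsIoU))
  gts <- lapply(images, function(im) boxes_to_xyxy(boxes(im), cfg$imageSize))
  evaluateDetections(dets, gts, classes = 0:(model_env(model)$cfg$nc - 1))
}
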