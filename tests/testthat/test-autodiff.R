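# Numeric gradient verification of the internal reverse-mode tape: every
# differentiable operation used by the network is checked against central
# differences on small random instances.

tape_check <- function(f_tape, leaves, tol = 1e-6) {
  tp <- stagenet:::tp_new()
  ids <- lapply(names(leaves), function(nm) stagenet:::tp_leaf(tp, leaves[[nm]], nm))
  names(ids) <- names(leaves)
  out <- f_tape(tp, ids)
  grads <- stagenet:::tp_backward(tp, out)
  lg <- stagenet:::tp_leaf_grads(tp, grads)
  for (nm in names(leaves)) {
    fn <- function(x) {
      l2 <- leaves; l2[[nm]] <- x
      tp2 <- stagenet:::tp_new()
      ids2 <- lapply(names(l2), function(n2) stagenet:::tp_leaf(tp2, l2[[n2]], n2))
      names(ids2) <- names(l2)
      stagenet:::tp_v(tp2, f_tape(tp2, ids2))
    }
    ng <- num_grad(fn, leaves[[nm]])
    ag <- lg[[nm]] %||% array(0, dim(ng) %||% length(ng))
    expect_lt(max(abs(ng - ag)), tol)
  }
}

test_that("convolution, depthwise and pooling gradients match finite differences", {
  set.seed(20)
  sg <- stagenet:::`%||%`  # silence lint; helpers loaded
  H <- 5; W <- 6; C <- 3; Co <- 4
  x <- array(rnorm(H * W * C), c(H, W, C))
  Wt <- matrix(rnorm(9 * C * Co) * 0.3, 9 * C, Co)
  b <- rnorm(Co)
  for (s in 1:2) {
    tape_check(function(tp, ids)
      stagenet:::ag_mean(tp, stagenet:::ag_relu(tp,
        stagenet:::ag_conv2d(tp, ids$x, ids$w, ids$b, 3, 3, s, 1))),
      list(x = x, w = Wt, b = b))
  }
  Wd <- matrix(rnorm(25 * C) * 0.2, 25, C)
  tape_check(function(tp, ids)
    stagenet:::ag_mean(tp, stagenet:::ag_dwconv(tp, ids$x, ids$w, 5, 5, 2, 2)),
    list(x = x, w = Wd))
  tape_check(function(tp, ids)
    stagenet:::ag_mean(tp, stagenet:::ag_maxpool(tp, ids$x, 3, 2, 1)),
    list(x = x))
})

test_that("normalization, resampling and attention gradients are exact", {
  set.seed(21)
  H <- 5; W <- 6; C <- 4
  x <- array(rnorm(H * W * C), c(H, W, C))
  mixer <- array(rnorm(H * W * C), c(H, W, C))
  tape_check(function(tp, ids)
    stagenet:::ag_mean(tp, stagenet:::ag_mul(tp,
      stagenet:::ag_bn_train(tp, ids$x, ids$g, ids$b), stagenet:::tp_leaf(tp, mixer))),
    list(x = x, g = rnorm(C), b = rnorm(C)), tol = 2e-5)
  sx <- array(runif(4 * 4 * 2) * (W - 1), c(4, 4, 2))
  sy <- array(runif(4 * 4 * 2) * (H - 1), c(4, 4, 2))
  tape_check(function(tp, ids)
    stagenet:::ag_mean(tp, stagenet:::ag_gridsample(tp, ids$x, ids$sx, ids$sy)),
    list(x = x, sx = sx, sy = sy), tol = 1e-5)
  # windowed attention: one fused node over all windows and heads
  plan <- stagenet:::irmb_window_plan(H, W, 3, 1)
  q <- array(rnorm(H * W * C) * 0.5, c(H, W, C))
  k <- array(rnorm(H * W * C) * 0.5, c(H, W, C))
  v <- array(rnorm(H * W * C), c(H, W, C))
  tape_check(function(tp, ids)
    stagenet:::ag_mean(tp, stagenet:::ag_ewmhsa(tp, ids$q, ids$k, ids$v, plan, 2)),
    list(q = q, k = k, v = v), tol = 1e-5)
})

test_that("shape ops, reductions and loss primitives backpropagate correctly", {
  set.seed(22)
  x <- array(rnorm(60), c(5, 4, 3))
  A <- matrix(rnorm(12), 3, 4)
  tape_check(function(tp, ids)
    stagenet:::ag_mean(tp, stagenet:::ag_gather(tp, ids$x,
      c(NA, 3L, 3L, 1L, 10L, 60L), c(2, 3, 1))), list(x = x))
  tape_check(function(tp, ids)
    stagenet:::ag_mean(tp, stagenet:::ag_slice_c(tp,
      stagenet:::ag_concat_c(tp, list(ids$x, ids$x)), c(2, 5))), list(x = x))
  tape_check(function(tp, ids)
    stagenet:::ag_mean(tp, stagenet:::ag_mul_chan(tp, ids$x, ids$l)),
    list(x = x, l = rnorm(3)))
  tgt <- array(rbinom(60, 1, 0.5), c(5, 4, 3))
  wt <- array(runif(60), c(5, 4, 3))
  tape_check(function(tp, ids)
    stagenet:::ag_bce_logits(tp, ids$x, tgt, wt), list(x = x))
  tape_check(function(tp, ids)
    stagenet:::ag_mean(tp, stagenet:::ag_sigmoid(tp, stagenet:::ag_gap(tp, ids$x))),
    list(x = x))
  # the two head loss nodes (Inner-IoU box loss and distribution loss)
  nb <- 8
  reg <- matrix(rnorm(3 * 4 * nb) * 0.5, 3, 4 * nb)
  centers <- cbind(c(20, 40, 60), c(20, 40, 60))
  gtb <- cbind(c(5, 30, 50), c(8, 28, 52), c(35, 55, 75), c(30, 50, 70))
  tape_check(function(tp, ids)
    stagenet:::ag_inner_box_loss(tp, ids$r, centers, gtb, 8, 0.75, nb),
    list(r = reg), tol = 1e-5)
  tgtd <- matrix(runif(12, 0, nb - 1.2), 3, 4)
  tape_check(function(tp, ids)
    stagenet:::ag_dfl_loss(tp, ids$r, tgtd, nb), list(r = reg), tol = 1e-5)
})
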