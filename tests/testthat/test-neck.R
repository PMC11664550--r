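test_that("DySample with a zero offset head is plain bilinear upsampling", {
  set.seed(4)
  for (i in 1:5) {
    x <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
    expect_lt(max(abs(dySample(x) - oracle_bilinear_up2(x))), 1e-9)
  }
  # constant input stays constant regardless of offsets
  xc <- array(3.5, c(4, 4, 4))
  w <- array(rnorm(4 * 32), c(1, 1, 4, 32))
  expect_lt(max(abs(dySample(xc, offsetWeight = w,
                             offsetBias = rnorm(32)) - 3.5)), 1e-9)
})

test_that("a constant one-pixel offset shifts the zero-offset output", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  base <- dySample(x)
  # bias of +1 input pixel in x for every group, zero in y; range factor 1
  bias <- c(rep(1, 16), rep(0, 16))
  shifted <- dySample(x, rangeFactor = 1, offsetBias = bias)
  # interior columns: output(j) == base(j + 2) since one input pixel = two
  # output pixels
  expect_lt(max(abs(shifted[, 1:12, ] - base[, 3:14, ])), 1e-9)
})

test_that("reparameterized deploy mode equals the multi-branch sum", {
  set.seed(6)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  b3a <- array(rnorm(3 * 3 * 3 * 5) * 0.3, c(3, 3, 3, 5))
  b3b <- array(rnorm(3 * 3 * 3 * 5) * 0.3, c(3, 3, 3, 5))
  tr <- repConvBlock(x, list(b3a, b3b), mode = "train")
  dp <- repConvBlock(x, list(b3a, b3b), mode = "deploy")
  expect_lt(max(abs(tr - dp)), 1e-5)
  # mixed kernel sizes with identity branch and bias
  sq <- array(rnorm(3 * 3 * 3 * 3) * 0.3, c(3, 3, 3, 3))
  one <- array(rnorm(1 * 1 * 3 * 3) * 0.3, c(1, 1, 3, 3))
  bias <- rnorm(3)
  tr2 <- repConvBlock(x, list(sq, one), identity = TRUE, bias = bias, "train")
  dp2 <- repConvBlock(x, list(sq, one), identity = TRUE, bias = bias, "deploy")
  expect_lt(max(abs(tr2 - dp2)), 1e-5)
  # single branch: both modes trivially identical
  expect_equal(repConvBlock(x, list(sq), mode = "train"),
               repConvBlock(x, list(sq), mode = "deploy"))
  # zero branches give zero output plus bias
  z <- array(0, c(3, 3, 3, 3))
  out <- repConvBlock(x, list(z), bias = c(1, 2, 3), mode = "train")
  expect_true(all(out[, , 1] == 1) && all(out[, , 3] == 3))
})

test_that("in-model RepNCSPELAN4 agrees between train and deploy", {
  cfg <- stageNetConfig("tiny")
  m <- stagenet:::net_new(cfg, seed = 9)
  stagenet:::add_repncspelan4(m, "blk", 8, 8, 8, 1)
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  run <- function(deploy) {
    tp <- stagenet:::tp_new()
    stagenet:::tp_v(tp, stagenet:::fw_repncspelan4(
      m, tp, stagenet:::tp_leaf(tp, x), "blk", train = FALSE, deploy = deploy))
  }
  expect_lt(max(abs(run(FALSE) - run(TRUE))), 1e-5)
})

test_that("SPPELAN and AConv obey their contracts", {
  xc <- array(2, c(8, 8, 6))
  out <- sppELAN(xc, cout = 5)
  expect_equal(dim(out), c(8, 8, 5))
  # max pools of a constant map are constant, so every output channel is flat
  expect_lt(max(apply(out, 3, function(ch) diff(range(ch)))), 1e-9)
  set.seed(7)
  xr <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  expect_equal(dim(sppELAN(xr, cout = 12))[3], 12)
  expect_equal(dim(aConv(xr, 10)), c(4, 4, 10))
  expect_equal(dim(aConv(array(1, c(7, 7, 2)), 3))[1:2], c(4, 4))
})

test_that("channel concatenation stacks widths and checks geometry", {
  a <- array(1, c(4, 4, 4)); b <- array(2, c(4, 4, 6))
  out <- concatFeatures(a, b)
  expect_equal(dim(out), c(4, 4, 10))
  expect_true(all(out[, , 1:4] == 1) && all(out[, , 5:10] == 2))
  expect_error(concatFeatures(a, array(1, c(5, 4, 2))), "spatial")
})

test_that("iRMB preserves shape and normalizes attention", {
  set.seed(8)
  x <- array(rnorm(10 * 10 * 8), c(10, 10, 8))
  out <- irmb(x, heads = 2, window = 4, ext = 2, seed = 3)
  expect_equal(dim(out), dim(x))
  rs <- attr(out, "attnRowSums")
  expect_gt(length(rs), 0)
  expect_lt(max(abs(rs - 1)), 1e-6)
  expect_error(irmb(x, heads = 3), "divisible")
  # degenerate configuration: 1x1 windows, identity value projection, delta
  # depthwise kernel, no normalization -> attention output is the input, so
  # the block returns input + input
  y <- irmb(x, heads = 1, window = 1, ext = 0, identityValue = TRUE)
  expect_lt(max(abs(array(y, dim(x)) - 2 * x)), 1e-9)
})

test_that("dual-stream fusion follows the weighted +1 combination", {
  set.seed(9)
  A <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  B <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  expect_true(all(dualStreamFuse(A, B, lambda = 0, mu = 0) == 2))
  expect_equal(dualStreamFuse(A, B, lambda = 1, mu = 0), A + 2)
  expect_equal(dualStreamFuse(A, B, lambda = 0, mu = 3), 3 * B + 2)
  expect_error(dualStreamFuse(A, array(0, c(5, 6, 4)), 1, 1), "match")
  # refinement applies only above the confidence threshold
  rk <- array(0, c(1, 1, 4, 4)); for (c in 1:4) rk[1, 1, c, c] <- 2
  gated <- dualStreamFuse(A, B, 0, 0, refineKernel = rk, tau = 10)
  expect_true(all(gated == 2))          # mean |2| < 10: pass-through
  refined <- dualStreamFuse(A, B, 0, 0, refineKernel = rk, tau = 1)
  expect_true(all(refined == 4))        # mean |2| > 1: pointwise conv applied
})

test_that("gradient of the fused map w.r.t. lambda at lambda = 0 is stream A", {
  set.seed(10)
  cfg <- stageNetConfig("tiny")
  m <- stagenet:::net_new(list(irmb = cfg$irmb, fusion = list(tau = Inf)), seed = 4)
  stagenet:::add_fuse(m, "f", 8, 8, 1)
  m$par[["f.lambda"]][] <- 0
  m$par[["f.mu"]][] <- 0
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  tp <- stagenet:::tp_new()
  out <- stagenet:::fw_fuse(m, tp, stagenet:::tp_leaf(tp, x), "f", train = FALSE)
  # recover stream A by evaluating the rep branch alone
  tp2 <- stagenet:::tp_new()
  a <- stagenet:::tp_v(tp2, stagenet:::fw_repncspelan4(
    m, tp2, stagenet:::tp_leaf(tp2, x), "f.rep", train = FALSE))
  g <- stagenet:::tp_leaf_grads(tp, stagenet:::tp_backward(tp, stagenet:::ag_sum(tp, out)))
  # d fused / d lambda_c = sum over pixels of A[, , c]
  expect_equal(as.numeric(g[["f.lambda"]]),
               as.numeric(apply(a, 3, sum)), tolerance = 1e-8)
  # finite-difference cross-check on one channel
  f_of <- function(l1) {
    m$par[["f.lambda"]][1] <- l1
    tpz <- stagenet:::tp_new()
    v <- stagenet:::tp_v(tpz, stagenet:::fw_fuse(m, tpz, stagenet:::tp_leaf(tpz, x),
                                                 "f", train = FALSE))
    sum(v)
  }
  eps <- 1e-6
  fd <- (f_of(eps) - f_of(-eps)) / (2 * eps)
  m$par[["f.lambda"]][1] <- 0
  expect_equal(fd, as.numeric(g[["f.lambda"]])[1], tolerance = 1e-4)
})
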