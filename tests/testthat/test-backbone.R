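test_that("conv2d matches identity, hand sums and the brute-force oracle", {
  set.seed(1)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  # identity 1x1 kernel per channel
  k <- array(0, c(1, 1, 2, 2)); k[1, 1, 1, 1] <- 1; k[1, 1, 2, 2] <- 1
  expect_equal(conv2d(x, k), x)
  # all-ones 3x3 on constant single-channel input: interior pixels sum to 9
  ones <- conv2d(array(1, c(5, 5, 1)), array(1, c(3, 3, 1, 1)))
  expect_equal(ones[3, 3, 1], 9)
  expect_equal(ones[1, 1, 1], 4)  # zero padding at the corner
  # random instances vs direct nested-loop evaluation
  for (s in 1:2) {
    k <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
    b <- rnorm(4)
    expect_lt(max(abs(conv2d(x, k, b, stride = s) - oracle_conv(x, k, b, s))), 1e-5)
  }
  expect_error(conv2d(x, array(1, c(3, 3, 3, 1))), "channel mismatch")
})

test_that("depthwise convolution never mixes channels", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  # delta kernels reproduce the input
  delta <- array(0, c(3, 3, 2)); delta[2, 2, ] <- 1
  expect_equal(depthwiseConv(x, delta), x)
  # zeroing channel 1 of the input zeroes only channel 1 of the output
  k <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  x0 <- x; x0[, , 1] <- 0
  y0 <- depthwiseConv(x0, k)
  expect_true(all(y0[, , 1] == 0))
  expect_equal(y0[, , 2], depthwiseConv(x, k)[, , 2])
  # equals a full convolution with a block-diagonal kernel
  kb <- array(0, c(3, 3, 2, 2)); kb[, , 1, 1] <- k[, , 1]; kb[, , 2, 2] <- k[, , 2]
  expect_lt(max(abs(depthwiseConv(x, k, stride = 2) -
                      conv2d(x, kb, stride = 2))), 1e-10)
  expect_error(depthwiseConv(x, array(1, c(3, 3, 3))), "mismatch")
})

test_that("batch norm, relu and global average pooling follow their formulas", {
  x <- array(5, c(1, 1, 1))
  expect_equal(as.numeric(batchNorm(x, mean = 3, var = 4, eps = 1e-12)), 1,
               tolerance = 1e-6)
  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  pool <- globalAvgPool(array(c(1, 5, 3, 7), c(2, 2, 1)))
  expect_equal(as.numeric(pool), 4)
  expect_error(batchNorm(x, eps = 0))
})

test_that("UIB block honors shortcut identity, stride and parameter count", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  # all-zero weights with shortcut: output equals input exactly
  y <- uibBlock(x, cout = 6, expansion = 2, kernel = 3, stride = 1,
                zeroWeights = TRUE)
  expect_equal(array(y, dim(x)), x)
  # stride 2 halves spatial dims
  y2 <- uibBlock(x, cout = 10, expansion = 2, kernel = 5, stride = 2)
  expect_equal(dim(y2), c(4, 4, 10))
  # parameter count equals the hand sum of the three convolutions + BN terms
  ce <- 6 * 2
  hand <- (6 * ce + 2 * ce) + (5 * 5 * ce + 2 * ce) + (ce * 10 + 2 * 10)
  expect_equal(attr(y2, "nparams"), hand)
})

test_that("backbone emits the contracted pyramid shapes", {
  cfg <- stageNetConfig("tiny")
  model <- stageNet(cfg, seed = 1)
  pf <- backboneForward(model, array(runif(640 * 640 * 3), c(640, 640, 3)))
  expect_equal(dim(featureMap(pf, "p3"))[1:2], c(80, 80))
  expect_equal(dim(featureMap(pf, "p4"))[1:2], c(40, 40))
  expect_equal(dim(featureMap(pf, "p5"))[1:2], c(20, 20))
  pf2 <- backboneForward(model, array(0.5, c(320, 320, 3)))
  expect_equal(dim(featureMap(pf2, "p3"))[1:2], c(40, 40))
  expect_equal(dim(featureMap(pf2, "p5"))[1:2], c(10, 10))
  expect_equal(dim(featureMap(pf2, "p3"))[3], cfg$backbone$widths[2])
  expect_error(backboneForward(model, array(0, c(100, 100, 3))), "divisible")
  # deterministic in inference mode
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(featureMap(backboneForward(model, x), "p5"),
                   featureMap(backboneForward(model, x), "p5"))
})

test_that("backbone parameters equal the audit's layer enumeration", {
  model <- stageNet(stageNetConfig("tiny"), seed = 2)
  rep <- auditModel(model, 320)
  me <- stagenet:::model_env(model)
  stored <- sum(vapply(ls(me$par), function(n) length(me$par[[n]]), numeric(1)))
  expect_equal(totalParams(rep), stored)
  bk_rows <- grepl("^(stem|s[1-4]\\.)", layerTable(rep)$name)
  bk_names <- ls(me$par)[grepl("^(stem|s[1-4]\\.)", ls(me$par))]
  expect_equal(sum(layerTable(rep)$params[bk_rows]),
               sum(vapply(bk_names, function(n) length(me$par[[n]]), numeric(1))))
})
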