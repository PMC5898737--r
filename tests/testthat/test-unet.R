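test_that("the default architecture matches its closed-form parameter count", {
  cfg <- unetConfig()
  expect_equal(countParameters(cfg), 387889)
  expect_equal(countConvLayers(cfg), 11)
  expect_equal(networkParameterCount(buildUnet(cfg, seed = 1)), 387889)
  # independently enumerated small config
  small <- unetConfig(nLevels = 2, baseChannels = 2)
  expect_equal(countParameters(small), 1371)
  expect_equal(countParameters(small), oracleParamCount(2, 2, 1, 1))
  # doubling the output head adds one 1x1x1 map: 16 weights + 1 bias
  expect_equal(countParameters(unetConfig(outChannels = 2)) -
                 countParameters(unetConfig()), 17)
})

test_that("closed form equals the built network for random configurations", {
  set.seed(20)
  for (i in 1:10) {
    cfg <- unetConfig(nLevels = sample(2:3, 1), baseChannels = sample(1:6, 1),
                      inChannels = sample(1:3, 1), outChannels = sample(1:3, 1))
    net <- buildUnet(cfg, seed = i)
    expect_equal(networkParameterCount(net), countParameters(cfg))
    expect_equal(countParameters(cfg),
                 oracleParamCount(cfg$nLevels, cfg$baseChannels,
                                  cfg$inChannels, cfg$outChannels))
  }
})

test_that("the convolution kernel matches a direct index-loop oracle", {
  set.seed(30)
  arr <- array(rnorm(7 * 6 * 5), c(7, 6, 5))
  w <- array(rnorm(27), c(3, 3, 3))
  # single-channel conv through the package kernel
  W <- matrix(as.numeric(w), 27, 1)  # dx fastest, matching the layout
  out <- fetseg:::cpp_conv3d_fwd(as.numeric(arr), c(7L, 6L, 5L, 1L), W, 0, 3L)
  expect_equal(array(out, c(7, 6, 5)), oracleConv3(arr, w), tolerance = 1e-12)
  # two input channels superpose linearly
  arr2 <- array(rnorm(7 * 6 * 5), c(7, 6, 5))
  w2 <- array(rnorm(27), c(3, 3, 3))
  W2 <- matrix(c(as.numeric(w), as.numeric(w2)), 54, 1)
  x2 <- c(as.numeric(arr), as.numeric(arr2))
  out2 <- fetseg:::cpp_conv3d_fwd(x2, c(7L, 6L, 5L, 2L), W2, 0.5, 3L)
  expect_equal(array(out2, c(7, 6, 5)),
               oracleConv3(arr, w) + oracleConv3(arr2, w2) + 0.5,
               tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences in every layer", {
  cfg <- unetConfig(nLevels = 2, baseChannels = 2)
  net <- buildUnet(cfg, seed = 2)
  set.seed(31)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  y <- array(0, c(8, 8, 4)); y[3:5, 3:5, 2:3] <- 1
  fw <- fetseg:::unetForward(net, x, cache = TRUE)
  dprob <- fetseg:::diceLossGrad(fw$prob, array(y, c(8, 8, 4, 1)))
  g <- fetseg:::unetBackward(net, fw$cache, dprob * fw$prob * (1 - fw$prob))
  eps <- 1e-6
  for (nm in names(net@weights)) {
    i <- sample(length(net@weights[[nm]]$W), 1)
    up <- net; up@weights[[nm]]$W[i] <- up@weights[[nm]]$W[i] + eps
    dn <- net; dn@weights[[nm]]$W[i] <- dn@weights[[nm]]$W[i] - eps
    fd <- (diceLoss(fetseg:::unetForward(up, x)$prob, y) -
             diceLoss(fetseg:::unetForward(dn, x)$prob, y)) / (2 * eps)
    expect_equal(g[[nm]]$dW[i], fd, tolerance = 1e-4)
  }
})

test_that("soft Dice loss reproduces hand-computed values and bounds", {
  d <- c(6, 6, 6)
  t <- array(rbinom(prod(d), 1, 0.5), d)
  expect_equal(diceLoss(t, t), -1, tolerance = 1e-5)
  expect_equal(diceLoss(1 - t, t), 0, tolerance = 1e-5)
  half <- array(0, d); half[1:3, , ] <- 1  # |T| = half the voxels
  p <- array(0.5, d)
  expect_equal(diceLoss(p, half), -0.5, tolerance = 1e-5)
  # in range and equal to -dsc for binary inputs at smooth = 0
  set.seed(40)
  for (i in 1:5) {
    pr <- array(runif(prod(d)), d)
    tr <- array(rbinom(prod(d), 1, 0.3), d)
    l <- diceLoss(pr, tr)
    expect_gte(l, -1); expect_lte(l, 0)
    pb <- (pr >= 0.5) * 1
    expect_equal(diceLoss(pb, tr, smooth = 0),
                 -dsc(brainMask(pb), brainMask(tr)))
  }
  expect_error(diceLoss(array(0.5, c(4, 4, 4)), array(1, c(4, 4, 2))),
               "shapes")
})

test_that("training reduces the loss on a single subject and is reproducible", {
  pair <- tinyTrainingPair(1)
  net <- buildUnet(unetConfig(), seed = 3)
  nonInc <- 0
  for (seed in 1:10) {
    fit <- trainUnet(net, list(pair), cfg = trainConfig(maxEpochs = 2,
                                                        seed = seed))
    if (fit$history$trainLoss[2] <= fit$history$trainLoss[1])
      nonInc <- nonInc + 1
  }
  expect_gte(nonInc, 8)
  # exact reproducibility for a fixed seed
  f1 <- trainUnet(net, list(pair), cfg = trainConfig(maxEpochs = 1, seed = 5))
  f2 <- trainUnet(net, list(pair), cfg = trainConfig(maxEpochs = 1, seed = 5))
  expect_equal(f1$history$trainLoss, f2$history$trainLoss, tolerance = 1e-6)
  expect_identical(f1$net@weights, f2$net@weights)
})

test_that("zero-epoch training is a no-op and empty training sets error", {
  net <- buildUnet(unetConfig(nLevels = 2, baseChannels = 2), seed = 1)
  fit <- trainUnet(net, list(tinyTrainingPair(2)),
                   cfg = trainConfig(maxEpochs = 0))
  expect_identical(fit$net@weights, net@weights)
  expect_equal(nrow(fit$history), 0)
  expect_error(trainUnet(net, list(), cfg = trainConfig(maxEpochs = 1)),
               "empty")
})

test_that("prediction thresholds behave at the degenerate ends", {
  cfg <- unetConfig(nLevels = 2, baseChannels = 2)
  net <- buildUnet(cfg, seed = 4)
  v <- brainVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  p0 <- predictMask(net, v, probThreshold = 0)
  expect_equal(sum(voxelData(p0$mask)), prod(dim(v)))
  # zero final layer: sigmoid(0) = 0.5 everywhere, kept by the >= rule
  net0 <- net
  net0@weights$final$W[] <- 0
  net0@weights$final$b[] <- 0
  p5 <- predictMask(net0, v, probThreshold = 0.5)
  expect_true(all(voxelData(p5$prob) == 0.5))
  expect_equal(sum(voxelData(p5$mask)), prod(dim(v)))
  expect_error(predictMask(net, brainVolume(array(0, c(7, 8, 4)))),
               "divisible")
})

test_that("a trained network round-trips through its checkpoint", {
  dirp <- withr::local_tempdir()
  net <- buildUnet(unetConfig(nLevels = 2, baseChannels = 3), seed = 9)
  saveUnet(net, file.path(dirp, "model"))
  back <- loadUnet(file.path(dirp, "model"))
  expect_identical(back@weights, net@weights)
  expect_equal(back@config$baseChannels, 3)
  side <- jsonlite::read_json(file.path(dirp, "model", "model.json"))
  expect_equal(side$nParameters, networkParameterCount(net))
})
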