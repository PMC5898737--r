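test_that("gradient magnitude matches the finite-difference definition", {
  cv <- brainVolume(array(4, c(6, 6, 6)))
  expect_equal(voxelData(gradientMagnitude(cv)), array(0, c(6, 6, 6)))
  # linear ramp I = 3x: interior gradient exactly 3
  d <- c(8, 6, 6)
  ramp <- brainVolume(array(rep(3 * seq_len(d[1]), times = d[2] * d[3]), d))
  g <- voxelData(gradientMagnitude(ramp))
  expect_equal(g[2:7, , ], array(3, c(6, 6, 6)))
  # random volume against the index-loop oracle
  set.seed(11)
  arr <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  expect_equal(voxelData(gradientMagnitude(brainVolume(arr))),
               oracleGradMag(arr), tolerance = 1e-6)
})

test_that("contour enhancement adds the gradient and preserves constants", {
  cv <- brainVolume(array(2.5, c(5, 5, 5)))
  expect_equal(voxelData(enhanceContours(cv)), voxelData(cv))
  # step edge of height h: central difference elevates edge voxels by h/2
  d <- c(10, 4, 4)
  h <- 3
  step <- array(rep(c(rep(0, 5), rep(h, 5)), times = 16), d)
  out <- voxelData(enhanceContours(brainVolume(step)))
  expect_equal(out[5, 1, 1], 0 + h / 2)
  expect_equal(out[6, 1, 1], h + h / 2)
  expect_equal(out[3, 1, 1], 0)
  set.seed(4)
  v <- brainVolume(array(rnorm(216), c(6, 6, 6)))
  expect_true(all(voxelData(enhanceContours(v)) >= voxelData(v)))
})

test_that("z-normalization yields mean 0, sd 1 and is idempotent", {
  set.seed(8)
  v <- brainVolume(array(rnorm(512, 5, 2), c(8, 8, 8)))
  z <- zNormalize(v)
  expect_lt(abs(mean(voxelData(z))), 1e-6)
  expect_lt(abs(sd(voxelData(z)) - 1), 1e-6)
  expect_equal(voxelData(zNormalize(z)), voxelData(z), tolerance = 1e-6)
  expect_error(zNormalize(brainVolume(array(1, c(4, 4, 4)))), "constant")
})

test_that("identity-valued augmentation returns the input unchanged", {
  set.seed(2)
  d <- c(12, 12, 8)
  v <- brainVolume(array(rnorm(prod(d)), d))
  m <- brainMask(array(rbinom(prod(d), 1, 0.2), d))
  idp <- augmentParams(rotationDeg = c(0, 0), translationFrac = c(0, 0),
                       shearDeg = c(0, 0), zoom = c(1, 1))
  out <- augmentPair(v, m, idp, seed = 99)
  expect_equal(voxelData(out$volume), voxelData(v), tolerance = 1e-12)
  expect_equal(voxelData(out$mask), voxelData(m))
})

test_that("augmentation keeps masks binary and moves a delta by the set translation", {
  set.seed(3)
  d <- c(20, 20, 8)
  v <- brainVolume(array(rnorm(prod(d)), d))
  m <- brainMask(array(rbinom(prod(d), 1, 0.3), d))
  out <- augmentPair(v, m, augmentParams(), seed = 7)
  expect_true(all(voxelData(out$mask) %in% c(0, 1)))
  expect_equal(dim(out$volume), d)
  # pure +0.1 translation on a 20-voxel axis displaces the peak by 2
  delta <- array(0, d); delta[10, 10, 4] <- 1
  trp <- augmentParams(rotationDeg = c(0, 0), translationFrac = c(0.1, 0.1),
                       shearDeg = c(0, 0), zoom = c(1, 1))
  outd <- augmentPair(brainVolume(delta), brainMask(delta), trp, seed = 1)
  peak <- which(voxelData(outd$volume) == max(voxelData(outd$volume)),
                arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(12, 12, 4 + round(0.1 * 8)))
})

test_that("zoom-only augmentation scales mask volume like zoom^3", {
  d <- c(32, 32, 32)
  co <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  m <- array(as.numeric((co$x - 16.5)^2 + (co$y - 16.5)^2 +
                          (co$z - 16.5)^2 <= 10^2), d)
  v <- brainVolume(array(1, d) + m)
  for (z in c(0.85, 1.15)) {
    zp <- augmentParams(rotationDeg = c(0, 0), translationFrac = c(0, 0),
                        shearDeg = c(0, 0), zoom = c(z, z))
    out <- augmentPair(v, brainMask(m), zp, seed = 5)
    ratio <- sum(voxelData(out$mask)) / sum(m)
    expect_lt(abs(ratio - z^3) / z^3, 0.15)
  }
})

test_that("the 70/30 split reproduces the cohort sizes and is exchangeable", {
  s <- splitDataset(1:37, 0.70, seed = 1)
  expect_length(s$trainIds, 26)
  expect_length(s$valIds, 11)
  expect_setequal(c(s$trainIds, s$valIds), 1:37)
  expect_identical(splitDataset(1:37, 0.70, seed = 1), s)
  expect_length(splitDataset(1:10, 0.70, seed = 2)$trainIds, 7)
  expect_error(splitDataset(1:2, 0.2, seed = 1), "degenerate")
  # exchangeability: each id lands in train at about the set fraction
  hits <- rowSums(vapply(1:200, function(sd)
    1:10 %in% splitDataset(1:10, 0.7, seed = sd)$trainIds, logical(10)))
  expect_true(all(abs(hits / 200 - 0.7) <= 0.1))
})
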