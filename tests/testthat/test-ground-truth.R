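test_that("manual region emulation dilates by a Euclidean ball", {
  m <- brainMask(array(0, c(9, 9, 9)))
  m@data[5, 5, 5] <- 1
  expect_equal(voxelData(makeManualRegion(m, 0)), voxelData(m))
  # margin 2 mm at 2 mm spacing: the 7-voxel face-connected cross
  out <- makeManualRegion(m, 2)
  expect_equal(sum(voxelData(out)), 7)
  idx <- which(voxelData(out) > 0, arr.ind = TRUE)
  d2 <- colSums((t(idx) - c(5, 5, 5))^2) * 4
  expect_true(all(d2 <= 4))
  # matches the brute-force within-distance count
  expect_equal(sum(voxelData(makeManualRegion(m, 5))),
               oracleBallCount(c(9, 9, 9), c(2, 2, 2), c(5, 5, 5), 5))
  # superset property on an arbitrary lesion
  set.seed(2)
  m2 <- brainMask(array(rbinom(9^3, 1, 0.1), c(9, 9, 9)))
  out2 <- makeManualRegion(m2, 4)
  expect_true(all(voxelData(out2)[voxelData(m2) > 0] == 1))
  expect_error(makeManualRegion(brainMask(array(0, c(4, 4, 4))), 2), "empty")
})

test_that("the 10 cm3 background sphere has the right voxel count and mean", {
  v <- brainVolume(array(2.5, c(41, 49, 41)))  # constant: support everywhere
  bs <- backgroundSphere(v, lesionSide = "left", voiVolumeCm3 = 10)
  nv <- sum(voxelData(bs$mask))
  expect_lt(abs(nv - 1250) / 1250, 0.05)       # 10,000 mm3 / 8 mm3 per voxel
  expect_equal(bs$backgroundMean, 2.5)
  # entirely contralateral (right = upper indices of the LR axis)
  idx <- which(voxelData(bs$mask) > 0, arr.ind = TRUE)
  expect_true(all(idx[, 1] > 21))
  # brute-force voxel count at the same centre agrees
  cen <- colMeans(idx)
  rMm <- (3 * 10 * 1000 / (4 * pi))^(1 / 3)
  expect_equal(nv, oracleBallCount(c(41, 49, 41), c(2, 2, 2), cen, rMm))
})

test_that("sphere mean is invariant to mirroring the volume with side swap", {
  s <- generateSubject(testSpec(), seed = 8)
  a <- backgroundSphere(s@summation, s@lesionSide)
  flipSide <- if (s@lesionSide == "left") "right" else "left"
  b <- backgroundSphere(mirrorSagittal(s@summation), flipSide)
  expect_equal(a$backgroundMean, b$backgroundMean, tolerance = 1e-12)
})

test_that("threshold segmentation keeps manual-region voxels above factor x background", {
  d <- c(21, 21, 21)
  vol <- array(1, d)
  lesion <- array(0, d); lesion[8:12, 8:12, 8:12] <- 1
  vol[lesion > 0] <- 2  # uniform lesion at 2x background
  v <- brainVolume(vol)
  manual <- makeManualRegion(brainMask(lesion), 6)
  t13 <- semiAutoSegment(v, manual, backgroundMean = 1, factor = 1.3)
  expect_equal(voxelData(t13), lesion)
  expect_false(t13@metadata$belowThreshold)
  # empty manual region -> empty result, flagged rather than an error
  t0 <- semiAutoSegment(v, brainMask(array(0, d)), 1, 1.3)
  expect_equal(sum(voxelData(t0)), 0)
  expect_true(t0@metadata$belowThreshold)
  # factor -> 0 recovers manual region intersected with positive activity
  vol2 <- vol; vol2[1:3, , ] <- 0
  tEps <- semiAutoSegment(brainVolume(vol2), manual, 1, factor = 1e-9)
  expect_equal(voxelData(tEps), (voxelData(manual) > 0 & vol2 > 0) * 1)
})

test_that("reference segmentation is anti-monotone in the threshold factor", {
  s <- generateSubject(testSpec(), seed = 12)
  manual <- makeManualRegion(s@truthLesion, 10)
  bg <- backgroundSphere(s@summation, s@lesionSide)
  sizes <- vapply(c(0.8, 1.0, 1.3, 1.6, 2.0), function(f)
    sum(voxelData(semiAutoSegment(s@summation, manual, bg$backgroundMean, f))),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # T is always inside the manual region
  t13 <- semiAutoSegment(s@summation, manual, bg$backgroundMean, 1.3)
  expect_true(all(voxelData(manual)[voxelData(t13) > 0] == 1))
})

test_that("semi-automatic reference overlaps the simulated lesion", {
  dices <- vapply(1:5, function(seed) {
    s <- generateSubject(testSpec(), seed = seed)
    gt <- groundTruthSegment(s)
    dsc(gt$mask, s@truthLesion)
  }, numeric(1))
  expect_true(all(dices >= 0.5))
})
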