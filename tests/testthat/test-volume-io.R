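test_that("NIfTI round trip preserves data and spacing for 3D and 4D", {
  dirp <- withr::local_tempdir()
  v <- brainVolume(array(7, c(4, 4, 4)))
  f <- file.path(dirp, "const.nii.gz")
  writeVolume(v, f)
  r <- readVolume(f)
  expect_equal(voxelData(r), voxelData(v))
  expect_equal(spacing(r), spacing(v))

  set.seed(42)
  v2 <- brainVolume(array(rnorm(512), c(8, 8, 8)), spacing = c(1.5, 2, 2.5))
  f2 <- file.path(dirp, "rand.nii.gz")
  writeVolume(v2, f2)
  r2 <- readVolume(f2)
  expect_equal(max(abs(voxelData(r2) - voxelData(v2))), 0)
  expect_equal(spacing(r2), c(1.5, 2, 2.5))

  frames <- lapply(1:10, function(i) brainVolume(array(i, c(4, 4, 4))))
  s <- dynamicSeries(frames, frameDurationMin = 5)
  f3 <- file.path(dirp, "dyn.nii.gz")
  writeVolume(s, f3)
  r3 <- readVolume(f3)
  expect_s4_class(r3, "DynamicSeries")
  expect_equal(nFrames(r3), 10)
  expect_equal(voxelData(r3@frames[[3]]), voxelData(frames[[3]]))
})

test_that("masks round trip as binary uint8 and bad inputs error", {
  dirp <- withr::local_tempdir()
  m <- brainMask(array(c(1, 0), c(4, 4, 4)))
  f <- file.path(dirp, "mask.nii.gz")
  writeVolume(m, f)
  r <- readVolume(f)
  expect_true(all(voxelData(r) %in% c(0, 1)))
  expect_equal(voxelData(r), voxelData(m))

  expect_error(writeVolume(m, file.path(dirp, "nope", "m.nii.gz")),
               "directory")
  img2d <- RNifti::asNifti(matrix(1, 5, 5))
  f2 <- file.path(dirp, "twod.nii.gz")
  RNifti::writeNifti(img2d, f2)
  expect_error(readVolume(f2), "3D or 4D")
  expect_error(readVolume(file.path(dirp, "missing.nii")), "not found")
})

test_that("resizeLinear is exact on identity and constant volumes", {
  set.seed(1)
  v <- brainVolume(array(rnorm(8 * 6 * 4), c(8, 6, 4)))
  expect_equal(voxelData(resizeLinear(v, c(8, 6, 4))), voxelData(v))
  cv <- brainVolume(array(3.7, c(9, 7, 5)))
  out <- resizeLinear(cv, c(5, 11, 3))
  expect_equal(voxelData(out), array(3.7, c(5, 11, 3)))
  expect_error(resizeLinear(v, c(0, 4, 4)), "targetShape")
})

test_that("resizeLinear matches a brute-force trilinear sampler and keeps physical extent", {
  set.seed(7)
  arr <- array(rnorm(9 * 7 * 5), c(9, 7, 5))
  v <- brainVolume(arr, spacing = c(2, 2, 2))
  out <- resizeLinear(v, c(5, 4, 3))
  expect_equal(voxelData(out), oracleTrilinear(arr, c(5, 4, 3)),
               tolerance = 1e-12)
  expect_equal(spacing(out) * c(5, 4, 3), c(2, 2, 2) * c(9, 7, 5))
})

test_that("resizing the MNI-like ramp to network space preserves the mean within 1%", {
  d <- c(91, 109, 91)
  ramp <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  v <- brainVolume(ramp)
  out <- resizeLinear(v, c(64, 64, 40))
  expect_lt(abs(mean(voxelData(out)) - mean(ramp)) / mean(ramp), 0.01)
})

test_that("mask resize is nearest-neighbour and strictly binary", {
  set.seed(3)
  m <- brainMask(array(rbinom(9 * 7 * 5, 1, 0.4), c(9, 7, 5)))
  out <- resizeLinear(m, c(6, 5, 4))
  expect_s4_class(out, "BrainMask")
  expect_true(all(voxelData(out) %in% c(0, 1)))
  # upsampling a mask back to the same grid is the identity
  expect_equal(voxelData(resizeLinear(m, c(9, 7, 5))), voxelData(m))
})

test_that("sumFrames selects whole frames in a half-open window", {
  frames <- lapply(1:10, function(i) brainVolume(array(1, c(4, 4, 4))))
  s <- dynamicSeries(frames)
  expect_equal(voxelData(sumFrames(s, 20, 40)), array(4, c(4, 4, 4)))
  allsum <- Reduce(`+`, lapply(frames, voxelData))
  expect_equal(voxelData(sumFrames(s, 0, 50)), allsum)
  expect_error(sumFrames(s, 20, 33), "aligned")
  expect_error(sumFrames(s, 30, 30), "window")
  # additivity over adjoining windows
  set.seed(5)
  frames2 <- lapply(1:10, function(i)
    brainVolume(array(rnorm(64), c(4, 4, 4))))
  s2 <- dynamicSeries(frames2)
  expect_equal(voxelData(sumFrames(s2, 0, 50)),
               voxelData(sumFrames(s2, 0, 20)) + voxelData(sumFrames(s2, 20, 50)))
})

test_that("mirrorSagittal reflects about the grid midline and is an involution", {
  set.seed(9)
  v <- brainVolume(array(rnorm(7 * 5 * 3), c(7, 5, 3)))
  expect_equal(voxelData(mirrorSagittal(mirrorSagittal(v))), voxelData(v))
  m <- brainMask(array(0, c(6, 4, 4)))
  m@data[2, 3, 1] <- 1
  mm <- mirrorSagittal(m)
  expect_equal(unname(which(voxelData(mm) > 0, arr.ind = TRUE)[1, ]),
               c(5, 3, 1))  # i -> n + 1 - i (1-based)
  expect_equal(sum(voxelData(mm)), sum(voxelData(m)))
})
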