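# The validation-cohort confusion matrix reported for this procedure, in
# the text-consistent orientation.
refCounts <- structure(list(TP = 10478, FP = 3025, FN = 1426, TN = 1787261),
                       class = "confusionCounts")

test_that("Dice handles identity, disjoint and pooled-count cases", {
  d <- c(6, 6, 6)
  a <- array(0, d); a[1:3, , ] <- 1
  b <- array(0, d); b[4:6, , ] <- 1
  expect_equal(dsc(brainMask(a), brainMask(a)), 1)
  expect_equal(dsc(brainMask(a), brainMask(b)), 0)
  expect_equal(dsc(brainMask(array(0, d)), brainMask(array(0, d))), 1)
  # pooled Dice from the reported confusion counts
  pooled <- with(refCounts, 2 * TP / (2 * TP + FP + FN))
  expect_equal(round(pooled, 4), 0.8248)
  expect_error(dsc(brainMask(a), brainMask(array(0, c(6, 6, 2)))), "shapes")
})

test_that("confusion counts match a per-voxel tally and the Dice identity", {
  d <- c(10, 10, 10)
  set.seed(50)
  p <- array(rbinom(prod(d), 1, 0.3), d)
  t <- array(rbinom(prod(d), 1, 0.3), d)
  cc <- confusionCounts(brainMask(p), brainMask(t))
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")],
               oracleConfusion(p, t)[c("TP", "FP", "FN", "TN")])
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, prod(d))
  expect_equal(dsc(brainMask(p), brainMask(t)),
               2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN))
  # P = T and P = complement(T)
  ccEq <- confusionCounts(brainMask(t), brainMask(t))
  expect_equal(ccEq$FP + ccEq$FN, 0)
  ccC <- confusionCounts(brainMask(1 - t), brainMask(t))
  expect_equal(ccC$TP + ccC$TN, 0)
})

test_that("voxel metrics reproduce the reported study values with Wald intervals", {
  vm <- voxelMetrics(refCounts)
  expect_equal(round(vm$Se, 2), 0.88)
  expect_equal(round(vm$PPV, 2), 0.78)
  # specificity and NPV were printed truncated (0.998, 0.999 -> "0.99")
  expect_equal(trunc(100 * vm$Sp) / 100, 0.99)
  expect_equal(trunc(100 * vm$NPV) / 100, 0.99)
  expect_equal(round(vm$ci95$PPV, 3), c(0.769, 0.783))
  # degenerate perfect classifier: everything 1, intervals clipped
  one <- voxelMetrics(structure(list(TP = 1, FP = 0, FN = 0, TN = 1),
                                class = "confusionCounts"))
  expect_equal(c(one$Se, one$Sp, one$PPV, one$NPV), rep(1, 4))
  expect_true(all(vapply(one$ci95, function(ci) all(ci >= 0 & ci <= 1),
                         logical(1))))
  # exchanging P and T swaps Se<->PPV and Sp<->NPV
  set.seed(51)
  p <- array(rbinom(512, 1, 0.4), c(8, 8, 8))
  t <- array(rbinom(512, 1, 0.4), c(8, 8, 8))
  m1 <- voxelMetrics(confusionCounts(brainMask(p), brainMask(t)))
  m2 <- voxelMetrics(confusionCounts(brainMask(t), brainMask(p)))
  expect_equal(m1$Se, m2$PPV)
  expect_equal(m1$Sp, m2$NPV)
  # zero denominators flag the metric without failing the others
  und <- voxelMetrics(structure(list(TP = 0, FP = 0, FN = 0, TN = 10),
                                class = "confusionCounts"))
  expect_true(all(c("Se", "PPV") %in% und$undefined))
  expect_equal(und$Sp, 1)
})

test_that("metrics are invariant under simultaneous sagittal mirroring", {
  set.seed(52)
  p <- brainMask(array(rbinom(512, 1, 0.3), c(8, 8, 8)))
  t <- brainMask(array(rbinom(512, 1, 0.3), c(8, 8, 8)))
  expect_equal(dsc(p, t), dsc(mirrorSagittal(p), mirrorSagittal(t)))
  expect_equal(unclass(confusionCounts(p, t)),
               unclass(confusionCounts(mirrorSagittal(p), mirrorSagittal(t))))
  expect_equal(dsc(p, t), dsc(t, p))
})

test_that("lesion detection counts components and false positives", {
  d <- c(16, 16, 16)
  lesion <- array(0, d); lesion[4:7, 4:7, 4:7] <- 1
  T1 <- brainMask(lesion)
  expect_equal(detectLesions(brainMask(lesion), list(T1))$nDetected, 1)
  expect_equal(detectLesions(brainMask(lesion), list(T1))$nFalsePositiveComponents, 0)
  miss <- detectLesions(brainMask(array(0, d)), list(T1))
  expect_equal(miss$nDetected, 0)
  expect_equal(miss$nLesions, 1)
  # lesion plus one distant 8-voxel blob: 1 detected, 1 false positive
  p <- lesion; p[12:13, 12:13, 12:13] <- 1
  det <- detectLesions(brainMask(p), list(T1))
  expect_equal(det$nDetected, 1)
  expect_equal(det$nFalsePositiveComponents, 1)
  expect_equal(det$detectionSensitivity, 1)
  # component labelling agrees with a flood-fill oracle
  set.seed(53)
  r <- array(rbinom(12^3, 1, 0.06), c(12, 12, 12))
  lab <- fetseg:::cpp_label26(as.integer(r), dim(r))
  expect_equal(max(lab), oracleComponentCount(r))
})
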