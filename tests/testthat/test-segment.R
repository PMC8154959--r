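test_that("labeling agrees with the flood-fill oracle on all 3x3 masks", {
  for (code in 0:511) {
    m <- matrix(as.integer(intToBits(code)[1:9]), 3, 3)
    for (conn in c(8, 4)) {
      got <- labelComponents(m, conn)
      ref <- floodFillLabels(m, conn)
      expect_equal(got@nComponents, max(ref))
      expect_identical(canonicalPartition(got@pixels),
                       canonicalPartition(ref))
      expect_equal(sum(got@areas), sum(m))
    }
  }
})

test_that("labeling agrees with the oracle on 1000 random 8x8 masks", {
  set.seed(2024)
  for (i in 1:1000) {
    m <- matrix(rbinom(64, 1, runif(1, 0.2, 0.8)), 8, 8)
    got <- labelComponents(m, 8)
    ref <- floodFillLabels(m, 8)
    expect_equal(got@nComponents, max(ref))
    expect_identical(canonicalPartition(got@pixels), canonicalPartition(ref))
  }
})

test_that("diagonal adjacency joins under 8- but not 4-connectivity", {
  m <- matrix(0L, 4, 4); m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_equal(labelComponents(m, 8)@nComponents, 1L)
  expect_equal(labelComponents(m, 4)@nComponents, 2L)
  # checkerboard corners + center are one 8-connected component
  cb <- matrix(0L, 3, 3); cb[c(1, 3, 5, 7, 9)] <- 1L
  expect_equal(labelComponents(cb, 8)@nComponents, 1L)
  # empty mask
  expect_equal(labelComponents(matrix(0L, 5, 5))@nComponents, 0L)
})

test_that("largest component is selected by area with scan-order tie-break", {
  m <- matrix(0L, 12, 30)
  m[2:6, 2:9] <- 1L        # 40 px
  m[9:11, 12:14] <- 1L     # 9 px
  m[2, 25] <- 1L           # 1 px
  cm <- largestComponent(labelComponents(m), minAreaPx = 1)
  expect_equal(areaPx(cm), 40)
  expect_false(isDegenerate(cm))
  expect_equal(labelComponents(cm@pixels)@nComponents, 1L)
  expect_equal(areaUm2(new("CavityMask", pixels = cm@pixels, index = 1L,
                           pixelSize = 2.5, degenerate = FALSE)),
               40 * 2.5^2)
  # single component is returned unchanged
  single <- matrix(0L, 5, 5); single[2:4, 2:4] <- 1L
  expect_identical(largestComponent(labelComponents(single),
                                    minAreaPx = 1)@pixels, single)
  # tie: two 10-px components; winner holds the scan-order-first pixel
  tie <- matrix(0L, 10, 10)
  tie[6:7, 1:5] <- 1L           # first pixel (6, 1)
  tie[1:2, 6:10] <- 1L          # first pixel (1, 6): earlier in (row, col)
  win <- largestComponent(labelComponents(tie), minAreaPx = 1)
  expect_equal(areaPx(win), 10)
  expect_equal(win@pixels[1, 6], 1L)
  expect_equal(win@pixels[6, 1], 0L)
})

test_that("selection is invariant to label renumbering", {
  set.seed(5)
  m <- matrix(rbinom(200, 1, 0.35), 10, 20)
  lm <- labelComponents(m)
  a <- largestComponent(lm, minAreaPx = 1)
  # renumber labels in reverse
  perm <- rev(seq_len(lm@nComponents))
  px <- lm@pixels
  px[px > 0] <- perm[px[px > 0]]
  lm2 <- new("LabelMap", pixels = px, nComponents = lm@nComponents,
             areas = lm@areas[order(perm)])
  b <- largestComponent(lm2, minAreaPx = 1)
  expect_identical(a@pixels, b@pixels)
  expect_equal(areaPx(a), max(lm@areas))
})

test_that("empty and sub-floor components yield degenerate masks", {
  empty <- largestComponent(labelComponents(matrix(0L, 6, 6)))
  expect_true(isDegenerate(empty))
  expect_equal(areaPx(empty), 0)
  expect_true(all(is.na(maskCentroid(empty))))
  speck <- matrix(0L, 20, 20); speck[3:4, 3:4] <- 1L
  expect_true(isDegenerate(largestComponent(labelComponents(speck),
                                            minAreaPx = 64)))
})

test_that("segmentSlice is deterministic and handles all-tissue slices", {
  spec <- embryoPreset("pre-elevation", sizeFactor = 0.25, seed = 5)
  spec <- phantomSpec(spec@imageSize, spec@nSlices, spec@pixelSize,
                      spec@thickness, spec@shapes, noiseSd = 0,
                      jitterSd = c(0, 0), seed = 5L)
  truth <- buildTruth(spec)
  stack <- renderStack(truth, spec)
  k <- spec@nSlices %/% 2
  m1 <- segmentSlice(getSlice(stack, k), pixelSize = pixelSize(stack))
  m2 <- segmentSlice(getSlice(stack, k), pixelSize = pixelSize(stack))
  expect_identical(m1@pixels, m2@pixels)
  # noiseless, jitterless: silhouette recovered essentially exactly
  sil <- matrix(as.integer(truth@volume@voxels[, , k] > 0),
                dim(truth@volume@voxels)[1])
  expect_gte(diceCoefficient(m1@pixels, sil), 0.99)
  # an all-tissue (dark) slice is degenerate, not an error
  dark <- array(as.integer(0.2 * 255), c(40, 60, 3))
  expect_true(isDegenerate(segmentSlice(dark)))
})

test_that("segmentation holds Dice >= 0.95 across 20 noisy seeded renders", {
  dice <- vapply(1:20, function(seed) {
    spec <- embryoPreset("elevating", sizeFactor = 0.08, seed = seed)
    truth <- buildTruth(spec)
    stack <- renderStack(truth, spec)
    k <- spec@nSlices %/% 2
    m <- segmentSlice(getSlice(stack, k), pixelSize = pixelSize(stack))
    sil <- matrix(as.integer(truth@volume@voxels[, , k] > 0),
                  dim(truth@volume@voxels)[1])
    silJ <- applyRigid(sil, truth@jitters[[k]])
    diceCoefficient(m@pixels, silJ)
  }, numeric(1))
  expect_true(all(dice >= 0.95))
})

test_that("the QC table reports area, centroid and degeneracy per slice", {
  good <- matrix(0L, 20, 20); good[5:14, 5:14] <- 1L
  masks <- list(asMask(good, 1L, 2), asMask(matrix(0L, 20, 20), 2L, 2))
  qc <- maskQC(masks)
  expect_equal(qc$index, 1:2)
  expect_equal(qc$area_px, c(100, 0))
  expect_equal(qc$centroid_row[1], 9.5)
  expect_equal(qc$degenerate, c(FALSE, TRUE))
})
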