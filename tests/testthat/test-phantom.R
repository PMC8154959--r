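test_that("ground-truth voxelization matches closed-form shape volumes", {
  # ellipsoid within 3% of 4/3 pi abc at 1 um sampling
  spec <- phantomSpec(imageSize = c(110, 70), nSlices = 44, pixelSize = 1,
                      thickness = 1, jitterSd = c(0, 0), noiseSd = 0,
                      shapes = list(ellipsoidShape(1L, "ell", c(55, 35, 22),
                                                   c(50, 30, 20))))
  truth <- buildTruth(spec)
  analytic <- 4 / 3 * pi * 50 * 30 * 20
  expect_equal(truth@volumesUm3[["ell"]], analytic)
  voxel <- measureVolume(truth@volume, 1L)
  expect_lt(abs(voxel - analytic) / analytic, 0.03)
  # extruded box: exact prism volume
  spec2 <- phantomSpec(imageSize = c(40, 40), nSlices = 10, pixelSize = 1,
                       thickness = 1, jitterSd = c(0, 0), noiseSd = 0,
                       shapes = list(boxShape(1L, "box", c(10, 20),
                                              c(10, 30), c(2, 8))))
  expect_equal(buildTruth(spec2)@volumesUm3[["box"]], 10 * 20 * 6)
})

test_that("two disjoint cubes give two labels with equal counts", {
  spec <- phantomSpec(imageSize = c(60, 60), nSlices = 12, pixelSize = 1,
                      thickness = 1, jitterSd = c(0, 0), noiseSd = 0,
                      shapes = list(
                        boxShape(1L, "a", c(20, 25), c(20, 25), c(3, 8)),
                        boxShape(2L, "b", c(35, 40), c(35, 40), c(3, 8))))
  vol <- buildTruth(spec)@volume
  expect_equal(sort(unique(as.integer(vol@voxels))), c(0L, 1L, 2L))
  expect_equal(sum(vol@voxels == 1L), sum(vol@voxels == 2L))
})

test_that("overlapping shapes: the later shape overwrites the earlier", {
  spec <- phantomSpec(imageSize = c(40, 40), nSlices = 8, pixelSize = 1,
                      thickness = 1, jitterSd = c(0, 0), noiseSd = 0,
                      shapes = list(
                        boxShape(1L, "under", c(10, 25), c(10, 25), c(1, 7)),
                        boxShape(2L, "over", c(18, 30), c(18, 30), c(1, 7))))
  vox <- buildTruth(spec)@volume@voxels
  expect_equal(unique(as.integer(vox[19:25, 19:25, 3])), 2L)
  expect_equal(unique(as.integer(vox[11:17, 11:17, 3])), 1L)
})

test_that("a shape that can leave the frame under jitter is rejected", {
  expect_error(
    phantomSpec(imageSize = c(40, 40), nSlices = 8, pixelSize = 1,
                thickness = 1, jitterSd = c(5, 3), noiseSd = 0,
                shapes = list(boxShape(1L, "edge", c(1, 10), c(1, 10),
                                       c(1, 7)))),
    "frame")
  # and the separability guarantee is enforced
  expect_error(
    phantomSpec(imageSize = c(40, 40), nSlices = 8, pixelSize = 1,
                thickness = 1, jitterSd = c(0, 0), noiseSd = 0.3,
                shapes = list()),
    "separation")
})

test_that("rendering is bit-identical for identical spec and seed", {
  spec <- embryoPreset("pre-elevation", sizeFactor = 0.08, seed = 21)
  t1 <- buildTruth(spec); s1 <- renderStack(t1, spec)
  t2 <- buildTruth(spec); s2 <- renderStack(t2, spec)
  expect_identical(t1@volume@voxels, t2@volume@voxels)
  for (i in seq_along(t1@jitters)) {
    expect_identical(t1@jitters[[i]]@theta, t2@jitters[[i]]@theta)
    expect_identical(t1@jitters[[i]]@tRow, t2@jitters[[i]]@tRow)
  }
  for (k in seq_len(nSlices(s1)))
    expect_identical(getSlice(s1, k), getSlice(s2, k))
  # a different seed changes the render
  spec3 <- embryoPreset("pre-elevation", sizeFactor = 0.08, seed = 22)
  s3 <- renderStack(buildTruth(spec3), spec3)
  expect_false(identical(getSlice(s1, 1), getSlice(s3, 1)))
})

test_that("tissue/cavity separation exceeds three noise sd by construction", {
  spec <- embryoPreset("elevating", sizeFactor = 0.08, seed = 1)
  expect_gte(spec@cavityLevel - spec@tissueLevel, 3 * spec@noiseSd)
  expect_gt(spec@cavityLevel, 0.5)
  expect_lt(spec@tissueLevel, 0.5)
})

test_that("presets define the staged anatomy", {
  pre <- embryoPreset("pre-elevation", sizeFactor = 0.1)
  expect_length(pre@shapes, 3L)
  expect_setequal(vapply(pre@shapes, function(s) s$name, character(1)),
                  c("tongue", "shelf_left", "shelf_right"))
  expect_equal(pre@thickness * pre@nSlices, 152 * 7)
  el <- embryoPreset("elevating", sizeFactor = 0.1)
  expect_equal(el@thickness * el@nSlices, 250 * 7)
  # elevating: one shelf sits markedly higher than the other
  bb <- lapply(el@shapes[2:3], palate3D:::.shapeBBox)
  heightL <- mean(bb[[1]][, 1]); heightR <- mean(bb[[2]][, 1])
  expect_gt(abs(heightL - heightR) , 200)  # um
  expect_error(embryoPreset("fused"), "arg")
})

test_that("red and blue channels never influence segmentation", {
  spec <- embryoPreset("elevating", sizeFactor = 0.08, seed = 13)
  truth <- buildTruth(spec)
  stack <- renderStack(truth, spec)
  k <- 5
  slice <- getSlice(stack, k)
  scrambled <- slice
  set.seed(1)
  scrambled[, , 1] <- sample(slice[, , 1])
  scrambled[, , 3] <- sample(slice[, , 3])
  m1 <- segmentSlice(slice, pixelSize = pixelSize(stack))
  m2 <- segmentSlice(scrambled, pixelSize = pixelSize(stack))
  expect_identical(m1@pixels, m2@pixels)
})

test_that("writePhantom emits sections plus plain-text ground truth", {
  dir <- withr::local_tempdir()
  spec <- embryoPreset("pre-elevation", sizeFactor = 0.08, seed = 2)
  out <- writePhantom(spec, dir)
  expect_true(all(file.exists(out$sections)))
  jit <- read.csv(file.path(dir, "jitters.csv"))
  expect_equal(nrow(jit), spec@nSlices)
  vols <- read.csv(file.path(dir, "volumes.csv"))
  expect_true(all(c("label", "voxels", "volume_um3") %in% names(vols)))
  # the rendered stack reloads identically
  st <- loadStack(orderStackFiles(file.path(dir, "sections")),
                  pixelSize = spec@pixelSize)
  expect_equal(nSlices(st), spec@nSlices)
  expect_identical(getSlice(st, 1),
                   getSlice(renderStack(out$truth, spec), 1))
})
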