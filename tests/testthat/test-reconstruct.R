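squareMask <- function(nr = 20, nc = 20, r = 5:14, c = 5:14, index = 1L) {
  m <- matrix(0L, nr, nc); m[r, c] <- 1L
  asMask(m, index)
}

alignedFrom <- function(masks, thickness = 7) {
  n <- length(masks)
  ok <- which(!vapply(masks, isDegenerate, logical(1)))
  ref <- ok[which.min(abs(ok - (n + 1) / 2))]
  new("AlignedStack", masks = masks,
      transforms = replicate(n, rigidTransform2D(), simplify = FALSE),
      referenceIndex = ref, thickness = thickness)
}

test_that("identical square masks assemble into a cuboid of label 1", {
  al <- alignedFrom(lapply(1:10, function(i) squareMask(index = i)),
                    thickness = 7)
  vol <- assembleVolume(al, spacing = c(2, 2, 7))
  expect_equal(dim(vol@voxels), c(20L, 20L, 10L))
  expect_equal(sum(vol@voxels == 1L), 100 * 10)
  expect_true(all(vol@voxels[5:14, 5:14, ] == 1L))
  expect_equal(measureVolume(vol, 1L), 1000 * 2 * 2 * 7)
})

test_that("degenerate slices are filled from the nearest good plane", {
  masks <- list(squareMask(index = 1L),
                asMask(matrix(0L, 20, 20), 2L),
                squareMask(r = 3:12, c = 3:12, index = 3L))
  vol <- assembleVolume(alignedFrom(masks))
  # slice 2 is a copy of a neighbor (tie goes to the earlier slice)
  expect_equal(vol@voxels[, , 2], vol@voxels[, , 1])
  allBad <- alignedFrom(list(squareMask(index = 1L),
                             asMask(matrix(0L, 20, 20), 2L)))
  allBad@masks[[1]]@degenerate <- TRUE
  allBad@masks[[1]]@pixels[] <- 0L
  expect_error(assembleVolume(allBad), "degenerate")
})

test_that("volume measurement is voxel count times anisotropic voxel volume", {
  vox <- array(0L, c(10, 10, 10)); vox[1:10, 1:10, 1:10][1:1000] <- 1L
  vol <- new("LabeledVolume", voxels = vox, spacing = c(2, 2, 7))
  expect_equal(measureVolume(vol, 1L), 1000 * 28)
  expect_equal(measureVolume(vol, 99L), 0)
})

test_that("volume is additive over labels and invariant to axis permutation", {
  set.seed(8)
  vox <- array(sample(0:3, 4 * 5 * 6, replace = TRUE), c(4, 5, 6))
  vol <- new("LabeledVolume", voxels = vox, spacing = c(1.5, 2, 7))
  total <- measureVolume(vol, 1:3)
  expect_equal(measureVolume(vol, 1L) + measureVolume(vol, 2L) +
               measureVolume(vol, 3L), total)
  # permute axes together with spacing: volumes unchanged
  pvol <- new("LabeledVolume", voxels = aperm(vox, c(3, 1, 2)),
              spacing = c(7, 1.5, 2))
  for (l in 1:3) expect_equal(measureVolume(pvol, l), measureVolume(vol, l))
  rep <- volumeReport(vol)
  expect_equal(rep$label, 1:3)
  expect_equal(sum(rep$volume_um3), total)
})

test_that("phantom ellipsoid volume matches the closed form within 3%", {
  vol <- local({
    ax <- function(n, sp) (seq_len(n) - 0.5) * sp
    g <- expand.grid(r = ax(110, 1), c = ax(70, 1), z = ax(44, 1))
    inside <- ((g$r - 55) / 50)^2 + ((g$c - 35) / 30)^2 +
      ((g$z - 22) / 20)^2 <= 1
    new("LabeledVolume", voxels = array(as.integer(inside), c(110, 70, 44)),
        spacing = c(1, 1, 1))
  })
  analytic <- 4 / 3 * pi * 50 * 30 * 20
  expect_lt(abs(measureVolume(vol, 1L) - analytic) / analytic, 0.03)
})

test_that("a single voxel yields a closed positive-volume marching-cell solid", {
  vol <- new("LabeledVolume", voxels = array(1L, c(1, 1, 1)),
             spacing = c(1, 1, 1))
  mesh <- extractSurface(vol, 1L)
  expect_true(isClosedMesh(mesh))
  v <- meshVolume(mesh)
  expect_gte(v, 0.4)
  expect_lte(v, 1.1)
})

test_that("a 10x10x10 cuboid mesh encloses within 10% of 1000 voxel volumes", {
  vox <- array(0L, c(12, 12, 12)); vox[2:11, 2:11, 2:11] <- 1L
  vol <- new("LabeledVolume", voxels = vox, spacing = c(1, 1, 1))
  mesh <- extractSurface(vol, 1L)
  expect_true(isClosedMesh(mesh))
  expect_lt(abs(meshVolume(mesh) - 1000) / 1000, 0.1)
  expect_error(extractSurface(vol, 7L), "no voxels")
})

test_that("mesh volume scales with anisotropic spacing", {
  vox <- array(0L, c(8, 8, 8)); vox[3:6, 3:6, 3:6] <- 1L
  iso <- extractSurface(new("LabeledVolume", voxels = vox,
                            spacing = c(1, 1, 1)))
  aniso <- extractSurface(new("LabeledVolume", voxels = vox,
                              spacing = c(2, 3, 7)))
  expect_equal(meshVolume(aniso), meshVolume(iso) * 2 * 3 * 7,
               tolerance = 1e-9)
})

test_that("mesh volume converges to voxel volume as resolution doubles", {
  err <- vapply(c(4, 2, 1), function(sp) {
    n <- ceiling(48 / sp)
    ax <- (seq_len(n) - 0.5) * sp
    g <- expand.grid(r = ax, c = ax, z = ax)
    inside <- (g$r - 24)^2 + (g$c - 24)^2 + (g$z - 24)^2 <= 20^2
    vol <- new("LabeledVolume", voxels = array(as.integer(inside), rep(n, 3)),
               spacing = rep(sp, 3))
    abs(meshVolume(extractSurface(vol)) - measureVolume(vol)) /
      measureVolume(vol)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("spike vertices are snapped back; clean meshes are untouched", {
  s <- uvSphere(radius = 10)
  expect_true(isClosedMesh(s))
  expect_equal(removeSpikes(s, 3)@vertices, s@vertices, tolerance = 1e-9)
  spiky <- s
  spiky@vertices[40, ] <- spiky@vertices[40, ] * 11  # 10 radii outward
  fixed <- removeSpikes(spiky, 3)
  expect_lt(abs(sqrt(sum(fixed@vertices[40, ]^2)) - 10) / 10, 0.1)
  expect_identical(fixed@faces, spiky@faces)
  tiny <- new("SurfaceMesh",
              vertices = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE),
              faces = matrix(1:3, 1), label = 1L, color = "gray")
  expect_identical(removeSpikes(tiny), tiny)
})

test_that("Taubin smoothing reduces radial noise without shrinking", {
  s <- uvSphere(radius = 10)
  expect_identical(smoothMesh(s, 0), s)
  set.seed(9)
  noisy <- s
  noisy@vertices <- noisy@vertices *
    (1 + stats::rnorm(nrow(noisy@vertices), 0, 0.05))
  rms <- function(m) {
    r <- sqrt(rowSums(m@vertices^2))
    sqrt(mean((r - 10)^2))
  }
  sm <- smoothMesh(noisy, 10)
  expect_lt(rms(sm), 0.5 * rms(noisy))
  expect_lt(abs(meshVolume(sm) - meshVolume(noisy)) / meshVolume(noisy),
            0.05)
  expect_identical(sm@faces, noisy@faces)
})

test_that("STL export writes 12 triangles for a cube and round-trips", {
  vox <- array(0L, c(3, 3, 3)); vox[2, 2, 2] <- 1L
  mesh <- uvSphere(radius = 5, nLat = 6, nLon = 8)
  dir <- withr::local_tempdir()
  # a unit cube has 12 triangles
  cube <- new("SurfaceMesh",
    vertices = as.matrix(expand.grid(0:1, 0:1, 0:1)),
    faces = matrix(as.integer(c(
      1, 3, 2, 2, 3, 4,   # z = 0
      5, 6, 7, 6, 8, 7,   # z = 1
      1, 2, 5, 2, 6, 5,   # y = 0
      3, 7, 4, 4, 7, 8,   # y = 1
      1, 5, 3, 3, 5, 7,   # x = 0
      2, 4, 6, 4, 8, 6)), ncol = 3, byrow = TRUE),
    label = 1L, color = "gray")
  expect_true(isClosedMesh(cube))
  p <- file.path(dir, "cube.stl")
  exportMesh(cube, p)
  back <- readSTL(p)
  expect_equal(nrow(back@faces), 12L)
  # general round trip: face count preserved, vertices to float32 precision
  p2 <- file.path(dir, "s.stl")
  exportMesh(mesh, p2, "stl")
  back2 <- readSTL(p2)
  expect_equal(nrow(back2@faces), nrow(mesh@faces))
  # every original vertex is reproduced to float32 precision
  nearest <- vapply(seq_len(nrow(mesh@vertices)), function(i) {
    d2 <- rowSums(sweep(back2@vertices, 2, mesh@vertices[i, ])^2)
    sqrt(min(d2))
  }, numeric(1))
  expect_lt(max(nearest), 1e-5)
})

test_that("PLY export carries the display color as vertex RGB", {
  mesh <- uvSphere(radius = 2, nLat = 4, nLon = 6)
  mesh@color <- "orange"
  dir <- withr::local_tempdir()
  p <- file.path(dir, "shelf.ply")
  exportMesh(mesh, p)
  lines <- readLines(p)
  expect_equal(lines[1], "ply")
  nv <- nrow(mesh@vertices)
  header_end <- which(lines == "end_header")
  vline <- strsplit(lines[header_end + 1], " ")[[1]]
  expect_equal(as.integer(vline[4:6]), c(255L, 165L, 0L))  # orange
  mesh@color <- "pink"
  exportMesh(mesh, p)
  vline <- strsplit(readLines(p)[header_end + 1], " ")[[1]]
  expect_equal(as.integer(vline[4:6]), c(255L, 192L, 203L))  # pink
})
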