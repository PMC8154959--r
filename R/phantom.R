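# run expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Phantom solid primitives
#'
#' Shapes are parameterised in micrometres in the phantom's physical frame:
#' (row, col) in-plane (row down from the image top) and z along the
#' section axis. \code{ellipsoidShape} is an axis-aligned ellipsoid;
#' \code{polygonShape} extrudes a simple in-plane polygon between two
#' section depths; \code{boxShape} is the axis-aligned rectangular special
#' case. Later shapes in a \linkS4class{PhantomSpec} overwrite earlier ones
#' where they overlap.
#'
#' @param label integer voxel label the shape writes.
#' @param name structure name (used in volume reports).
#' @param center,semiaxes ellipsoid center and semi-axes, \code{c(row, col,
#'   z)} micrometres.
#' @param poly n x 2 matrix of (row, col) polygon vertices, micrometres.
#' @param zRange \code{c(zmin, zmax)} extrusion depths, micrometres.
#' @param rowRange,colRange box extents, micrometres.
#' @return A shape descriptor list for \code{\link{phantomSpec}}.
#' @name phantom-shapes
NULL

#' @rdname phantom-shapes
#' @export
ellipsoidShape <- function(label, name, center, semiaxes) {
  stopifnot(length(center) == 3, length(semiaxes) == 3, all(semiaxes > 0))
  list(kind = "ellipsoid", label = as.integer(label), name = name,
       center = as.numeric(center), semiaxes = as.numeric(semiaxes))
}

#' @rdname phantom-shapes
#' @export
polygonShape <- function(label, name, poly, zRange) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3, length(zRange) == 2,
            zRange[2] > zRange[1])
  list(kind = "polygon", label = as.integer(label), name = name,
       poly = poly, zRange = as.numeric(zRange))
}

#' @rdname phantom-shapes
#' @export
boxShape <- function(label, name, rowRange, colRange, zRange) {
  polygonShape(label, name,
               rbind(c(rowRange[1], colRange[1]), c(rowRange[1], colRange[2]),
                     c(rowRange[2], colRange[2]), c(rowRange[2], colRange[1])),
               zRange)
}

# regular polygon approximation of an ellipse (row, col um)
.ellipsePolygon <- function(center, semi, n = 48) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + semi[1] * cos(a), center[2] + semi[2] * sin(a))
}

# micrometre bounding box of a shape, rows x cols only
.shapeBBox <- function(s) {
  if (s$kind == "ellipsoid")
    rbind(s$center[1:2] - s$semiaxes[1:2], s$center[1:2] + s$semiaxes[1:2])
  else rbind(apply(s$poly, 2, min), apply(s$poly, 2, max))
}

# conservative fit check: every bbox corner must keep a margin covering
# 3-sigma translation plus the arc swept by a 3-sigma rotation about the
# image center
.checkShapesInFrame <- function(spec) {
  frame <- spec@imageSize * spec@pixelSize  # c(rows, cols) um
  ctr <- frame / 2
  tmarg <- 3 * spec@jitterSd[1] * spec@pixelSize
  rot <- 3 * spec@jitterSd[2] * pi / 180
  for (s in spec@shapes) {
    bb <- .shapeBBox(s)
    corners <- as.matrix(expand.grid(bb[, 1], bb[, 2]))
    for (i in seq_len(nrow(corners))) {
      p <- corners[i, ]
      need <- tmarg + 2 * sin(min(rot, pi) / 2) * sqrt(sum((p - ctr)^2))
      margin <- min(p[1], frame[1] - p[1], p[2], frame[2] - p[2])
      if (margin < need)
        return(sprintf(
          "shape '%s' can leave the frame under maximal jitter (margin %.1f < %.1f um)",
          s$name, margin, need))
    }
  }
  TRUE
}

#' Construct a phantom specification
#'
#' @param imageSize \code{c(rows, cols)} pixels.
#' @param nSlices number of sections.
#' @param pixelSize,thickness micrometres (defaults 1.75 um/px, 7 um
#'   sections).
#' @param shapes list of shape descriptors (see
#'   \code{\link{ellipsoidShape}}).
#' @param tissueLevel,cavityLevel mean green intensities of stained tissue
#'   and unstained lumen. The defaults (0.2, 0.8) are symmetric about the
#'   pipeline's fixed 0.5 threshold, so mean filtering introduces no
#'   systematic boundary bias.
#' @param noiseSd additive Gaussian intensity noise sd (default 0.05; the
#'   class separation must stay >= 3 sd).
#' @param jitterSd per-slice rigid jitter sd, \code{c(px, degrees)}
#'   (default c(5, 3)).
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(imageSize, nSlices, pixelSize = 1.75, thickness = 7,
                        shapes = list(), tissueLevel = 0.2,
                        cavityLevel = 0.8, noiseSd = 0.05,
                        jitterSd = c(5, 3), seed = 1L) {
  new("PhantomSpec", imageSize = as.integer(imageSize),
      nSlices = as.integer(nSlices), pixelSize = pixelSize,
      thickness = thickness, shapes = shapes, tissueLevel = tissueLevel,
      cavityLevel = cavityLevel, noiseSd = noiseSd,
      jitterSd = as.numeric(jitterSd), seed = as.integer(seed))
}

#' Embryonic palate phantom presets
#'
#' Two scene presets mimic the oral cavity of the mouse embryo around
#' shelf elevation, as seen in coronal section series; the bright cavity
#' region of each rendered slice is the union of the three structures.
#' "pre-elevation": two vertical shelf slabs flank a midline tongue body
#' (152 sections at full scale, as for an E12.5 series). "elevating": one
#' shelf already horizontal above a laterally shifted tongue while the
#' other remains vertical, giving the asymmetric, laterally deviated
#' configuration seen mid-elevation (250 sections, late E13.5).
#' \code{sizeFactor} scales the raster and slice count down while scaling
#' pixel size and thickness up, so the physical micrometre geometry (and
#' hence all ground-truth volumes) is unchanged; small factors render and
#' reconstruct in seconds.
#'
#' @param stage "pre-elevation" or "elevating".
#' @param sizeFactor raster/slice-count scale in (0, 1] (default 1).
#' @param seed RNG seed stored in the spec (default 1).
#' @return A \linkS4class{PhantomSpec} with exactly 3 labeled shapes:
#'   2 tongue, 3 left shelf, 4 right shelf (label 1 is reserved for the
#'   cavity label the reconstruction pipeline itself writes).
#' @export
embryoPreset <- function(stage = c("pre-elevation", "elevating"),
                         sizeFactor = 1, seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(sizeFactor > 0, sizeFactor <= 1)
  n0 <- if (stage == "pre-elevation") 152L else 250L
  nSlices <- max(8L, as.integer(round(n0 * sizeFactor)))
  D <- n0 * 7                      # physical depth, um
  thickness <- D / nSlices
  imageSize <- as.integer(round(c(1000, 2000) * sizeFactor))
  pixelSize <- 1750 / imageSize[1]  # frame fixed at 1750 x 3500 um
  # extruded (z-uniform) primitives: the tongue body spans the full depth
  # so no slice is empty, and consecutive silhouettes are identical up to
  # the applied jitter, which is exactly what slice-to-slice registration
  # assumes; shelf slabs overlap the tongue so the bright union stays one
  # connected component on every slice
  tongue <- function(colCenter) polygonShape(
    2L, "tongue", .ellipsePolygon(c(880, colCenter), c(340, 550)),
    c(0, D))
  if (stage == "pre-elevation") {
    shapes <- list(
      tongue(1750),
      boxShape(3L, "shelf_left", c(600, 1150), c(1100, 1450), c(0, D)),
      boxShape(4L, "shelf_right", c(600, 1150), c(2050, 2400), c(0, D)))
  } else {
    shapes <- list(
      tongue(1600),
      boxShape(3L, "shelf_left", c(520, 700), c(1250, 1950), c(0, D)),
      boxShape(4L, "shelf_right", c(600, 1150), c(1900, 2250), c(0, D)))
  }
  phantomSpec(imageSize = imageSize, nSlices = nSlices,
              pixelSize = pixelSize, thickness = thickness, shapes = shapes,
              seed = seed)
}

# voxelize one shape into the label array (in place semantics via return)
.voxelizeShape <- function(vox, s, rr, cc, zz) {
  if (s$kind == "ellipsoid") {
    fr <- ((rr - s$center[1]) / s$semiaxes[1])^2
    fc <- ((cc - s$center[2]) / s$semiaxes[2])^2
    inplane <- outer(fr, fc, "+")
    for (k in which(abs(zz - s$center[3]) < s$semiaxes[3])) {
      rem <- 1 - ((zz[k] - s$center[3]) / s$semiaxes[3])^2
      plane <- vox[, , k]
      plane[inplane <= rem] <- s$label
      vox[, , k] <- plane
    }
  } else {
    inside <- .pointsInPolygon(rr, cc, s$poly)
    for (k in which(zz >= s$zRange[1] & zz <= s$zRange[2])) {
      plane <- vox[, , k]
      plane[inside] <- s$label
      vox[, , k] <- plane
    }
  }
  vox
}

# even-odd rule point-in-polygon over the (rr x cc) grid
.pointsInPolygon <- function(rr, cc, poly) {
  nr <- length(rr); nc <- length(cc)
  X <- matrix(rr, nr, nc)
  Y <- matrix(cc, nr, nc, byrow = TRUE)
  inside <- matrix(FALSE, nr, nc)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > Y) != (yj > Y)) &
      (X < (xj - xi) * (Y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# analytic volume of a shape where a closed form exists (um^3)
.shapeVolume <- function(s) {
  if (s$kind == "ellipsoid") {
    4 / 3 * pi * prod(s$semiaxes)
  } else {
    p <- s$poly
    n <- nrow(p)
    j <- c(n, seq_len(n - 1))
    area <- abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
    area * diff(s$zRange)
  }
}

#' Build the ground truth of a phantom
#'
#' Voxelizes every shape at the spec's sampling (voxel centers at
#' \code{(i - 0.5) * spacing}), later shapes overwriting earlier ones where
#' they overlap, and draws the per-slice rigid jitters from the spec seed.
#' Per-label volumes are reported analytically (ellipsoid and extruded
#' polygon closed forms); where overlap makes the analytic value
#' inapplicable to the voxel grid, both are available via
#' \code{\link{volumeReport}} on the truth volume.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{PhantomTruth}.
#' @export
buildTruth <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- c(spec@imageSize, spec@nSlices)
  rr <- (seq_len(d[1]) - 0.5) * spec@pixelSize
  cc <- (seq_len(d[2]) - 0.5) * spec@pixelSize
  zz <- (seq_len(d[3]) - 0.5) * spec@thickness
  vox <- array(0L, d)
  for (s in spec@shapes) vox <- .voxelizeShape(vox, s, rr, cc, zz)
  vol <- new("LabeledVolume", voxels = vox,
             spacing = c(spec@pixelSize, spec@pixelSize, spec@thickness))
  volumes <- vapply(spec@shapes, .shapeVolume, numeric(1))
  names(volumes) <- vapply(spec@shapes, function(s) s$name, character(1))
  center <- (spec@imageSize + 1) / 2
  jitters <- .withSeed(spec@seed, lapply(seq_len(spec@nSlices), function(k)
    rigidTransform2D(
      theta = stats::rnorm(1, 0, spec@jitterSd[2]) * pi / 180,
      tRow = stats::rnorm(1, 0, spec@jitterSd[1]),
      tCol = stats::rnorm(1, 0, spec@jitterSd[1]),
      center = center)))
  new("PhantomTruth", volume = vol, jitters = jitters,
      volumesUm3 = volumes)
}

#' Render a phantom as an H&E-like section stack
#'
#' Each ground-truth z-plane is rendered as an RGB photograph: the green
#' channel carries the segmentation signal (bright cavity on dark tissue),
#' while red and blue mimic the pink H&E hue and are cosmetic — the
#' pipeline never reads them. Seeded Gaussian noise is added and clipped to
#' [0, 1], then each slice is displaced by its recorded rigid jitter
#' (simulating slide placement) and quantised to 8 bits. Identical
#' spec + seed gives bit-identical stacks.
#'
#' @param truth the \linkS4class{PhantomTruth} built from \code{spec}.
#' @param spec the \linkS4class{PhantomSpec}.
#' @return A \linkS4class{SectionStack}.
#' @export
renderStack <- function(truth, spec) {
  stopifnot(is(truth, "PhantomTruth"), is(spec, "PhantomSpec"))
  d <- dim(truth@volume@voxels)
  slices <- .withSeed(spec@seed + 1L, lapply(seq_len(d[3]), function(k) {
    cav <- truth@volume@voxels[, , k] > 0L
    g <- ifelse(cav, spec@cavityLevel, spec@tissueLevel)
    r <- ifelse(cav, 0.95, 0.80)
    b <- ifelse(cav, 0.93, 0.75)
    ch <- lapply(list(r, g, b), function(x)
      pmin(pmax(x + stats::rnorm(length(x), 0, spec@noiseSd), 0), 1))
    J <- truth@jitters[[k]]
    ch <- lapply(ch, function(x)
      applyRigid(matrix(x, d[1], d[2]), J, interpolation = "bilinear"))
    arr <- array(0L, c(d[1], d[2], 3))
    for (i in 1:3) arr[, , i] <- as.integer(round(ch[[i]] * 255))
    arr
  }))
  new("SectionStack", slices = slices, pixelSize = spec@pixelSize,
      thickness = spec@thickness)
}

#' Write a phantom stack and its ground-truth sidecars
#'
#' Writes the rendered sections as numbered TIFFs plus plain-text ground
#' truth: the applied per-slice jitters (CSV), per-label volumes (CSV), and
#' the label volume as a CSV of foreground voxel coordinates.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param dir output directory.
#' @return Invisibly, a list with the truth object and written paths.
#' @export
writePhantom <- function(spec, dir) {
  truth <- buildTruth(spec)
  stack <- renderStack(truth, spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- saveStack(stack, file.path(dir, "sections"))
  jit <- data.frame(
    index = seq_along(truth@jitters),
    theta_deg = vapply(truth@jitters, function(T) T@theta * 180 / pi,
                       numeric(1)),
    t_row = vapply(truth@jitters, function(T) T@tRow, numeric(1)),
    t_col = vapply(truth@jitters, function(T) T@tCol, numeric(1)))
  utils::write.csv(jit, file.path(dir, "jitters.csv"), row.names = FALSE)
  utils::write.csv(volumeReport(truth@volume),
                   file.path(dir, "volumes.csv"), row.names = FALSE)
  idx <- which(truth@volume@voxels > 0L, arr.ind = TRUE)
  utils::write.csv(
    data.frame(row = idx[, 1], col = idx[, 2], slice = idx[, 3],
               label = truth@volume@voxels[idx]),
    file.path(dir, "truth_voxels.csv"), row.names = FALSE)
  invisible(list(truth = truth, sections = paths, dir = dir))
}
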