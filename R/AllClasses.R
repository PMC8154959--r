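#' @useDynLib palate3D, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' RoiSpec: rectangular region of interest in pixel coordinates
#'
#' Pixel coordinates are 1-based \code{(row, col)} with row 1 at the image
#' top, matching R matrix indexing. The ROI must lie fully inside the raster
#' it is applied to; that is checked at extraction time, since a RoiSpec is
#' independent of any particular image.
#'
#' @slot row,col 1-based pixel offsets of the ROI's top-left corner.
#' @slot height,width ROI extent in pixels.
#' @export
setClass("RoiSpec",
  representation(row = "integer", col = "integer",
                 height = "integer", width = "integer"),
  validity = function(object) {
    if (object@row < 1L || object@col < 1L)
      return("ROI origin must be >= 1 in both coordinates")
    if (object@height < 1L || object@width < 1L)
      return("ROI height and width must be positive")
    TRUE
  })

#' SectionStack: an ordered stack of serial-section RGB photographs
#'
#' Each slice is an integer array \code{rows x cols x 3} with 8-bit channel
#' intensities (0..255), all slices sharing one raster size. Slices are held
#' in capture order; slice i of the stack is section i of the series.
#'
#' @slot slices list of \code{rows x cols x 3} integer arrays (0..255).
#' @slot pixelSize in-plane pixel size in micrometres (isotropic).
#' @slot thickness section thickness in micrometres (shared by all slices).
#' @export
setClass("SectionStack",
  representation(slices = "list", pixelSize = "numeric",
                 thickness = "numeric"),
  validity = function(object) {
    if (length(object@slices) < 2L)
      return("a stack needs at least 2 slices")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    if (object@thickness <= 0) return("thickness must be > 0")
    dims <- vapply(object@slices, function(s) dim(s), integer(3))
    if (any(dims[3, ] != 3L)) return("every slice must have 3 channels")
    if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
      return("all slices must share one raster size")
    TRUE
  })

#' CavityMask: the selected oral-cavity component of one section
#'
#' A binary raster holding exactly one 8-connected component (the largest
#' bright component of the thresholded section), or nothing at all when the
#' slice is degenerate (empty, damaged, or below the minimum-area floor).
#' Degenerate masks are carried through the pipeline and filled in during
#' volume assembly rather than raising errors.
#'
#' @slot pixels integer matrix of 0/1.
#' @slot index slice ordinal within its stack (1-based).
#' @slot pixelSize in-plane pixel size, micrometres.
#' @slot degenerate TRUE when no acceptable component was found.
#' @export
setClass("CavityMask",
  representation(pixels = "matrix", index = "integer",
                 pixelSize = "numeric", degenerate = "logical"),
  validity = function(object) {
    px <- object@pixels
    if (!all(px %in% c(0L, 1L))) return("mask pixels must be 0/1")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    if (object@degenerate && any(px != 0L))
      return("a degenerate mask must be empty")
    TRUE
  })

#' LabelMap: connected-component labeling of a binary raster
#'
#' Foreground pixels carry component labels forming the contiguous set
#' \code{1..nComponents}; background is 0. \code{areas[k]} is the pixel
#' count of component k, so \code{sum(areas)} equals the number of
#' foreground pixels.
#'
#' @slot pixels integer matrix of labels (0 = background).
#' @slot nComponents number of distinct components.
#' @slot areas integer vector of per-component pixel counts.
#' @export
setClass("LabelMap",
  representation(pixels = "matrix", nComponents = "integer",
                 areas = "integer"),
  validity = function(object) {
    n <- object@nComponents
    if (length(object@areas) != n) return("one area per component required")
    labs <- unique(as.integer(object@pixels))
    labs <- labs[labs != 0L]
    if (n > 0 && !setequal(labs, seq_len(n)))
      return("labels must form the contiguous set 1..nComponents")
    if (sum(object@areas) != sum(object@pixels != 0L))
      return("areas must sum to the foreground pixel count")
    TRUE
  })

#' RigidTransform2D: in-plane rotation plus translation
#'
#' The forward map is \code{T(p) = R(theta) (p - center) + center + t} on
#' points \code{p = (row, col)} in 1-based pixel coordinates, with
#' \code{R = [[cos, -sin], [sin, cos]]} acting on (row, col). Because row
#' increases downward, positive \code{theta} is counter-clockwise in
#' (row, col) algebra and appears clockwise on screen. Rigid maps preserve
#' distances exactly.
#'
#' @slot theta rotation angle in radians.
#' @slot tRow,tCol translation in pixels.
#' @slot center rotation center \code{c(row, col)} in pixels.
#' @export
setClass("RigidTransform2D",
  representation(theta = "numeric", tRow = "numeric", tCol = "numeric",
                 center = "numeric"),
  validity = function(object) {
    if (length(object@center) != 2L) return("center must be length 2")
    if (!all(is.finite(c(object@theta, object@tRow, object@tCol,
                         object@center))))
      return("transform parameters must be finite")
    TRUE
  })

#' AlignedStack: cavity masks registered to a common reference frame
#'
#' @slot masks list of transformed \linkS4class{CavityMask}, stack order.
#' @slot transforms list of composed \linkS4class{RigidTransform2D}, one per
#'   slice, mapping that slice's pixel coordinates into the reference frame;
#'   the reference slice's transform is the identity.
#' @slot referenceIndex 1-based ordinal of the reference slice.
#' @slot thickness section thickness, micrometres.
#' @export
setClass("AlignedStack",
  representation(masks = "list", transforms = "list",
                 referenceIndex = "integer", thickness = "numeric"),
  validity = function(object) {
    if (length(object@masks) != length(object@transforms))
      return("one transform per mask required")
    i <- object@referenceIndex
    if (i < 1L || i > length(object@masks))
      return("referenceIndex out of range")
    Tr <- object@transforms[[i]]
    if (abs(Tr@theta) > 1e-9 || abs(Tr@tRow) > 1e-9 || abs(Tr@tCol) > 1e-9)
      return("reference transform must be the identity")
    TRUE
  })

#' LabeledVolume: anisotropic voxel grid of structure labels
#'
#' Label 0 is background; the reconstruction pipeline writes the cavity as
#' label 1; phantom ground truth additionally uses 2 (tongue), 3 and 4
#' (left/right palatal shelf). Voxel (r, c, z) spans physical extents given
#' by \code{spacing} (micrometres per voxel along row, col, and section
#' axes); in-plane and section spacings generally differ (7 um sections vs
#' finer in-plane sampling), and all volume arithmetic honours that
#' anisotropy.
#'
#' @slot voxels 3D integer array of labels (rows x cols x sections).
#' @slot spacing numeric length 3: micrometres per voxel along (row, col, z).
#' @export
setClass("LabeledVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) return("voxels must be 3D")
    if (length(object@spacing) != 3L) return("spacing must be length 3")
    if (any(object@spacing <= 0)) return("spacing components must be > 0")
    TRUE
  })

#' SurfaceMesh: triangle mesh of one labeled structure
#'
#' Vertices are 3D points in micrometres; faces are 1-based vertex-index
#' triples wound so that face normals point outward (the signed volume of a
#' closed mesh is positive).
#'
#' @slot vertices numeric matrix n x 3 (micrometres).
#' @slot faces integer matrix m x 3 of 1-based vertex indices.
#' @slot label integer structure id the mesh was extracted from.
#' @slot color display color name (e.g. "orange", "pink", "gray").
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 label = "integer", color = "character"),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
    if (ncol(object@faces) != 3L) return("faces must be m x 3")
    if (nrow(object@faces) > 0) {
      f <- range(object@faces)
      if (f[1] < 1L || f[2] > nrow(object@vertices))
        return("face indices out of vertex range")
    }
    TRUE
  })

#' PhantomSpec: parameters of a synthetic serial-section stack
#'
#' Describes a 3D scene of labeled solids (ellipsoids and extruded
#' polygons, parameterised in micrometres) imaged as an H&E-like section
#' series: stained tissue is dark and the cavity lumen bright in the green
#' channel. Rendering adds seeded Gaussian intensity noise and applies a
#' seeded random rigid jitter per slice, emulating slide placement.
#'
#' The default intensity levels keep the tissue/cavity separation at least
#' three noise standard deviations wide, so the fixed 0.5 threshold always
#' lies between the class means; the validity method enforces this, along
#' with every shape fitting inside the frame under maximal (3 sigma)
#' jitter.
#'
#' @slot imageSize c(rows, cols) pixels.
#' @slot nSlices number of sections.
#' @slot pixelSize,thickness micrometres.
#' @slot shapes list of shape descriptors (see \code{\link{ellipsoidShape}}).
#' @slot tissueLevel,cavityLevel mean green-channel intensities in [0, 1].
#' @slot noiseSd additive Gaussian noise sd (intensity units).
#' @slot jitterSd c(translation px, rotation degrees) per-slice jitter sd.
#' @slot seed integer RNG seed; all randomness derives from it.
#' @export
setClass("PhantomSpec",
  representation(imageSize = "integer", nSlices = "integer",
                 pixelSize = "numeric", thickness = "numeric",
                 shapes = "list", tissueLevel = "numeric",
                 cavityLevel = "numeric", noiseSd = "numeric",
                 jitterSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nSlices < 2L) return("nSlices must be >= 2")
    if (object@pixelSize <= 0 || object@thickness <= 0)
      return("pixelSize and thickness must be > 0")
    if (object@cavityLevel - object@tissueLevel < 3 * object@noiseSd)
      return("cavity/tissue separation must be >= 3 noise sd")
    if (length(object@jitterSd) != 2L || any(object@jitterSd < 0))
      return("jitterSd must be c(translation px, rotation deg) >= 0")
    msg <- .checkShapesInFrame(object)
    if (!isTRUE(msg)) return(msg)
    TRUE
  })

#' PhantomTruth: ground truth attached to a rendered phantom
#'
#' @slot volume \linkS4class{LabeledVolume} of ground-truth labels.
#' @slot jitters list of \linkS4class{RigidTransform2D} actually applied to
#'   each rendered slice (the reference slice's jitter is recorded like any
#'   other; no slice is privileged).
#' @slot volumesUm3 named per-label volumes in cubic micrometres (analytic
#'   where a closed form exists, else voxel-counted).
#' @export
setClass("PhantomTruth",
  representation(volume = "LabeledVolume", jitters = "list",
                 volumesUm3 = "numeric"))
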