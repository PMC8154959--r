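#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("sectionThickness", function(x) standardGeneric("sectionThickness"))

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' @rdname accessors
#' @export
setGeneric("areaPx", function(x) standardGeneric("areaPx"))

#' @rdname accessors
#' @export
setGeneric("areaUm2", function(x) standardGeneric("areaUm2"))

#' @rdname accessors
#' @export
setGeneric("maskCentroid", function(x) standardGeneric("maskCentroid"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' Accessors for palate3D objects
#'
#' Slot access for the pipeline's S4 containers. \code{nSlices} counts
#' sections; \code{pixelSize}/\code{sectionThickness} return micrometre
#' sampling geometry; \code{areaPx}/\code{areaUm2}/\code{maskCentroid}
#' summarise a \linkS4class{CavityMask} (centroid is \code{c(row, col)} in
#' pixels, \code{NA} for degenerate masks); \code{meshVertices} and
#' \code{meshFaces} expose \linkS4class{SurfaceMesh} geometry.
#'
#' @param x the object.
#' @return See details; scalar counts, numeric vectors, or matrices.
#' @name accessors
#' @aliases nSlices pixelSize sectionThickness maskPixels areaPx areaUm2
#'   maskCentroid isDegenerate meshVertices meshFaces
NULL

#' @rdname accessors
setMethod("nSlices", "SectionStack", function(x) length(x@slices))
#' @rdname accessors
setMethod("nSlices", "AlignedStack", function(x) length(x@masks))
#' @rdname accessors
setMethod("pixelSize", "SectionStack", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "CavityMask", function(x) x@pixelSize)
#' @rdname accessors
setMethod("sectionThickness", "SectionStack", function(x) x@thickness)
#' @rdname accessors
setMethod("maskPixels", "CavityMask", function(x) x@pixels)
#' @rdname accessors
setMethod("areaPx", "CavityMask", function(x) sum(x@pixels))
#' @rdname accessors
setMethod("areaUm2", "CavityMask", function(x) sum(x@pixels) * x@pixelSize^2)
#' @rdname accessors
setMethod("maskCentroid", "CavityMask", function(x) {
  if (x@degenerate || sum(x@pixels) == 0L) return(c(row = NA_real_, col = NA_real_))
  idx <- which(x@pixels == 1L, arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
})
#' @rdname accessors
setMethod("isDegenerate", "CavityMask", function(x) x@degenerate)
#' @rdname accessors
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)

setMethod("show", "SectionStack", function(object) {
  d <- dim(object@slices[[1]])
  cat(sprintf(
    "SectionStack: %d slices of %d x %d px, %.3g um/px, %.3g um sections\n",
    length(object@slices), d[1], d[2], object@pixelSize, object@thickness))
})

setMethod("show", "CavityMask", function(object) {
  if (object@degenerate) {
    cat(sprintf("CavityMask (slice %d): degenerate (empty)\n", object@index))
  } else {
    ce <- maskCentroid(object)
    cat(sprintf(
      "CavityMask (slice %d): %d px (%.4g um^2), centroid (%.1f, %.1f)\n",
      object@index, areaPx(object), areaUm2(object), ce[1], ce[2]))
  }
})

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf(
    "RigidTransform2D: theta %.4f deg, t (%.3f, %.3f) px, center (%.1f, %.1f)\n",
    object@theta * 180 / pi, object@tRow, object@tCol,
    object@center[1], object@center[2]))
})

setMethod("show", "AlignedStack", function(object) {
  cat(sprintf("AlignedStack: %d masks, reference slice %d\n",
              length(object@masks), object@referenceIndex))
})

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@voxels)
  labs <- sort(unique(as.integer(object@voxels)))
  cat(sprintf(
    "LabeledVolume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um, labels {%s}\n",
    d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3],
    paste(labs, collapse = ", ")))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh (label %d, %s): %d vertices, %d faces\n",
              object@label, object@color, nrow(object@vertices),
              nrow(object@faces)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d px, %d slices, %.3g um/px, %.3g um sections, %d shapes, seed %d\n",
    object@imageSize[1], object@imageSize[2], object@nSlices,
    object@pixelSize, object@thickness, length(object@shapes), object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d recorded jitters; volumes (um^3): %s\n",
              length(object@jitters),
              paste(sprintf("%s=%.4g", names(object@volumesUm3),
                            object@volumesUm3), collapse = ", ")))
})
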