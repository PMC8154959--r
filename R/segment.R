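#' Label connected foreground components
#'
#' Two foreground pixels share a label iff they are connected through a
#' chain of horizontally, vertically, or (for 8-connectivity) diagonally
#' adjacent foreground pixels. 8-connectivity is the pipeline default;
#' 4-connectivity is available for comparison.
#'
#' @param mask integer matrix of 0/1 (e.g. from \code{\link{binarize}}).
#' @param connectivity 8 (default) or 4.
#' @return A \linkS4class{LabelMap}. An empty mask yields
#'   \code{nComponents = 0}, not an error.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) stop("labelComponents expects a matrix")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  res <- .cpp_label_components(m, as.integer(connectivity))
  new("LabelMap", pixels = res$labels, nComponents = res$n,
      areas = as.integer(res$areas))
}

# first foreground pixel of each label in raster-scan ((row, col)
# lexicographic) order; used for the deterministic area tie-break
.firstPixelScanOrder <- function(labels, n) {
  first <- rep(Inf, n)
  idx <- which(labels > 0L, arr.ind = TRUE)
  if (nrow(idx)) {
    key <- (idx[, 1] - 1) * (ncol(labels) + 1) + idx[, 2]  # row-major rank
    lab <- labels[idx]
    o <- order(key)
    first_seen <- !duplicated(lab[o])
    first[lab[o][first_seen]] <- key[o][first_seen]
  }
  first
}

#' Select the largest component as the oral cavity
#'
#' Keeps only the pixels of the maximum-area component. Ties are broken
#' deterministically: the component whose first foreground pixel comes
#' earliest in raster-scan ((row, col) lexicographic) order wins, which is
#' independent of how labels happen to be numbered. A "largest" component
#' below \code{minAreaPx} is treated as noise and the mask flagged
#' degenerate rather than letting a speck define the cavity; degenerate
#' masks flow through the pipeline and are filled in during volume
#' assembly.
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param minAreaPx minimum acceptable component area in pixels (default 64).
#' @param pixelSize in-plane pixel size, micrometres (default 1).
#' @param index slice ordinal recorded in the mask (default 1).
#' @return A \linkS4class{CavityMask}; degenerate (empty) when the map has
#'   no component of acceptable size.
#' @export
largestComponent <- function(labels, minAreaPx = 64, pixelSize = 1,
                             index = 1L) {
  stopifnot(is(labels, "LabelMap"))
  empty <- function() new("CavityMask",
    pixels = matrix(0L, nrow(labels@pixels), ncol(labels@pixels)),
    index = as.integer(index), pixelSize = pixelSize, degenerate = TRUE)
  if (labels@nComponents == 0L) return(empty())
  amax <- max(labels@areas)
  if (amax < minAreaPx) return(empty())
  cand <- which(labels@areas == amax)
  if (length(cand) > 1L) {
    first <- .firstPixelScanOrder(labels@pixels, labels@nComponents)
    cand <- cand[which.min(first[cand])]
  }
  px <- matrix(as.integer(labels@pixels == cand),
               nrow(labels@pixels), ncol(labels@pixels))
  new("CavityMask", pixels = px, index = as.integer(index),
      pixelSize = pixelSize, degenerate = FALSE)
}

#' Segment the oral cavity of one section
#'
#' Composition of the per-slice pipeline: green-channel conversion, square
#' mean filtering, fixed-threshold binarisation, 8-connected component
#' labeling, and largest-component selection. Deterministic: equal inputs
#' give equal masks.
#'
#' @param slice integer \code{rows x cols x 3} array (0..255).
#' @param pixelSize in-plane pixel size, micrometres.
#' @param index slice ordinal recorded in the mask.
#' @param window mean-filter window (default 15).
#' @param threshold binarisation level (default 0.5).
#' @param invert foreground polarity flag (default FALSE: bright cavity).
#' @param connectivity component connectivity (default 8).
#' @param minAreaPx degeneracy floor in pixels (default 64).
#' @return A \linkS4class{CavityMask}.
#' @export
segmentSlice <- function(slice, pixelSize = 1, index = 1L, window = 15,
                         threshold = 0.5, invert = FALSE, connectivity = 8,
                         minAreaPx = 64) {
  g <- greenChannel(slice)
  g <- meanFilter(g, window)
  b <- binarize(g, threshold, invert)
  largestComponent(labelComponents(b, connectivity),
                   minAreaPx = minAreaPx, pixelSize = pixelSize,
                   index = index)
}

#' Segment every slice of a stack
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param ... passed to \code{\link{segmentSlice}}.
#' @return List of \linkS4class{CavityMask}, one per slice, stack order.
#' @export
segmentStack <- function(stack, ...) {
  stopifnot(is(stack, "SectionStack"))
  lapply(seq_len(nSlices(stack)), function(i)
    segmentSlice(getSlice(stack, i), pixelSize = pixelSize(stack),
                 index = i, ...))
}

#' Per-slice segmentation quality-control table
#'
#' @param masks list of \linkS4class{CavityMask} (e.g. from
#'   \code{\link{segmentStack}}).
#' @return data.frame with columns \code{index}, \code{area_px},
#'   \code{centroid_row}, \code{centroid_col}, \code{degenerate}.
#' @export
maskQC <- function(masks) {
  do.call(rbind, lapply(masks, function(m) {
    ce <- maskCentroid(m)
    data.frame(index = m@index, area_px = areaPx(m),
               centroid_row = unname(ce[1]), centroid_col = unname(ce[2]),
               degenerate = isDegenerate(m))
  }))
}
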