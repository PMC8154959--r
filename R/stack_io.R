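#' Construct a region-of-interest specification
#'
#' @param row,col 1-based pixel offsets of the top-left corner.
#' @param height,width extent in pixels.
#' @return A \linkS4class{RoiSpec}.
#' @examples
#' roiSpec(1, 1, 100, 200)
#' @export
roiSpec <- function(row, col, height, width) {
  new("RoiSpec", row = as.integer(row), col = as.integer(col),
      height = as.integer(height), width = as.integer(width))
}

# read one RGB section file as an integer 0..255 array (rows x cols x 3)
.readSection <- function(path) {
  if (!file.exists(path)) stop("cannot read section image: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '", ext, "' for ", path))
  if (length(dim(px)) == 2L) stop("non-RGB (single-channel) image: ", path)
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(px)[3] != 3L) stop("non-RGB image (", dim(px)[3], " channels): ", path)
  a <- array(as.integer(round(px * 255)), dim = dim(px))
  a
}

#' Order section files for stack loading
#'
#' Files are ordered either by a manifest (a text file listing one path per
#' line, in section order) or by lexicographic sort of the file names, which
#' reproduces capture order when names carry zero-padded section numbers.
#' File timestamps are never consulted.
#'
#' @param dir directory holding the section images.
#' @param order "name" (lexicographic) or "manifest".
#' @param manifest path of the manifest file when \code{order = "manifest"};
#'   relative entries are resolved against \code{dir}.
#' @param pattern file-name regular expression (default TIFF/PNG).
#' @return Character vector of paths in section order.
#' @export
orderStackFiles <- function(dir, order = c("name", "manifest"),
                            manifest = NULL,
                            pattern = "\\.(tif|tiff|png)$") {
  order <- match.arg(order)
  if (order == "manifest") {
    if (is.null(manifest)) stop("order = 'manifest' requires a manifest path")
    entries <- readLines(manifest, warn = FALSE)
    entries <- entries[nzchar(trimws(entries))]
    paths <- ifelse(file.exists(entries), entries, file.path(dir, entries))
  } else {
    paths <- sort(list.files(dir, pattern = pattern, ignore.case = TRUE,
                             full.names = TRUE))
  }
  if (length(paths) < 2L) stop("need at least 2 section images in ", dir)
  paths
}

#' Load an ordered serial-section stack
#'
#' Reads TIFF or PNG section photographs in the order given, normalises
#' channel intensities to 8-bit, and checks that all rasters share one
#' size. The in-plane pixel size has no default: it is never stated by
#' image files and guessing it would silently corrupt every micrometre
#' measurement downstream.
#'
#' @param paths ordered character vector of image files (section order).
#' @param pixelSize in-plane pixel size, micrometres per pixel (required).
#' @param thickness section thickness, micrometres (default 7).
#' @return A \linkS4class{SectionStack} whose slice i is \code{paths[i]}.
#' @seealso \code{\link{orderStackFiles}}, \code{\link{extractRoi}}
#' @export
loadStack <- function(paths, pixelSize, thickness = 7) {
  if (missing(pixelSize)) stop("pixelSize (um/px) is required")
  if (length(paths) < 2L) stop("need at least 2 section images")
  slices <- lapply(paths, .readSection)
  dims <- vapply(slices, function(s) dim(s)[1:2], integer(2))
  ref <- dims[, 1]
  bad <- which(dims[1, ] != ref[1] | dims[2, ] != ref[2])
  if (length(bad))
    stop("dimension mismatch in slices: ",
         paste(basename(paths[bad]), collapse = ", "),
         " (expected ", ref[1], " x ", ref[2], ")")
  new("SectionStack", slices = slices, pixelSize = pixelSize,
      thickness = thickness)
}

#' Save a stack as numbered TIFF files
#'
#' Writes one 8-bit RGB TIFF per slice with zero-padded names so that a
#' lexicographic reload reproduces the stack bit-exactly.
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Invisibly, the written paths in slice order.
#' @export
saveStack <- function(stack, dir, prefix = "section") {
  stopifnot(is(stack, "SectionStack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nSlices(stack)
  wid <- max(4L, nchar(as.character(n)))
  paths <- file.path(dir, sprintf("%s_%0*d.tif", prefix, wid, seq_len(n)))
  for (i in seq_len(n))
    tiff::writeTIFF(stack@slices[[i]] / 255, paths[i], bits.per.sample = 8L)
  invisible(paths)
}

#' Crop every slice of a stack to a region of interest
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param roi a \linkS4class{RoiSpec}; must lie inside every slice raster.
#' @return A \linkS4class{SectionStack} of \code{height x width} slices;
#'   pixel size and thickness unchanged.
#' @export
extractRoi <- function(stack, roi) {
  stopifnot(is(stack, "SectionStack"), is(roi, "RoiSpec"))
  d <- dim(stack@slices[[1]])
  r2 <- roi@row + roi@height - 1L
  c2 <- roi@col + roi@width - 1L
  if (r2 > d[1] || c2 > d[2])
    stop("ROI [", roi@row, ":", r2, ", ", roi@col, ":", c2,
         "] exceeds raster ", d[1], " x ", d[2], " (slice 1)")
  slices <- lapply(stack@slices, function(s)
    s[roi@row:r2, roi@col:c2, , drop = FALSE])
  new("SectionStack", slices = slices, pixelSize = stack@pixelSize,
      thickness = stack@thickness)
}

#' Extract one slice of a stack
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param i slice ordinal (1-based).
#' @return The slice's integer \code{rows x cols x 3} pixel array (0..255).
#' @export
getSlice <- function(stack, i) {
  stopifnot(is(stack, "SectionStack"))
  if (i < 1L || i > nSlices(stack)) stop("slice index out of range: ", i)
  stack@slices[[i]]
}

#' Physical positions of sampled observation planes
#'
#' Serial sections are often inspected at a fixed section interval; with
#' 7 um sections, an interval of 15 sections spaces observation planes
#' 105 um apart and an interval of 10 sections spaces them 70 um apart.
#'
#' @param firstIndex section ordinal of the first plane.
#' @param interval plane spacing in sections (>= 1).
#' @param count number of planes (>= 1).
#' @param thickness section thickness, micrometres (default 7).
#' @param nSlices optional stack length; indices beyond it are an error.
#' @return data.frame with columns \code{index} (section ordinal) and
#'   \code{depth_um} (depth of plane k below the first plane,
#'   \code{(k-1) * interval * thickness}).
#' @examples
#' planePositions(1, interval = 15, count = 7, thickness = 7)
#' @export
planePositions <- function(firstIndex, interval, count, thickness = 7,
                           nSlices = NULL) {
  if (interval < 1) stop("interval must be >= 1")
  if (count < 1) stop("count must be >= 1")
  k <- seq_len(count) - 1L
  idx <- firstIndex + k * interval
  if (!is.null(nSlices) && max(idx) > nSlices)
    stop("plane index ", max(idx), " exceeds stack length ", nSlices)
  data.frame(index = idx, depth_um = k * interval * thickness)
}
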