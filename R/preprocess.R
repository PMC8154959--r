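#' Green-channel greyscale conversion
#'
#' Hematoxylin and eosin both absorb strongly in the green band, so the
#' green channel carries the best tissue/lumen contrast of an H&E
#' brightfield capture: stained tissue is dark, the unstained cavity
#' bright. Red and blue are discarded entirely.
#'
#' @param x an integer \code{rows x cols x 3} slice array (0..255), e.g.
#'   from \code{\link{getSlice}}.
#' @return Numeric matrix of green intensities scaled to [0, 1].
#' @export
greenChannel <- function(x) {
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("greenChannel expects an RGB (rows x cols x 3) array")
  g <- x[, , 2]
  if (is.integer(x) || max(g) > 1) g <- g / 255
  g
}

#' Square mean filter with edge replication
#'
#' Each output pixel is the arithmetic mean of the \code{window x window}
#' neighborhood centred on it (225 source pixels for the default 15 x 15
#' window). Borders are handled by edge replication: zero padding would
#' darken the frame edge and carve false cavity boundaries at the ROI rim.
#'
#' @param img numeric matrix in [0, 1].
#' @param window odd window side length in pixels (default 15).
#' @return Filtered matrix, same size; values stay within the input range.
#' @export
meanFilter <- function(img, window = 15) {
  if (!is.matrix(img)) stop("meanFilter expects a matrix")
  if (window < 1 || window %% 2 != 1)
    stop("window must be a positive odd integer, got ", window)
  if (window == 1) return(img)
  if (any(dim(img) < window))
    stop("image smaller than the filter window")
  k <- matrix(1 / window^2, window, window)
  f <- EBImage::filter2(img, k, boundary = "replicate")
  # filter2 is FFT-based; clamp float dust back into the input's range
  pmin(pmax(f, min(img)), max(img))
}

#' Fixed-threshold binarisation
#'
#' Thresholds a normalised greyscale image at a fixed level, foreground
#' being the bright side by default (the unstained cavity lumen of an H&E
#' section). The comparison is strictly greater-than on the [0, 1] scale;
#' since 8-bit data normalised by 255 can never equal 0.5 exactly, strict
#' and non-strict comparison differ only for synthetically exact values.
#'
#' @param img numeric matrix in [0, 1].
#' @param threshold level in (0, 1), default 0.5.
#' @param invert if TRUE, foreground is the dark side (pixel < 1 -
#'   threshold complement behaviour: the returned mask is the complement of
#'   the default one).
#' @return Integer matrix of 0/1.
#' @export
binarize <- function(img, threshold = 0.5, invert = FALSE) {
  if (!is.matrix(img)) stop("binarize expects a matrix")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1), got ", threshold)
  m <- (img > threshold)
  if (invert) m <- !m
  matrix(as.integer(m), nrow(img), ncol(img))
}
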