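#' Construct a rigid in-plane transform
#'
#' @param theta rotation in radians (see \linkS4class{RigidTransform2D} for
#'   the sign convention).
#' @param tRow,tCol translation in pixels.
#' @param center rotation center \code{c(row, col)}, pixels.
#' @return A \linkS4class{RigidTransform2D}.
#' @export
rigidTransform2D <- function(theta = 0, tRow = 0, tCol = 0,
                             center = c(0, 0)) {
  new("RigidTransform2D", theta = theta, tRow = tRow, tCol = tCol,
      center = as.numeric(center))
}

# (rotation matrix, offset) normal form: T(p) = R p + b
.toMatrixForm <- function(T) {
  R <- matrix(c(cos(T@theta), sin(T@theta),
                -sin(T@theta), cos(T@theta)), 2, 2)
  b <- T@center + c(T@tRow, T@tCol) - R %*% T@center
  list(R = R, b = as.numeric(b))
}

.fromMatrixForm <- function(R, b, center = c(0, 0)) {
  theta <- atan2(R[2, 1], R[1, 1])
  t <- as.numeric(b + R %*% center - center)
  rigidTransform2D(theta = theta, tRow = t[1], tCol = t[2], center = center)
}

#' Transform algebra for rigid 2D maps
#'
#' \code{composeRigid(A, B)} returns the transform applying B first, then A
#' (\code{T(p) = A(B(p))}); \code{invertRigid(T)} returns the inverse map;
#' \code{transformPoints(T, pts)} applies the forward map to an n x 2
#' matrix of (row, col) points.
#'
#' @param A,B,T \linkS4class{RigidTransform2D} objects.
#' @param pts numeric n x 2 matrix (or length-2 vector) of (row, col).
#' @return A transform, or for \code{transformPoints} the mapped points.
#' @name transform-algebra
NULL

#' @rdname transform-algebra
#' @export
composeRigid <- function(A, B) {
  a <- .toMatrixForm(A); b <- .toMatrixForm(B)
  .fromMatrixForm(a$R %*% b$R, as.numeric(a$R %*% b$b) + a$b,
                  center = B@center)
}

#' @rdname transform-algebra
#' @export
invertRigid <- function(T) {
  m <- .toMatrixForm(T)
  .fromMatrixForm(t(m$R), as.numeric(-t(m$R) %*% m$b), center = T@center)
}

#' @rdname transform-algebra
#' @export
transformPoints <- function(T, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  m <- .toMatrixForm(T)
  t(m$R %*% t(pts) + m$b)
}

# deviation of a transform from the identity: rotation magnitude (deg)
# and the point displacement at the raster center, where the registered
# anatomy sits (the target-registration-error convention for a pose)
.transformDeviation <- function(T, dim = c(100, 100)) {
  ctr <- matrix((1 + dim) / 2, 1)
  d <- transformPoints(T, ctr) - ctr
  c(deg = abs(T@theta) * 180 / pi, px = sqrt(sum(d^2)))
}

#' Apply a rigid transform to a raster
#'
#' Resamples by inverse mapping: output pixel q takes the value of the
#' input at \code{T^-1(q)}. Binary masks use nearest-neighbor sampling (so
#' they stay binary); greyscale images use bilinear interpolation.
#' Out-of-frame regions are filled with background 0. The identity
#' transform reproduces the raster bit-exactly.
#'
#' @param x a \linkS4class{CavityMask}, or a numeric/integer matrix (a
#'   matrix of only 0/1 is resampled as a mask, anything else bilinearly).
#' @param T a \linkS4class{RigidTransform2D}.
#' @param interpolation "auto" (default, by input kind), "nearest", or
#'   "bilinear".
#' @return Same type as \code{x}.
#' @export
applyRigid <- function(x, T,
                       interpolation = c("auto", "nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is(T, "RigidTransform2D"))
  if (is(x, "CavityMask")) {
    px <- .cpp_rigid_resample(x@pixels + 0, T@theta, T@tRow, T@tCol,
                              T@center[1], T@center[2], FALSE)
    return(new("CavityMask",
               pixels = matrix(as.integer(px), nrow(px), ncol(px)),
               index = x@index, pixelSize = x@pixelSize,
               degenerate = x@degenerate))
  }
  if (!is.matrix(x)) stop("applyRigid expects a CavityMask or a matrix")
  binary <- all(x %in% c(0, 1))
  nn <- switch(interpolation, nearest = TRUE, bilinear = FALSE,
               auto = binary)
  out <- .cpp_rigid_resample(x + 0, T@theta, T@tRow, T@tCol,
                             T@center[1], T@center[2], !nn)
  if (is.integer(x)) matrix(as.integer(round(out)), nrow(x), ncol(x))
  else out
}

# centroid and principal-axis angle from second central moments
.maskMoments <- function(px) {
  idx <- which(px == 1L, arr.ind = TRUE)
  ce <- colMeans(idx)
  dr <- idx[, 1] - ce[1]; dc <- idx[, 2] - ce[2]
  mu20 <- mean(dr^2); mu02 <- mean(dc^2); mu11 <- mean(dr * dc)
  list(centroid = ce, angle = 0.5 * atan2(2 * mu11, mu20 - mu02))
}

# Dice score of T(moving) against fixed for a candidate (theta, t);
# fields may be anti-aliased mask fields; soft = bilinear resampling of
# the moving field, making the score smooth in the parameters
.diceAt <- function(moving, fixed, theta, tRow, tCol, center, soft = TRUE) {
  .cpp_rigid_dice(moving + 0, fixed + 0, theta, tRow, tCol,
                  center[1], center[2], soft)
}

#' Dice coefficient between two binary masks
#'
#' @param a,b \linkS4class{CavityMask} objects or 0/1 matrices of equal size.
#' @return \code{2|A n B| / (|A| + |B|)}; 0 when both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "CavityMask")) a <- a@pixels
  if (is(b, "CavityMask")) b <- b@pixels
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(0)
  2 * sum(a * b) / (sa + sb)
}

#' Estimate the rigid transform aligning one cavity mask to another
#'
#' Intensity-free mask registration: translation is initialised from the
#' centroid difference and rotation from the difference of the masks'
#' second-moment principal-axis angles (second moments cannot distinguish
#' an angle from its pi-complement, so both candidates are scored and the
#' higher-Dice one kept). The initial pose is then refined by coordinate
#' descent maximising the Dice overlap of the transformed moving mask
#' against the fixed mask: a fine rotation grid around the current angle,
#' then a local translation search, repeated \code{refineRounds} times.
#' Fully deterministic.
#'
#' @param moving,fixed non-degenerate \linkS4class{CavityMask} objects.
#' @param maxRotDeg rotation search bound in degrees (default 10).
#' @param refineRounds refinement rounds (default 2).
#' @return A \linkS4class{RigidTransform2D} mapping \code{moving}
#'   coordinates into the \code{fixed} frame (rotation centred on the
#'   moving mask's centroid).
#' @export
estimateRigid <- function(moving, fixed, maxRotDeg = 10, refineRounds = 2) {
  stopifnot(is(moving, "CavityMask"), is(fixed, "CavityMask"))
  if (isDegenerate(moving) || isDegenerate(fixed))
    stop("estimateRigid requires non-degenerate masks")
  mm <- .maskMoments(moving@pixels)
  mf <- .maskMoments(fixed@pixels)
  center <- as.numeric(mm$centroid)
  t0 <- as.numeric(mf$centroid - mm$centroid)
  maxRot <- maxRotDeg * pi / 180
  # anti-aliased mask fields: a small box filter turns the hard 1-px mask
  # edges into linear ramps, so the soft Dice objective carries subpixel
  # boundary information and its maximum localises the pose far more
  # precisely than binary overlap
  movS <- meanFilter(moving@pixels + 0, 3)
  fixS <- meanFilter(fixed@pixels + 0, 3)

  wrap <- function(a) atan2(sin(a), cos(a))
  cand <- unique(c(0, wrap(mf$angle - mm$angle),
                   wrap(mf$angle - mm$angle + pi)))
  cand <- unique(pmin(pmax(cand, -maxRot), maxRot))

  score <- function(th, tr, tc) .diceAt(movS, fixS, th, tr, tc, center)

  best <- list(theta = cand[1], tRow = t0[1], tCol = t0[2], dice = -1)
  for (th0 in cand) {
    th <- th0; tr <- t0[1]; tc <- t0[2]
    for (round in seq_len(refineRounds)) {
      span <- if (round == 1) 5 * pi / 180 else 0.3 * pi / 180
      step <- if (round == 1) 0.1 * pi / 180 else 0.02 * pi / 180
      grid <- th + seq(-span, span, by = step)
      grid <- grid[abs(grid) <= maxRot + 1e-12]
      if (!length(grid)) grid <- th
      grid <- grid[order(abs(grid - th))]  # ties prefer the smallest change
      d <- vapply(grid, function(g) score(g, tr, tc), numeric(1))
      th <- grid[which.max(d)]
      shifts <- as.matrix(expand.grid(
        dr = if (round == 1) seq(-2, 2, by = 1) else seq(-0.5, 0.5, by = 0.1),
        dc = if (round == 1) seq(-2, 2, by = 1) else seq(-0.5, 0.5, by = 0.1)))
      shifts <- shifts[order(shifts[, 1]^2 + shifts[, 2]^2), , drop = FALSE]
      d <- apply(shifts, 1, function(s) score(th, tr + s[[1]], tc + s[[2]]))
      k <- which.max(d)
      tr <- unname(tr + shifts[k, 1]); tc <- unname(tc + shifts[k, 2])
    }
    dice <- score(th, tr, tc)
    if (dice > best$dice)
      best <- list(theta = th, tRow = tr, tCol = tc, dice = dice)
  }
  rigidTransform2D(theta = best$theta, tRow = best$tRow, tCol = best$tCol,
                   center = center)
}

#' Align a stack of cavity masks to a common reference slice
#'
#' Pairwise transforms are estimated between consecutive non-degenerate
#' slices and composed outward from the reference slice (the middle of the
#' stack by default, which halves worst-case drift versus anchoring at an
#' end). Degenerate slices inherit the composed transform of their nearest
#' non-degenerate neighbor toward the reference.
#'
#' @param masks list of \linkS4class{CavityMask} in stack order, at least
#'   one non-degenerate.
#' @param reference "middle" or a 1-based slice ordinal.
#' @param thickness section thickness, micrometres (default 7); carried to
#'   the aligned stack for volume assembly.
#' @param ... passed to \code{\link{estimateRigid}}.
#' @return An \linkS4class{AlignedStack}: transformed masks plus the
#'   per-slice composed transforms.
#' @export
alignStack <- function(masks, reference = "middle", thickness = 7, ...) {
  n <- length(masks)
  if (n < 2L) stop("alignStack needs at least 2 masks")
  ok <- !vapply(masks, isDegenerate, logical(1))
  if (!any(ok)) stop("all slices are degenerate; nothing to align")
  ref <- if (identical(reference, "middle")) {
    good <- which(ok)
    good[which.min(abs(good - (n + 1) / 2))]
  } else {
    r <- as.integer(reference)
    if (r < 1L || r > n) stop("reference index out of range: ", r)
    if (!ok[r]) stop("reference slice ", r, " is degenerate")
    r
  }
  transforms <- vector("list", n)
  transforms[[ref]] <- rigidTransform2D(center = as.numeric(
    maskCentroid(masks[[ref]])))
  for (dir in c(1L, -1L)) {
    lastGood <- ref
    i <- ref + dir
    while (i >= 1L && i <= n) {
      if (ok[i]) {
        P <- estimateRigid(masks[[i]], masks[[lastGood]], ...)
        transforms[[i]] <- composeRigid(transforms[[lastGood]], P)
        lastGood <- i
      } else {
        transforms[[i]] <- transforms[[lastGood]]
      }
      i <- i + dir
    }
  }
  aligned <- lapply(seq_len(n), function(i)
    if (ok[i]) applyRigid(masks[[i]], transforms[[i]]) else masks[[i]])
  new("AlignedStack", masks = aligned, transforms = transforms,
      referenceIndex = as.integer(ref), thickness = thickness)
}

#' Transform table of an aligned stack
#'
#' @param aligned an \linkS4class{AlignedStack}.
#' @return data.frame with per-slice \code{index}, \code{theta_deg},
#'   \code{t_row}, \code{t_col}, and \code{dice_to_neighbor} (Dice overlap
#'   of the aligned mask with the aligned previous slice; NA for slice 1
#'   and degenerate pairs).
#' @export
transformTable <- function(aligned) {
  stopifnot(is(aligned, "AlignedStack"))
  n <- nSlices(aligned)
  dice <- rep(NA_real_, n)
  for (i in 2:n) {
    a <- aligned@masks[[i - 1]]; b <- aligned@masks[[i]]
    if (!isDegenerate(a) && !isDegenerate(b))
      dice[i] <- diceCoefficient(a, b)
  }
  data.frame(
    index = seq_len(n),
    theta_deg = vapply(aligned@transforms, function(T) T@theta * 180 / pi,
                       numeric(1)),
    t_row = vapply(aligned@transforms, function(T) T@tRow, numeric(1)),
    t_col = vapply(aligned@transforms, function(T) T@tCol, numeric(1)),
    dice_to_neighbor = dice)
}
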