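#' Assemble aligned cavity masks into a labeled voxel volume
#'
#' Stacks the aligned per-slice masks along the section axis as label 1 on
#' background 0. Degenerate slices (damaged or empty sections) are filled
#' with a copy of the nearest non-degenerate plane, ties going to the
#' earlier slice, so isolated bad sections do not punch holes through the
#' reconstruction.
#'
#' @param aligned an \linkS4class{AlignedStack}.
#' @param spacing voxel spacing \code{c(row, col, z)} in micrometres; by
#'   default taken from the masks' pixel size and the stack thickness.
#' @return A \linkS4class{LabeledVolume} with one z-plane per slice.
#' @export
assembleVolume <- function(aligned, spacing = NULL) {
  stopifnot(is(aligned, "AlignedStack"))
  n <- nSlices(aligned)
  ok <- !vapply(aligned@masks, isDegenerate, logical(1))
  if (!any(ok)) stop("cannot assemble an all-degenerate stack")
  if (is.null(spacing)) {
    ps <- pixelSize(aligned@masks[[1]])
    spacing <- c(ps, ps, aligned@thickness)
  }
  d <- dim(aligned@masks[[1]]@pixels)
  vox <- array(0L, c(d[1], d[2], n))
  good <- which(ok)
  for (k in seq_len(n)) {
    src <- good[which.min(abs(good - k))]
    vox[, , k] <- aligned@masks[[src]]@pixels
  }
  new("LabeledVolume", voxels = vox, spacing = as.numeric(spacing))
}

#' Measure the physical volume of a labeled structure
#'
#' Volume is the matching-voxel count times the anisotropic voxel volume
#' \code{spacing[1] * spacing[2] * spacing[3]}. Additive over disjoint
#' labels; a label can be a vector to measure a union of structures.
#'
#' @param vol a \linkS4class{LabeledVolume}.
#' @param label integer label id(s); an absent label measures 0.
#' @return Volume in cubic micrometres.
#' @export
measureVolume <- function(vol, label = 1L) {
  stopifnot(is(vol, "LabeledVolume"))
  sum(vol@voxels %in% label) * prod(vol@spacing)
}

#' Per-label volume report
#'
#' @param vol a \linkS4class{LabeledVolume}.
#' @return data.frame with columns \code{label}, \code{voxels},
#'   \code{volume_um3}, one row per positive label present.
#' @export
volumeReport <- function(vol) {
  stopifnot(is(vol, "LabeledVolume"))
  labs <- sort(unique(as.integer(vol@voxels)))
  labs <- labs[labs > 0L]
  counts <- vapply(labs, function(l) sum(vol@voxels == l), numeric(1))
  data.frame(label = labs, voxels = counts,
             volume_um3 = counts * prod(vol@spacing))
}

#' Extract the triangulated iso-surface of a labeled structure
#'
#' Triangulates the 0.5 iso-level of the label's indicator field, sampled
#' at voxel centers and padded with background so interior structures
#' yield closed (watertight) meshes. Triangulation is marching tetrahedra
#' on the Freudenthal 6-tetrahedra cube decomposition, which is crack-free
#' across cube faces by construction. Vertices are scaled by the voxel
#' spacing into micrometres, honouring the anisotropy between in-plane and
#' section sampling; faces are wound outward (positive signed volume).
#'
#' @param vol a \linkS4class{LabeledVolume}.
#' @param label structure id; may be a vector to extract a union. Must
#'   occupy at least one voxel.
#' @param color display color name recorded on the mesh (default "gray").
#' @return A \linkS4class{SurfaceMesh}.
#' @export
extractSurface <- function(vol, label = 1L, color = "gray") {
  stopifnot(is(vol, "LabeledVolume"))
  ind <- array(as.numeric(vol@voxels %in% label), dim(vol@voxels))
  if (sum(ind) == 0)
    stop("label ", paste(label, collapse = "/"),
         " occupies no voxels; nothing to extract")
  d <- dim(ind) + 2L
  padded <- array(0, d)
  padded[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- ind
  res <- .cpp_marching_tets(as.numeric(padded), as.integer(d), 0.5)
  # padded 0-based index i maps to unpadded voxel center (i - 0.5) * spacing
  v <- res$vertices
  v <- sweep(sweep(v, 2, 0.5, "-"), 2, vol@spacing, "*")
  mesh <- new("SurfaceMesh", vertices = v,
              faces = matrix(as.integer(res$faces), ncol = 3),
              label = as.integer(label[1]), color = color)
  if (nrow(mesh@faces) > 0 && meshVolume(mesh) < 0)
    mesh@faces <- mesh@faces[, c(1L, 3L, 2L)]
  mesh
}

#' Signed enclosed volume of a triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes against the
#' origin; for a closed mesh with outward winding this is the enclosed
#' volume in cubic micrometres.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return Signed volume (um^3).
#' @export
meshVolume <- function(mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (nrow(mesh@faces) == 0) return(0)
  a <- mesh@vertices[mesh@faces[, 1], , drop = FALSE]
  b <- mesh@vertices[mesh@faces[, 2], , drop = FALSE]
  c <- mesh@vertices[mesh@faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Is a mesh closed (watertight)?
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return TRUE when every undirected edge is shared by exactly two faces.
#' @export
isClosedMesh <- function(mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  f <- mesh@faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# sparse vertex adjacency (1-ring) from the face list
.vertexAdjacency <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  n <- nrow(mesh@vertices)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  A@x[] <- 1  # collapse duplicate edge entries to 0/1
  A
}

# centroid of each vertex's 1-ring neighbors
.neighborCentroid <- function(A, V) {
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  as.matrix(A %*% V) / deg
}

#' Snap spike vertices back to their neighborhood
#'
#' Reconstruction spikes are isolated vertices far from the local surface.
#' For every vertex the distance to the centroid of its 1-ring neighbors
#' is computed; vertices whose distance exceeds
#' \code{median + iqrFactor * IQR} of that statistic are snapped onto the
#' neighbor centroid. Face topology is unchanged. Meshes with fewer than 5
#' vertices are returned untouched (too small to define outliers).
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param iqrFactor outlier cut in IQR units (default 3).
#' @return The cleaned \linkS4class{SurfaceMesh}.
#' @export
removeSpikes <- function(mesh, iqrFactor = 3) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (nrow(mesh@vertices) < 5L || nrow(mesh@faces) == 0) return(mesh)
  A <- .vertexAdjacency(mesh)
  ctr <- .neighborCentroid(A, mesh@vertices)
  d <- sqrt(rowSums((mesh@vertices - ctr)^2))
  cut <- stats::median(d) + iqrFactor * stats::IQR(d)
  out <- d > cut
  if (any(out)) mesh@vertices[out, ] <- ctr[out, , drop = FALSE]
  mesh
}

#' Taubin mesh smoothing
#'
#' Two-step neighborhood averaging per iteration: a shrink step with
#' weight \code{lambda} followed by an inflate step with negative weight
#' \code{mu}, the classic anti-shrink pairing that suppresses surface
#' noise while keeping the enclosed volume nearly constant. Topology is
#' unchanged; 0 iterations is the identity.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param iterations smoothing passes (default 10).
#' @param lambda shrink-step weight (default 0.5).
#' @param mu inflate-step weight (default -0.53).
#' @return The smoothed \linkS4class{SurfaceMesh}.
#' @export
smoothMesh <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (iterations == 0 || nrow(mesh@faces) == 0) return(mesh)
  A <- .vertexAdjacency(mesh)
  V <- mesh@vertices
  for (i in seq_len(iterations)) {
    V <- V + lambda * (.neighborCentroid(A, V) - V)
    V <- V + mu * (.neighborCentroid(A, V) - V)
  }
  mesh@vertices <- V
  mesh
}

# RGB (0..255) of a display color name
.colorRGB <- function(name) as.integer(grDevices::col2rgb(name))

#' Export a surface mesh to STL or PLY
#'
#' Binary STL carries geometry only (the CAD interchange default); ASCII
#' PLY additionally carries the structure's display color as per-vertex
#' uchar RGB (e.g. palatal shelves orange, tongue pink). Re-importing an
#' STL reproduces vertices to float32 precision.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output file.
#' @param format "stl" or "ply"; default inferred from the extension.
#' @return Invisibly, \code{path}.
#' @export
exportMesh <- function(mesh, path, format = NULL) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "ply"))
  if (format == "stl") .writeSTL(mesh, path) else .writePLY(mesh, path)
  invisible(path)
}

.writeSTL <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "palate3D binary STL"))[1:80]
  writeBin(header, con)
  nf <- nrow(mesh@faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  V <- mesh@vertices
  for (i in seq_len(nf)) {
    tri <- V[mesh@faces[i, ], , drop = FALSE]
    u <- tri[2, ] - tri[1, ]; v <- tri[3, ] - tri[1, ]
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    len <- sqrt(sum(n^2))
    if (len > 0) n <- n / len
    writeBin(as.numeric(c(n, t(tri))), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
}

#' Read a binary STL file
#'
#' Duplicate corner points are welded exactly, rebuilding a vertex/face
#' representation; used for round-trip checks of exported models.
#'
#' @param path STL file.
#' @param label,color metadata for the resulting mesh.
#' @return A \linkS4class{SurfaceMesh}.
#' @export
readSTL <- function(path, label = 1L, color = "gray") {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, raw(), 80))
  nf <- readBin(con, integer(), 1, size = 4, endian = "little")
  corners <- matrix(0, 3 * nf, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, numeric(), 12, size = 4, endian = "little")
    corners[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, byrow = TRUE)
    invisible(readBin(con, raw(), 2))
  }
  key <- apply(corners, 1, paste, collapse = ",")
  uid <- !duplicated(key)
  vid <- match(key, key[uid])
  new("SurfaceMesh", vertices = corners[uid, , drop = FALSE],
      faces = matrix(as.integer(vid), ncol = 3, byrow = TRUE),
      label = as.integer(label), color = color)
}

.writePLY <- function(mesh, path) {
  rgb <- .colorRGB(mesh@color)
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("comment palate3D structure label %d color %s",
            mesh@label, mesh@color),
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6g %.6g %.6g %d %d %d",
                     mesh@vertices[, 1], mesh@vertices[, 2],
                     mesh@vertices[, 3], rgb[1], rgb[2], rgb[3]), con)
  if (nf > 0)
    writeLines(sprintf("3 %d %d %d", mesh@faces[, 1] - 1L,
                       mesh@faces[, 2] - 1L, mesh@faces[, 3] - 1L), con)
}
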