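# Independent oracles and fixture builders used across the suite.

# Breadth-first flood-fill labeling, the reference implementation that
# labelComponents is checked against. Deliberately simple and slow.
floodFillLabels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (mask[r0, c0] == 0 || lab[r0, c0] != 0) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] == 1 && lab[r, c] == 0) {
          lab[r, c] <- cur
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
  }
  lab
}

# canonical form of a labeling: each foreground pixel mapped to the
# smallest linear index of its component, so two labelings agree iff they
# induce the same partition
canonicalPartition <- function(lab) {
  v <- as.integer(lab)
  out <- integer(length(v))
  for (l in unique(v[v > 0])) {
    members <- which(v == l)
    out[members] <- min(members)
  }
  out
}

# asymmetric test blob with unambiguous orientation
blobMask <- function(nr = 80, nc = 160) {
  m <- matrix(0L, nr, nc)
  rr <- row(m); cc <- col(m)
  m[((rr - nr / 2) / (nr * 0.25))^2 + ((cc - nc / 2) / (nc * 0.3))^2 <= 1] <- 1L
  m[rr > nr * 0.3 & rr < nr * 0.5 & cc > nc * 0.62 & cc < nc * 0.8] <- 1L
  m
}

asMask <- function(px, index = 1L, pixelSize = 1) {
  new("CavityMask", pixels = px, index = as.integer(index),
      pixelSize = pixelSize, degenerate = all(px == 0L))
}

# closed UV-sphere triangulation with outward winding
uvSphere <- function(radius = 1, nLat = 14, nLon = 20, center = c(0, 0, 0)) {
  lat <- seq(0, pi, length.out = nLat + 2)[2:(nLat + 1)]
  lon <- seq(0, 2 * pi, length.out = nLon + 1)[-(nLon + 1)]
  g <- expand.grid(lat = lat, lon = lon)
  ring <- cbind(sin(g$lat) * cos(g$lon), sin(g$lat) * sin(g$lon), cos(g$lat))
  V <- rbind(c(0, 0, 1), ring, c(0, 0, -1)) * radius
  V <- sweep(V, 2, center, "+")
  idx <- function(i, j) 1L + (j - 1L) * nLat + i  # ring vertex (lat i, lon j)
  top <- 1L; bot <- nrow(V)
  F <- list()
  for (j in seq_len(nLon)) {
    j2 <- if (j == nLon) 1L else j + 1L
    F[[length(F) + 1]] <- c(top, idx(1, j2), idx(1, j))
    F[[length(F) + 1]] <- c(bot, idx(nLat, j), idx(nLat, j2))
    for (i in seq_len(nLat - 1)) {
      F[[length(F) + 1]] <- c(idx(i, j), idx(i, j2), idx(i + 1, j))
      F[[length(F) + 1]] <- c(idx(i + 1, j), idx(i, j2), idx(i + 1, j2))
    }
  }
  mesh <- new("SurfaceMesh", vertices = V,
              faces = matrix(as.integer(unlist(F)), ncol = 3, byrow = TRUE),
              label = 1L, color = "gray")
  if (meshVolume(mesh) < 0) mesh@faces <- mesh@faces[, c(1L, 3L, 2L)]
  mesh
}

# per-slice pose-recovery residuals of an aligned phantom stack:
# the composed transform of slice i should equal J_ref o J_i^-1 up to the
# shared reference frame; returns (deg, px) deviations per slice
alignmentResiduals <- function(aligned, truth, dim) {
  ref <- aligned@referenceIndex
  sapply(seq_len(nSlices(aligned)), function(i) {
    ideal <- composeRigid(truth@jitters[[ref]],
                          invertRigid(truth@jitters[[i]]))
    D <- composeRigid(invertRigid(ideal), aligned@transforms[[i]])
    palate3D:::.transformDeviation(D, dim)
  })
}

# render-and-reconstruct one phantom preset, returning the quantities the
# phantom validation suite scores
runPhantomRecovery <- function(stage = "elevating", sizeFactor = 0.1,
                               seed = 1L, mesh = TRUE) {
  spec <- embryoPreset(stage, sizeFactor = sizeFactor, seed = seed)
  truth <- buildTruth(spec)
  stack <- renderStack(truth, spec)
  masks <- segmentStack(stack)
  aligned <- alignStack(masks, thickness = sectionThickness(stack),
                        maxRotDeg = 25)
  resid <- alignmentResiduals(aligned, truth, dim(getSlice(stack, 1))[1:2])
  vol <- assembleVolume(aligned)
  v <- measureVolume(vol, 1L)
  vt <- measureVolume(truth@volume, c(1:4))
  out <- list(residual_deg = mean(resid[1, ]), residual_px = mean(resid[2, ]),
              volume_um3 = v, truth_um3 = vt,
              volume_err_pct = 100 * abs(v - vt) / vt)
  if (mesh) {
    m <- extractSurface(vol, 1L)
    out$mesh_um3 <- meshVolume(m)
    out$mesh_voxel_err_pct <- 100 * abs(out$mesh_um3 - v) / v
  }
  out
}
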