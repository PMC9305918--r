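#' Centerline-based maximal diameter change
#'
#' The clinical reference task: extract the aortic centerline of the fixed
#' anatomy, sample it every 0.5 mm, measure the maximal cross-section
#' diameter (maximal chord of the section contour) orthogonal to the
#' centerline at each station, and locate the station where the fixed and
#' moving diameters differ the most.
#'
#' @name diameterAnalysis
NULL

#' Extract a centerline from a mask or mesh
#'
#' Ridge-following minimal path: the interior distance transform is
#' computed, the two ends of the object are found by geodesic sweeps, and
#' a shortest path weighted to hug the maximal-inscribed-sphere ridge links
#' them. The voxel path is smoothed with smoothing splines per coordinate
#' and resampled at \code{step} mm; ends are trimmed by \code{trim} mm to
#' avoid cap artifacts.
#'
#' @param x binary mask (\linkS4class{ImageVolume}) or
#'   \linkS4class{SurfaceMesh} (voxelized internally at 1 mm).
#' @param step resampling step (mm).
#' @param trim minimum length trimmed from each end (mm); automatically
#'   enlarged to 1.6 times the maximal inscribed radius, the scale over
#'   which the minimal path transitions from the end-cap rim to the axis.
#' @param smoothDf smoothing-spline degrees of freedom per 100 mm of path.
#' @return A \linkS4class{CenterlineCurve}.
#' @export
extractCenterline <- function(x, step = 0.5, trim = 8, smoothDf = 8) {
  if (is(x, "SurfaceMesh")) {
    grid <- gridForMesh(x, spacing = c(1, 1, 1), margin = 5)
    x <- rasterizeMesh(x, grid)$mask
  }
  mask <- imgData(x) > 0.5
  d <- dim(x); sp <- spacing(x); or <- origin(x)
  if (!any(mask)) stop("empty mask")
  inv <- imageVolume(1 - mask, sp, or)
  dt <- imgData(distanceTransform(inv, "mm"))  # distance to background
  dmax <- max(dt[mask])
  # connectivity check via one geodesic sweep
  unit <- array(1.0, d)
  seed <- which(mask & dt >= 0.9 * dmax)[1]
  sweep1 <- .mask_dijkstra(mask, as.integer(d), sp, unit, as.integer(seed), 0L)
  reach <- is.finite(sweep1$dist)
  dim(reach) <- d
  if (any(mask & !reach)) stop("mask is not a single connected component")
  e1 <- as.integer(sweep1$far)
  sweep2 <- .mask_dijkstra(mask, as.integer(d), sp, unit, e1, 0L)
  e2 <- as.integer(sweep2$far)
  # ridge-hugging weights: cheap where the inscribed sphere is large
  w <- array(1.0, d)
  w[mask] <- (1 + (dmax - dt[mask]) / dmax * 60)^2
  path <- .mask_dijkstra(mask, as.integer(d), sp, w, e1, e2)$path
  pidx <- arrayInd(as.integer(path), d)
  pw <- sweep(sweep(pidx - 1, 2, sp, "*"), 2, or, "+")
  # arc-length parameter along the raw voxel path
  seg <- sqrt(rowSums(diff(pw)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  trim <- max(trim, 1.6 * dmax)
  if (L <= 2 * trim + 4 * step) stop("object too short for centerline analysis")
  # drop the path ends before fitting: near the object ends the geodesic
  # endpoints sit at cap corners, not on the lumen axis
  keep <- s >= trim & s <= L - trim
  pw <- pw[keep, , drop = FALSE]
  s <- s[keep] - min(s[keep])
  L <- max(s)
  df <- max(4, round(smoothDf * L / 100))
  sOut <- seq(0, L, by = step)
  fit <- lapply(1:3, function(c) stats::smooth.spline(s, pw[, c], df = df))
  pts <- sapply(fit, function(f) stats::predict(f, sOut)$y)
  tang <- sapply(fit, function(f) stats::predict(f, sOut, deriv = 1)$y)
  tang <- tang / sqrt(rowSums(tang^2))
  # reparameterize by actual arc length of the smoothed curve
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  new("CenterlineCurve", points = pts, arcLength = arc, tangents = tang)
}

# intersect mesh with the plane through p0 with normal nrm; returns the
# closed contour (loop of points) nearest to p0, or NULL if ill-defined
.sectionContour <- function(v, f, p0, nrm) {
  dist <- as.vector((v - matrix(p0, nrow(v), 3, byrow = TRUE)) %*% nrm)
  dist[dist == 0] <- 1e-9   # vertices exactly on the plane
  d1 <- dist[f[, 1]]; d2 <- dist[f[, 2]]; d3 <- dist[f[, 3]]
  crossed <- (pmin(d1, d2, d3) < 0) & (pmax(d1, d2, d3) > 0)
  if (!any(crossed)) return(NULL)
  fc <- f[crossed, , drop = FALSE]
  dc <- cbind(d1, d2, d3)[crossed, , drop = FALSE]
  # for each crossed face, find its two crossed edges and intersection points
  edges <- rbind(c(1, 2), c(2, 3), c(3, 1))
  segA <- matrix(NA_real_, nrow(fc), 3)
  segB <- matrix(NA_real_, nrow(fc), 3)
  keyA <- keyB <- character(nrow(fc))
  for (r in seq_len(nrow(fc))) {
    pts <- list(); keys <- character(0)
    for (e in 1:3) {
      i <- edges[e, 1]; j <- edges[e, 2]
      di <- dc[r, i]; dj <- dc[r, j]
      if ((di < 0 && dj >= 0) || (dj < 0 && di >= 0)) {
        t <- di / (di - dj)
        p <- v[fc[r, i], ] + t * (v[fc[r, j], ] - v[fc[r, i], ])
        pts[[length(pts) + 1]] <- p
        a <- min(fc[r, i], fc[r, j]); b <- max(fc[r, i], fc[r, j])
        keys <- c(keys, paste0(a, "_", b))
      }
    }
    if (length(pts) != 2) return(NULL)
    segA[r, ] <- pts[[1]]; segB[r, ] <- pts[[2]]
    keyA[r] <- keys[1]; keyB[r] <- keys[2]
  }
  # chain segments into loops via shared edge keys (union-find)
  allKeys <- unique(c(keyA, keyB))
  parent <- seq_along(allKeys)
  names(parent) <- allKeys
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ka <- match(keyA, allKeys); kb <- match(keyB, allKeys)
  for (r in seq_len(nrow(fc))) {
    ra <- find(ka[r]); rb <- find(kb[r])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_along(allKeys), find, 0L)
  segComp <- comp[ka]
  # pick the loop whose centroid is nearest the station point
  best <- NULL; bestD <- Inf
  for (cid in unique(segComp)) {
    rows <- segComp == cid
    pts <- rbind(segA[rows, , drop = FALSE], segB[rows, , drop = FALSE])
    ctr <- colMeans(pts)
    dd <- sum((ctr - p0)^2)
    if (dd < bestD) { bestD <- dd; best <- pts }
  }
  best
}

#' Maximal cross-section diameter profile along a centerline
#'
#' At each \code{step}-mm station the mesh is cut with the plane orthogonal
#' to the centerline tangent; the diameter is the maximal chord of the
#' section contour nearest the centerline (sections that are open or absent
#' are flagged NA rather than fatal).
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param centerline a \linkS4class{CenterlineCurve} inside the mesh.
#' @param step station spacing (mm).
#' @return A \linkS4class{DiameterProfile}.
#' @export
diameterProfile <- function(mesh, centerline, step = 0.5) {
  L <- max(centerline@arcLength)
  stations <- seq(0, L, by = step)
  ci <- .centerlineAt(centerline, stations)
  v <- vertices(mesh); f <- faces(mesh)
  dvec <- rep(NA_real_, length(stations))
  for (i in seq_along(stations)) {
    contour <- .sectionContour(v, f, ci$points[i, ], ci$tangents[i, ])
    if (is.null(contour) || nrow(contour) < 3) next
    # maximal chord via 2D convex hull in the section plane
    nrm <- ci$tangents[i, ]
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2], nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    rel <- sweep(contour, 2, ci$points[i, ], "-")
    xy <- cbind(rel %*% e1, rel %*% e2)
    hull <- grDevices::chull(xy)
    hp <- xy[hull, , drop = FALSE]
    dvec[i] <- sqrt(max(as.vector(stats::dist(hp))^2))
  }
  new("DiameterProfile", stations = stations, d = dvec)
}

#' Maximal diameter change between two profiles
#'
#' @param fixedProfile,movingProfile \linkS4class{DiameterProfile}s on the
#'   same stations (both measured against the fixed centerline).
#' @return list(magnitude, location, index, profileFixed, profileMoving);
#'   ties break toward the smaller arc length.
#' @export
maxDiameterChange <- function(fixedProfile, movingProfile) {
  if (length(fixedProfile@stations) != length(movingProfile@stations) ||
      max(abs(fixedProfile@stations - movingProfile@stations)) > 1e-6)
    stop("profiles are not on the same stations")
  dd <- abs(fixedProfile@d - movingProfile@d)
  ok <- which(!is.na(dd))
  if (!length(ok)) stop("no valid stations")
  i <- ok[which.max(dd[ok])]   # which.max takes the first maximum: ties
  list(magnitude = dd[i], location = fixedProfile@stations[i], index = i,
       profileFixed = fixedProfile, profileMoving = movingProfile)
}

#' VDM-based maximal diameter change
#'
#' Warps the fixed mesh with a registration-derived displacement field and
#' measures the diameter-change profile against the fixed mesh on the same
#' fixed centerline, mirroring the ground-truth measurement.
#'
#' @param fixedMesh fixed \linkS4class{SurfaceMesh}.
#' @param field \linkS4class{DisplacementField} from \code{\link{runVDM}}.
#' @param centerline fixed-anatomy \linkS4class{CenterlineCurve}.
#' @param step station spacing (mm).
#' @return As \code{\link{maxDiameterChange}}.
#' @export
vdmDiameterChange <- function(fixedMesh, field, centerline, step = 0.5) {
  moved <- warpMesh(field, fixedMesh)
  pf <- diameterProfile(fixedMesh, centerline, step)
  pm <- diameterProfile(moved, centerline, step)
  maxDiameterChange(pf, pm)
}
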