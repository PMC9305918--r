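#' Ground-truth displacement fields from boundary images
#'
#' Given corresponding fixed and deformed meshes, the experiment's declared
#' ground truth is not the analytic vertex displacement but the displacement
#' field recovered by registering blurred "boundary images" of the two
#' vertex clouds - mirroring how the synthetic moving image is manufactured,
#' so the measured field and the images it explains are exactly concordant.
#'
#' @name groundTruth
NULL

# barycentric subsampling of every face so that sub-edges are <= maxEdge;
# returns the original vertices plus the face-interior sample points
.surfaceSamplePoints <- function(mesh, maxEdge) {
  v <- vertices(mesh); f <- faces(mesh)
  e <- pmax(sqrt(rowSums((v[f[, 1], ] - v[f[, 2], ])^2)),
            sqrt(rowSums((v[f[, 2], ] - v[f[, 3], ])^2)),
            sqrt(rowSums((v[f[, 3], ] - v[f[, 1], ])^2)))
  lev <- pmax(1L, as.integer(ceiling(e / maxEdge)))
  out <- list(v)
  for (L in sort(unique(lev[lev > 1L]))) {
    idx <- which(lev == L)
    bc <- expand.grid(i = 0:L, j = 0:L)
    bc <- bc[bc$i + bc$j <= L, ]
    W <- cbind(bc$i, bc$j, L - bc$i - bc$j) / L
    # skip pure corners (already present as vertices)
    W <- W[rowSums(W == 1) == 0, , drop = FALSE]
    if (!nrow(W)) next
    a <- v[f[idx, 1], , drop = FALSE]
    b <- v[f[idx, 2], , drop = FALSE]
    cc <- v[f[idx, 3], , drop = FALSE]
    for (r in seq_len(nrow(W)))
      out[[length(out) + 1]] <- W[r, 1] * a + W[r, 2] * b + W[r, 3] * cc
  }
  do.call(rbind, out)
}

#' Convert a mesh to a binary boundary image
#'
#' Voxels containing at least one mesh vertex are set to one, all others to
#' zero (nearest-voxel assignment; multiple vertices in one voxel count
#' once). With \code{maxEdge} set, each face is additionally subsampled on
#' a barycentric lattice until sub-edges fall below \code{maxEdge}, so the
#' surface saturates the voxel shell regardless of how much the mesh has
#' been stretched - this removes the vertex-density imprint that otherwise
#' biases the boundary registration.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param grid list(dim, spacing, origin) or an \linkS4class{ImageVolume}
#'   providing the grid.
#' @param maxEdge optional surface sampling pitch (mm); NULL = vertices only.
#' @return Binary \linkS4class{ImageVolume}.
#' @export
meshToBoundaryImage <- function(mesh, grid, maxEdge = NULL) {
  if (is(grid, "ImageVolume"))
    grid <- list(dim = dim(grid), spacing = spacing(grid), origin = origin(grid))
  v <- if (is.null(maxEdge)) vertices(mesh)
       else .surfaceSamplePoints(mesh, maxEdge)
  ci <- round(sweep(sweep(v, 2, grid$origin, "-"), 2, grid$spacing, "/"))
  bad <- which(ci[, 1] < 0 | ci[, 2] < 0 | ci[, 3] < 0 |
               ci[, 1] >= grid$dim[1] | ci[, 2] >= grid$dim[2] |
               ci[, 3] >= grid$dim[3])
  if (length(bad))
    stop("vertices outside grid: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  arr <- array(0, grid$dim)
  arr[1 + ci[, 1] + grid$dim[1] * (ci[, 2] + grid$dim[2] * ci[, 3])] <- 1
  imageVolume(arr, grid$spacing, grid$origin)
}

#' Blur a boundary image
#'
#' Gaussian blur (sigma in voxels, default 5) softening the binary vertex
#' occupancy so that a gradient-driven registration has capture range.
#' Mass-conserving for interior support.
#'
#' @param b boundary \linkS4class{ImageVolume}.
#' @param sigma Gaussian standard deviation in voxels.
#' @return Smooth nonnegative \linkS4class{ImageVolume}.
#' @export
blurBoundary <- function(b, sigma = 5) {
  if (sigma <= 0) stop("sigma must be > 0")
  gaussianSmooth(b, sigma, units = "voxels", renorm = FALSE)
}

#' Register two blurred boundary images
#'
#' Single-stage B-spline registration minimizing the mean squared
#' difference plus a bending-energy penalty. Follows the standard
#' convention: the returned field lives on the fixed image's grid and maps
#' fixed-space points to moving-space points.
#'
#' @param moving,fixed blurred boundary images on the same grid.
#' @param controlSpacing final B-spline control spacing (mm).
#' @param coarseSpacing control spacing (mm) of an optional preliminary
#'   pass that captures large smooth displacement (e.g. respiratory drag)
#'   before the fine pass; NULL skips it.
#' @param bendingWeight bending-energy weight (on intensity-normalized
#'   images). Besides smoothness, this pins the components of the motion
#'   that a featureless tube surface cannot determine (tangential sliding).
#' @param levels,maxIter,sampleCap optimizer settings.
#' @param initDisp length-3 initial translation (mm) seeded into the
#'   B-spline; a penalty-free constant that supplies capture range for
#'   large bulk displacement of the surface.
#' @return A \linkS4class{DisplacementField}; \code{meta$trace} records
#'   per-pass, per-level final costs, and \code{meta$converged} is FALSE if
#'   the final pass failed to decrease its cost.
#' @export
registerBoundaries <- function(moving, fixed, controlSpacing = 8,
                               coarseSpacing = NULL, bendingWeight = 0.5,
                               levels = 2, maxIter = 200, sampleCap = 20000,
                               initDisp = c(0, 0, 0)) {
  stopifnot(.sameGrid(moving, fixed))
  supp <- imgData(fixed) + imgData(moving) > 1e-4 * max(imgData(fixed))
  reg <- .bboxRegion(imageVolume(supp * 1, spacing(fixed), origin(fixed)),
                     margin = 4)
  spacings <- c(coarseSpacing[coarseSpacing > controlSpacing], controlSpacing)
  d <- dim(fixed)
  pts <- .gridPoints(fixed)
  compose <- function(ffds, at) {
    y <- at
    for (f in rev(ffds)) y <- y + .ffdEval(f, y)
    y
  }
  ffds <- list()
  traces <- list()
  movingCur <- moving
  for (k in seq_along(spacings)) {
    ffd <- .ffdRegister(fixed, movingCur, metric = "SSD",
                        controlSpacing = spacings[k],
                        beWeight = bendingWeight, simRegion = reg,
                        levels = levels, maxIter = maxIter,
                        sampleCap = sampleCap,
                        initDisp = if (k == 1) initDisp else c(0, 0, 0))
    ffds[[k]] <- ffd
    traces[[k]] <- ffd$trace
    if (k < length(spacings)) {
      y <- compose(ffds, pts)
      movingCur <- imageVolume(array(sampleVolume(moving, y, "linear"), d),
                               spacing(fixed), origin(fixed))
    }
  }
  finalTr <- ffds[[length(ffds)]]$trace
  conv <- finalTr[[length(finalTr)]][["convergence"]] %in% c(0, 1)
  u <- compose(ffds, pts) - pts
  fld <- displacementField(array(u, c(d, 3)), spacing(fixed), origin(fixed),
                           meta = list(stage = "boundary", trace = traces,
                                       converged = conv))
  attr(fld, "ffd") <- list(passes = ffds)
  fld
}

#' Synthesize the ground-truth field and synthetic moving data
#'
#' Builds blurred boundary images of the fixed and deformed meshes,
#' registers them with the deformed boundary as the fixed image (so the
#' recovered transform pulls fixed-space anatomy onto the deformed
#' anatomy by standard resampling), creates the synthetic moving image and
#' mask that way, and numerically inverts the transform to obtain the
#' declared ground-truth field in the package's fixed-to-moving convention.
#' Warping the fixed mesh with the returned field yields the mesh that is
#' exactly concordant with the synthetic moving image.
#'
#' @param fixedMesh,deformedMesh corresponding meshes (same connectivity).
#' @param image,mask fixed CT-like image and mask
#'   (\linkS4class{ImageVolume}s on a common grid).
#' @param sigma boundary blur in voxels.
#' @param maxEdge surface sampling pitch for the boundary images (mm);
#'   default half the smallest voxel side, which saturates the voxel shell
#'   and removes the vertex-density imprint of stretched faces.
#' @param window radial support of the synthesized deformation, as
#'   c(inner, outer) distances (mm) from the vessel surface: the field is
#'   kept as recovered within \code{inner}, blended smoothly to identity
#'   beyond \code{outer}. Deformation and physiologic displacement are
#'   local tissue phenomena; without the window the bending-regularized
#'   registration extrapolates them as a constant (zero-cost) translation
#'   of all distant tissue, which no anatomy does. NULL disables.
#' @param ... passed to \code{\link{registerBoundaries}}.
#' @return list with elements \code{field} (ground-truth
#'   \linkS4class{DisplacementField}, fixed to moving), \code{movingImage},
#'   \code{movingMask}, \code{gtMesh} (fixed mesh warped by \code{field}),
#'   and \code{boundaryField} (the raw deformed-to-fixed registration).
#' @export
makeGroundTruth <- function(fixedMesh, deformedMesh, image, mask, sigma = 2,
                            maxEdge = NULL, window = NULL, ...) {
  grid <- list(dim = dim(image), spacing = spacing(image), origin = origin(image))
  if (is.null(maxEdge)) maxEdge <- 0.5 * min(grid$spacing)
  B <- blurBoundary(meshToBoundaryImage(fixedMesh, grid, maxEdge), sigma)
  Bd <- blurBoundary(meshToBoundaryImage(deformedMesh, grid, maxEdge), sigma)
  # deformed boundary as fixed: T' maps deformed space -> fixed space;
  # the mesh-centroid offset seeds the optimization (capture range for
  # respiratory-scale bulk displacement of the surface)
  ctrOff <- colMeans(vertices(fixedMesh)) - colMeans(vertices(deformedMesh))
  back <- registerBoundaries(moving = B, fixed = Bd, initDisp = ctrOff, ...)
  if (!is.null(window)) {
    shells <- imageVolume(
      pmin(imgData(meshToBoundaryImage(fixedMesh, grid, maxEdge)) +
           imgData(meshToBoundaryImage(deformedMesh, grid, maxEdge)), 1),
      grid$spacing, grid$origin)
    dshell <- imgData(distanceTransform(shells, "mm"))
    w <- array(1, grid$dim)
    ramp <- dshell > window[1] & dshell < window[2]
    w[ramp] <- cos(pi / 2 * (dshell[ramp] - window[1]) /
                   (window[2] - window[1]))^2
    w[dshell >= window[2]] <- 0
    for (c in 1:3) back@field[, , , c] <- back@field[, , , c] * w
  }
  movingImage <- warpImage(back, image, interpolation = "cubic")
  movingMask <- warpImage(back, mask, mask = TRUE)
  field <- invertDisplacementField(back)
  field@meta$trace <- back@meta$trace
  field@meta$converged <- back@meta$converged
  gtMesh <- warpMesh(field, fixedMesh)
  list(field = field, movingImage = movingImage, movingMask = movingMask,
       gtMesh = gtMesh, boundaryField = back)
}
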