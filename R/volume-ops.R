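#' Clamp negative intensities to zero
#'
#' Applied to both CT inputs before registration so that low-attenuation
#' lung tissue does not dominate the similarity metric.
#'
#' @param vol an \linkS4class{ImageVolume} (HU-valued).
#' @return An \linkS4class{ImageVolume} with \code{max(value, 0)} voxel-wise.
#' @export
clampNegative <- function(vol) {
  imageVolume(pmax(imgData(vol), 0), spacing(vol), origin(vol))
}

#' Separable Gaussian smoothing
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param sigma standard deviation; scalar or length 3.
#' @param units "voxels" or "mm".
#' @param renorm renormalize the kernel near the volume edges (avoids edge
#'   dimming for images; keep FALSE for mass-conserving smoothing).
#' @return Smoothed \linkS4class{ImageVolume}.
#' @export
gaussianSmooth <- function(vol, sigma, units = c("voxels", "mm"),
                           renorm = FALSE) {
  units <- match.arg(units)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  sv <- if (units == "mm") sigma / spacing(vol) else sigma
  out <- .gauss_blur3(imgData(vol), as.integer(dim(vol)), as.numeric(sv), renorm)
  imageVolume(out, spacing(vol), origin(vol))
}

#' Distance to a mask
#'
#' Euclidean distance (in mm, or voxel units) from every voxel to the
#' nearest nonzero voxel of \code{mask}.
#'
#' @param mask binary \linkS4class{ImageVolume}.
#' @param units "mm" (anisotropy-aware) or "voxels".
#' @return \linkS4class{ImageVolume} of distances.
#' @export
distanceTransform <- function(mask, units = c("mm", "voxels")) {
  units <- match.arg(units)
  sp <- if (units == "mm") spacing(mask) else c(1, 1, 1)
  d <- .edt3(imgData(mask) > 0.5, as.integer(dim(mask)), as.numeric(sp))
  imageVolume(d, spacing(mask), origin(mask))
}

#' Morphological dilation/erosion of a binary mask
#'
#' Euclidean-ball structuring element of the given radius, implemented by
#' thresholding the distance transform.
#'
#' @param mask binary \linkS4class{ImageVolume}.
#' @param radius radius of the ball.
#' @param units "voxels" or "mm".
#' @return Binary \linkS4class{ImageVolume}.
#' @export
dilateMask <- function(mask, radius, units = c("voxels", "mm")) {
  units <- match.arg(units)
  if (radius <= 0) return(mask)
  d <- distanceTransform(mask, units = if (units == "mm") "mm" else "voxels")
  imageVolume((imgData(d) <= radius) * 1.0, spacing(mask), origin(mask))
}

#' @rdname dilateMask
#' @export
erodeMask <- function(mask, radius, units = c("voxels", "mm")) {
  units <- match.arg(units)
  if (radius <= 0) return(mask)
  inv <- imageVolume(1 - (imgData(mask) > 0.5), spacing(mask), origin(mask))
  d <- distanceTransform(inv, units = if (units == "mm") "mm" else "voxels")
  keep <- (imgData(mask) > 0.5) & (imgData(d) > radius)
  imageVolume(keep * 1.0, spacing(mask), origin(mask))
}

#' Resample an image at arbitrary world points
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param pts N x 3 matrix of world coordinates (mm).
#' @param interpolation "nearest", "linear" or "cubic".
#' @return numeric vector of sampled values (clamped-edge extrapolation).
#' @export
sampleVolume <- function(vol, pts, interpolation = c("linear", "nearest", "cubic")) {
  interpolation <- match.arg(interpolation)
  code <- c(nearest = 0L, linear = 1L, cubic = 3L)[[interpolation]]
  .warp_at_points(imgData(vol), as.integer(dim(vol)), spacing(vol), origin(vol),
                  rbind(pts), code)
}

#' Warp an image with a displacement field
#'
#' Pull-back resampling on the field's grid: \code{out(x) = img(x + u(x))}.
#' With the package's fixed-to-moving field convention this resamples a
#' moving-space image onto the fixed grid.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param img the image to resample.
#' @param interpolation "cubic" for images (default), "linear", or "nearest";
#'   binary masks use linear-then-threshold via \code{mask = TRUE}.
#' @param mask logical: treat \code{img} as a binary mask (linear
#'   interpolation thresholded at 0.5).
#' @return \linkS4class{ImageVolume} on the field's grid.
#' @export
warpImage <- function(field, img, interpolation = c("cubic", "linear", "nearest"),
                      mask = FALSE) {
  interpolation <- match.arg(interpolation)
  d <- dim(field)
  grid <- imageVolume(array(0, d), spacing(field), origin(field))
  pts <- .gridPoints(grid)
  u <- matrix(field@field, ncol = 3)
  vals <- sampleVolume(img, pts + u,
                       interpolation = if (mask) "linear" else interpolation)
  if (mask) vals <- (vals >= 0.5) * 1.0
  imageVolume(array(vals, d), spacing(field), origin(field))
}

#' Warp a mesh with a displacement field
#'
#' Each vertex moves by the field interpolated (trilinearly) at its
#' position; connectivity is untouched, preserving vertex correspondence.
#'
#' @param field a \linkS4class{DisplacementField} (fixed -> moving).
#' @param mesh a \linkS4class{SurfaceMesh} in fixed space.
#' @param strict error if any vertex lies outside the field domain.
#' @return The warped \linkS4class{SurfaceMesh}.
#' @export
warpMesh <- function(field, mesh, strict = TRUE) {
  v <- vertices(mesh)
  if (strict) {
    lo <- origin(field); hi <- origin(field) + (dim(field) - 1) * spacing(field)
    out <- which(v[, 1] < lo[1] | v[, 2] < lo[2] | v[, 3] < lo[3] |
                 v[, 1] > hi[1] | v[, 2] > hi[2] | v[, 3] > hi[3])
    if (length(out))
      stop("vertices outside field domain: ", paste(utils::head(out, 5), collapse = ", "),
           if (length(out) > 5) " ..." else "")
  }
  u <- .field_at_points(field@field, as.integer(dim(field)), spacing(field),
                        origin(field), v)
  surfaceMesh(v + u, faces(mesh), meshMeta(mesh))
}

#' Evaluate a displacement field at points
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param pts N x 3 world coordinates.
#' @return N x 3 matrix of displacements (mm).
#' @export
fieldAtPoints <- function(field, pts) {
  .field_at_points(field@field, as.integer(dim(field)), spacing(field),
                   origin(field), rbind(pts))
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the field v with (x + u) followed by (x + v)
#' equal to the identity; accurate for smooth, non-folding fields.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param iters fixed-point iterations.
#' @return The inverse \linkS4class{DisplacementField} on the same grid.
#' @export
invertDisplacementField <- function(field, iters = 20L) {
  inv <- .invert_field(field@field, as.integer(dim(field)), spacing(field),
                       origin(field), as.integer(iters))
  displacementField(inv, spacing(field), origin(field),
                    meta = list(invertedFrom = field@meta))
}

#' Jacobian determinant of a displacement field
#'
#' Local volume-change factor of the map x + u(x), by central differences.
#' Positivity everywhere means the transform does not fold.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @return \linkS4class{ImageVolume} of determinant values.
#' @export
jacobianDeterminant <- function(field) {
  jd <- .jacobian_det(field@field, as.integer(dim(field)), spacing(field))
  imageVolume(jd, spacing(field), origin(field))
}
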