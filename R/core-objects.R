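#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm (length 3 or scalar).
#' @param origin world coordinate (mm) of the first voxel center.
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' vol <- imageVolume(array(0, c(8, 8, 8)), spacing = 1)
#' dim(vol)
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "double"
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a SurfaceMesh
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 matrix of 1-based vertex indices.
#' @param meta optional list of per-vertex annotations.
#' @return A \linkS4class{SurfaceMesh}.
#' @export
surfaceMesh <- function(vertices, faces, meta = list()) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = vertices, faces = faces, meta = meta)
}

#' Construct a DisplacementField
#'
#' @param field 4D array (nx, ny, nz, 3) of displacements in mm
#'   (fixed-space point x corresponds to x + u(x) in moving space).
#' @param spacing,origin grid geometry (mm).
#' @param meta optional metadata list.
#' @return A \linkS4class{DisplacementField}.
#' @export
displacementField <- function(field, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                              meta = list()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(field) <- "double"
  new("DisplacementField", field = field, spacing = as.numeric(spacing),
      origin = as.numeric(origin), meta = meta)
}

#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 rotation matrix, or NULL for identity.
#' @param translation,center length-3 vectors (mm).
#' @return A \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(rotation = NULL, translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  if (is.null(rotation)) rotation <- diag(3)
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation), center = as.numeric(center))
}

#' Rotation matrix from per-axis Euler angles
#'
#' Composes Rz %*% Ry %*% Rx from rotations about the x, y and z axes.
#'
#' @param angles length-3 vector of angles in radians.
#' @return 3 x 3 rotation matrix.
#' @export
eulerRotation <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Construct an intensity model for phantom rasterization
#'
#' Defaults put contrast-filled lumen at 350 HU on a 40 HU soft-tissue
#' background overlaid with smooth random heterogeneity (standard deviation
#' \code{textureSD}, correlation length \code{textureScale}) that emulates
#' the mediastinal fat/muscle/vessel mosaic around the aorta. The texture
#' matters: static background structure is what anchors the rigid
#' alignment when the aorta itself moves (respiration), exactly as the
#' thoracic anatomy does in clinical scans. No baseline noise is added
#' (noise is a perturbation, not part of the clean phantom).
#'
#' @param lumenHU,backgroundHU mean intensities (HU).
#' @param supersampling linear boundary antialiasing factor (>= 1).
#' @param textureSD standard deviation of the background heterogeneity
#'   (HU); 0 disables.
#' @param textureScale correlation length of the heterogeneity (mm).
#' @param seed seed for the texture field.
#' @return An \linkS4class{IntensityModel}.
#' @export
intensityModel <- function(lumenHU = 350, backgroundHU = 40, supersampling = 3,
                           textureSD = 35, textureScale = 8, seed = 1L) {
  new("IntensityModel", lumenHU = lumenHU, backgroundHU = backgroundHU,
      supersampling = supersampling, textureSD = textureSD,
      textureScale = textureScale, seed = as.numeric(seed))
}

#' @describeIn ImageVolume-accessors the raw 3D array
#' @param x object.
#' @export
setMethod("imgData", "ImageVolume", function(x) x@data)

#' @describeIn ImageVolume-accessors voxel spacing (mm)
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)

#' @describeIn ImageVolume-accessors world coordinate of the first voxel center
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)

#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

#' @describeIn SurfaceMesh-accessors vertex coordinate matrix
#' @param x object.
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)

#' @describeIn SurfaceMesh-accessors face index matrix
#' @export
setMethod("faces", "SurfaceMesh", function(x) x@faces)

#' @describeIn SurfaceMesh-accessors annotation list
#' @export
setMethod("meshMeta", "SurfaceMesh", function(x) x@meta)

#' @describeIn DisplacementField-accessors the (nx,ny,nz,3) displacement array
#' @param x object.
#' @export
setMethod("fieldArray", "DisplacementField", function(x) x@field)

#' @export
setMethod("spacing", "DisplacementField", function(x) x@spacing)

#' @export
setMethod("origin", "DisplacementField", function(x) x@origin)

#' @export
setMethod("dim", "DisplacementField", function(x) dim(x@field)[1:3])

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %d x %d x %d, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              paste(signif(object@origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces", nrow(object@vertices),
              nrow(object@faces)))
  if (length(object@meta)) cat(sprintf(", meta: %s",
                                       paste(names(object@meta), collapse = ", ")))
  cat("\n")
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@field)
  mg <- sqrt(object@field[, , , 1]^2 + object@field[, , , 2]^2 +
             object@field[, , , 3]^2)
  cat(sprintf("DisplacementField %d x %d x %d (fixed -> moving), |u| max %.3g mm\n",
              d[1], d[2], d[3], max(mg)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.3g deg, translation (%s) mm\n", ang,
              paste(signif(object@translation, 4), collapse = ", ")))
})

setMethod("show", "CenterlineCurve", function(object) {
  cat(sprintf("CenterlineCurve: %d points, length %.1f mm\n",
              nrow(object@points), max(object@arcLength)))
})

# ---- internal grid helpers ----

# world coordinates of all voxel centers, as an (nvox x 3) matrix
.gridPoints <- function(vol) {
  d <- dim(vol)[1:3]
  sp <- spacing(vol); or <- origin(vol)
  xs <- or[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- or[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- or[3] + (seq_len(d[3]) - 1) * sp[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

# world -> continuous 0-based voxel index
.worldToIndex <- function(vol, pts) {
  sweep(sweep(pts, 2, origin(vol), "-"), 2, spacing(vol), "/")
}

.sameGrid <- function(a, b, tol = 1e-6) {
  all(dim(a)[1:3] == dim(b)[1:3]) &&
    max(abs(spacing(a) - spacing(b))) < tol &&
    max(abs(origin(a) - origin(b))) < tol
}

#' Apply a rigid transform to points
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param pts N x 3 matrix of world points (mm).
#' @return transformed N x 3 matrix.
#' @export
applyRigidTransform <- function(transform, pts) {
  pts <- rbind(pts)  # accept a single point as a vector
  ctr <- transform@center
  sweep(sweep(pts, 2, ctr, "-") %*% t(transform@rotation), 2,
        ctr + transform@translation, "+")
}

#' Invert a rigid transform
#' @param transform a \linkS4class{RigidTransform}.
#' @return the inverse \linkS4class{RigidTransform} (same center).
#' @export
invertRigidTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, translation = -as.numeric(Rt %*% transform@translation),
                 center = transform@center)
}
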