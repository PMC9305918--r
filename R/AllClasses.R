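#' @import methods
NULL

#' 3D scalar image volume
#'
#' A scalar 3D grid (CT-angiography-like, usually Hounsfield units) with
#' axis-aligned world geometry: world coordinate of voxel \code{(i,j,k)}
#' (1-based) is \code{origin + (c(i,j,k) - 1) * spacing}, in millimeters.
#'
#' @slot data 3D numeric array.
#' @slot spacing voxel spacing in mm (length 3, positive).
#' @slot origin world coordinate (mm) of the center of the first voxel.
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive numbers")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be 3 finite numbers")
    TRUE
  })

#' Indexed triangle mesh in world millimeters
#'
#' Vertex order is meaningful: deformed copies of a mesh keep identical
#' vertex count and order, so vertex-wise correspondence is positional.
#'
#' @slot vertices N x 3 numeric matrix (mm).
#' @slot faces M x 3 integer matrix of 1-based vertex indices.
#' @slot meta list of optional per-vertex annotations (e.g. tube coordinates
#'   \code{s}, \code{theta}, outward radial directions, analytic displacement).
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", meta = "list"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    if (ncol(v) != 3L) return("vertices must be N x 3")
    if (ncol(f) != 3L) return("faces must be M x 3")
    if (any(f < 1L) || any(f > nrow(v))) return("face index out of range")
    TRUE
  })

#' Dense displacement field on an image grid
#'
#' Maps fixed-space points to moving-space points: a point \code{x} in the
#' fixed image corresponds to \code{x + u(x)} in the moving image. The same
#' field both transports fixed-surface vertices onto the moving anatomy and
#' pulls the moving image back onto the fixed grid.
#'
#' @slot field 4D numeric array (nx, ny, nz, 3), displacement in mm.
#' @slot spacing,origin grid geometry as in \linkS4class{ImageVolume}.
#' @slot meta list: optimizer traces, convergence flags, stage parameters.
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(field = "array", spacing = "numeric", origin = "numeric",
                 meta = "list"),
  validity = function(object) {
    d <- dim(object@field)
    if (length(d) != 4L || d[4] != 3L) return("field must be (nx,ny,nz,3)")
    if (any(!is.finite(object@field))) return("field must be finite")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive numbers")
    TRUE
  })

#' Rigid transform (rotation about a center plus translation)
#'
#' Maps \code{x} to \code{R (x - center) + center + translation}.
#'
#' @slot rotation 3 x 3 orthonormal matrix with det = +1.
#' @slot translation,center length-3 vectors (mm).
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 center = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation not orthonormal")
    if (det(R) < 0) return("rotation must be proper (det = +1)")
    TRUE
  })

#' Discretized centerline curve
#'
#' @slot points P x 3 matrix of ordered samples (mm).
#' @slot arcLength cumulative arc length per point (mm), strictly increasing.
#' @slot tangents P x 3 unit tangent vectors.
#' @exportClass CenterlineCurve
setClass("CenterlineCurve",
  representation(points = "matrix", arcLength = "numeric", tangents = "matrix"),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 3L) return("points must be P x 3")
    if (length(object@arcLength) != nrow(p)) return("arcLength length mismatch")
    if (any(diff(object@arcLength) <= 0)) return("arcLength must be strictly increasing")
    nrm <- sqrt(rowSums(object@tangents^2))
    if (any(abs(nrm - 1) > 1e-9)) return("tangents must be unit norm")
    TRUE
  })

#' Intensity model for phantom rasterization
#'
#' @slot lumenHU mean intensity of the contrast-filled lumen (HU).
#' @slot backgroundHU mean intensity of the surrounding soft tissue (HU).
#' @slot supersampling linear supersampling factor for partial-volume
#'   antialiasing at the lumen boundary (>= 1).
#' @slot textureSD,textureScale amplitude (HU) and correlation length (mm)
#'   of the smooth background heterogeneity (soft-tissue mosaic).
#' @slot seed seed for the texture field.
#' @exportClass IntensityModel
setClass("IntensityModel",
  representation(lumenHU = "numeric", backgroundHU = "numeric",
                 supersampling = "numeric", textureSD = "numeric",
                 textureScale = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@lumenHU <= object@backgroundHU)
      return("lumenHU must exceed backgroundHU (contrast present)")
    if (object@supersampling < 1) return("supersampling must be >= 1")
    if (object@textureSD < 0) return("textureSD must be >= 0")
    TRUE
  })

#' Configuration of one registration stage
#'
#' @slot similarity "NCC", "MI" or "SSD".
#' @slot bendingWeight,rigidityWeight penalty weights (>= 0).
#' @slot controlSpacing B-spline control-point spacing (mm).
#' @slot levels number of multiresolution levels.
#' @slot maxIter optimizer iterations per level.
#' @slot sampleCap maximum number of similarity samples per level.
#' @exportClass StageConfig
setClass("StageConfig",
  representation(similarity = "character", bendingWeight = "numeric",
                 rigidityWeight = "numeric", controlSpacing = "numeric",
                 levels = "numeric", maxIter = "numeric", sampleCap = "numeric"),
  validity = function(object) {
    if (!object@similarity %in% c("NCC", "MI", "SSD"))
      return("similarity must be NCC, MI or SSD")
    if (object@bendingWeight < 0 || object@rigidityWeight < 0)
      return("penalty weights must be >= 0")
    if (object@controlSpacing <= 0) return("controlSpacing must be > 0")
    TRUE
  })

#' Per-face and per-vertex growth metrics
#'
#' @slot ar per-face area ratio (dimensionless; 1 = no areal change).
#' @slot din per-vertex signed deformation in the fixed-surface normal
#'   direction (mm; outward growth positive).
#' @slot arOnVertices area-weighted interpolation of \code{ar} onto vertices.
#' @slot displacement per-vertex displacement magnitude (mm).
#' @exportClass GrowthMetrics
setClass("GrowthMetrics",
  representation(ar = "numeric", din = "numeric", arOnVertices = "numeric",
                 displacement = "numeric"),
  validity = function(object) {
    if (any(object@ar <= 0)) return("area ratios must be positive")
    if (length(object@arOnVertices) != length(object@din))
      return("arOnVertices/din length mismatch")
    TRUE
  })

#' Arc-length-indexed maximal cross-section diameter profile
#'
#' @slot stations arc-length positions (mm), uniformly spaced.
#' @slot d maximal cross-section diameter per station (mm); NA where the
#'   section was ill-defined (flagged, e.g. near the tube ends).
#' @exportClass DiameterProfile
setClass("DiameterProfile",
  representation(stations = "numeric", d = "numeric"),
  validity = function(object) {
    if (length(object@stations) != length(object@d)) return("length mismatch")
    if (any(object@d[!is.na(object@d)] <= 0)) return("diameters must be positive")
    TRUE
  })
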