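#' Synthetic aortic growth phantoms
#'
#' The phantom generator builds a candy-cane shaped tube (ascending limb,
#' semicircular arch, descending limb) that emulates the thoracic aorta,
#' applies parametric growth deformations with exact vertex correspondence,
#' and rasterizes CT-like volumes with partial-volume antialiasing. Because
#' every deformation operator is analytic, the per-vertex ground-truth
#' displacement is known exactly and is carried in the mesh metadata.
#'
#' @name phantoms
NULL

#' Phantom specification
#'
#' @slot ascendingLength,descendingLength straight limb lengths (mm).
#' @slot archRadius radius of the semicircular arch (mm); 0 gives a straight
#'   tube of length \code{ascendingLength + descendingLength}.
#' @slot lumenRadius lumen radius (mm): a constant or a function of arc length.
#' @slot nCirc vertices per circumference ring.
#' @slot axialStep ring spacing along the centerline (mm).
#' @slot sampleStep centerline sampling step (mm, <= 0.5).
#' @slot deformations list of deformation descriptors (see
#'   \code{\link{makeGrowthPhantom}}).
#' @slot wallIrregularity standard deviation (mm) of the smooth random
#'   radius variation that emulates the natural irregularity of a real
#'   aortic wall.
#' @slot seed integer seed for any randomized choices.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(ascendingLength = "numeric", archRadius = "numeric",
                 descendingLength = "numeric", lumenRadius = "ANY",
                 nCirc = "numeric", axialStep = "numeric",
                 sampleStep = "numeric", deformations = "list",
                 wallIrregularity = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@ascendingLength < 0 || object@descendingLength < 0 ||
        object@archRadius < 0)
      return("segment lengths must be >= 0")
    if (object@nCirc < 8) return("nCirc must be >= 8")
    if (object@axialStep <= 0 || object@axialStep > 2)
      return("axialStep must be in (0, 2] mm")
    for (d in object@deformations) {
      if (!is.null(d$magnitude) && d$magnitude < 0)
        return("deformation magnitudes must be >= 0")
      if (!is.null(d$extent) && d$extent <= 0)
        return("deformation extents must be > 0")
    }
    TRUE
  })

#' Create a phantom specification
#'
#' Defaults describe a desk-scale thoracic aorta: 45 mm ascending limb,
#' 25 mm arch radius (78.5 mm arch), 60 mm descending limb, 12 mm lumen
#' radius.
#'
#' @param ascendingLength,archRadius,descendingLength geometry (mm).
#' @param lumenRadius constant radius (mm), length-2 linear taper
#'   (proximal, distal), or function of arc length.
#' @param nCirc,axialStep,sampleStep mesh/curve discretization.
#' @param deformations list of deformation descriptors.
#' @param wallIrregularity sd (mm) of the smooth random radius variation;
#'   real aortic walls are not surfaces of revolution, and the gentle
#'   irregularity both looks clinical and anchors the tangential component
#'   of any registration against the surface (a perfectly smooth tube is
#'   rotation- and slide-degenerate).
#' @param seed integer seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(ascendingLength = 45, archRadius = 25,
                        descendingLength = 60, lumenRadius = 12,
                        nCirc = 32, axialStep = 1.5, sampleStep = 0.5,
                        deformations = list(), wallIrregularity = 0,
                        seed = 1L) {
  obj <- new("PhantomSpec", ascendingLength = ascendingLength,
             archRadius = archRadius, descendingLength = descendingLength,
             lumenRadius = lumenRadius, nCirc = nCirc, axialStep = axialStep,
             sampleStep = sampleStep, deformations = deformations,
             wallIrregularity = wallIrregularity, seed = as.numeric(seed))
  obj
}

#' Build the centerline curve of a phantom
#'
#' The curve starts at the bottom of the ascending limb, rises along +z,
#' turns through a semicircular arch in the x-z plane, and descends along
#' -z. Straight limbs are tangent to the arch, so the curve is C1.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{CenterlineCurve} sampled at \code{sampleStep} mm.
#' @export
makeCenterline <- function(spec) {
  La <- spec@ascendingLength; Ra <- spec@archRadius; Ld <- spec@descendingLength
  Larch <- pi * Ra
  Ltot <- La + Larch + Ld
  if (Ltot <= 0) stop("phantom centerline has zero length")
  s <- seq(0, Ltot, by = spec@sampleStep)
  if (s[length(s)] < Ltot - 1e-9) s <- c(s, Ltot)
  pts <- matrix(0, length(s), 3)
  tan <- matrix(0, length(s), 3)
  for (i in seq_along(s)) {
    si <- s[i]
    if (si <= La) {
      pts[i, ] <- c(0, 0, si)
      tan[i, ] <- c(0, 0, 1)
    } else if (si <= La + Larch && Ra > 0) {
      phi <- (si - La) / Ra
      pts[i, ] <- c(Ra - Ra * cos(phi), 0, La + Ra * sin(phi))
      tan[i, ] <- c(sin(phi), 0, cos(phi))
    } else {
      sd <- si - La - Larch
      pts[i, ] <- c(2 * Ra, 0, La - sd)
      tan[i, ] <- c(0, 0, -1)
    }
  }
  new("CenterlineCurve", points = pts, arcLength = s, tangents = tan)
}

# rotation-minimizing frames by the double-reflection method
.rmfFrames <- function(pts, tans) {
  n <- nrow(pts)
  n1 <- matrix(0, n, 3)
  t0 <- tans[1, ]
  ref <- if (abs(t0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * t0) * t0
  n1[1, ] <- v / sqrt(sum(v^2))
  for (i in seq_len(n - 1)) {
    v1 <- pts[i + 1, ] - pts[i, ]
    c1 <- sum(v1^2)
    if (c1 < 1e-14) { n1[i + 1, ] <- n1[i, ]; next }
    nL <- n1[i, ] - (2 / c1) * sum(v1 * n1[i, ]) * v1
    tL <- tans[i, ] - (2 / c1) * sum(v1 * tans[i, ]) * v1
    v2 <- tans[i + 1, ] - tL
    c2 <- sum(v2^2)
    n1[i + 1, ] <- if (c2 < 1e-14) nL else nL - (2 / c2) * sum(v2 * nL) * v2
  }
  n2 <- cbind(tans[, 2] * n1[, 3] - tans[, 3] * n1[, 2],
              tans[, 3] * n1[, 1] - tans[, 1] * n1[, 3],
              tans[, 1] * n1[, 2] - tans[, 2] * n1[, 1])
  list(n1 = n1, n2 = n2)
}

# linear interpolation of centerline quantities at arbitrary arc lengths
.centerlineAt <- function(centerline, s) {
  arc <- centerline@arcLength
  idx <- findInterval(s, arc, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(arc) - 1L)
  f <- (s - arc[idx]) / (arc[idx + 1] - arc[idx])
  p <- centerline@points[idx, , drop = FALSE] * (1 - f) +
       centerline@points[idx + 1, , drop = FALSE] * f
  tn <- centerline@tangents[idx, , drop = FALSE] * (1 - f) +
        centerline@tangents[idx + 1, , drop = FALSE] * f
  tn <- tn / sqrt(rowSums(tn^2))
  list(points = p, tangents = tn)
}

#' Sweep a tube mesh along a centerline
#'
#' Uses rotation-minimizing frames, so the angular coordinate theta is
#' twist-free along the tube. Per-vertex arc length, angle and outward
#' radial direction are stored in the mesh metadata for analytic oracles.
#'
#' @param centerline a \linkS4class{CenterlineCurve}.
#' @param radiusProfile constant radius (mm) or function of arc length.
#' @param nCirc vertices per ring (>= 8).
#' @param axialStep ring spacing (mm, <= 2).
#' @param irregularity sd (mm) of smooth random radius variation (0 = a
#'   perfect surface of revolution).
#' @param seed seed for the irregularity pattern.
#' @return A \linkS4class{SurfaceMesh} (open tube; caps are added internally
#'   during rasterization).
#' @export
makeTubeMesh <- function(centerline, radiusProfile = 12, nCirc = 32,
                         axialStep = 1.5, irregularity = 0, seed = 1L) {
  if (nCirc < 8) stop("nCirc must be >= 8")
  if (axialStep > 2) stop("axialStep must be <= 2 mm")
  L <- max(centerline@arcLength)
  s <- seq(0, L, by = axialStep)
  if (s[length(s)] < L - 1e-9) s <- c(s, L)
  ci <- .centerlineAt(centerline, s)
  rfun <- .radiusFun(radiusProfile, L)
  r <- rfun(s)
  if (any(r <= 0)) stop("lumen radius must be positive everywhere")
  fr <- .rmfFrames(ci$points, ci$tangents)
  nA <- length(s)
  theta <- 2 * pi * (seq_len(nCirc) - 1) / nCirc
  nV <- nA * nCirc
  verts <- matrix(0, nV, 3)
  radial <- matrix(0, nV, 3)
  svec <- rep(s, each = nCirc)
  tvec <- rep(theta, times = nA)
  dr <- if (irregularity > 0)
    .wallIrregularity(svec, tvec, L, irregularity, seed) else 0
  rv <- rep(r, each = nCirc) + dr
  if (any(rv <= 0)) stop("lumen radius must be positive everywhere")
  for (i in seq_len(nA)) {
    rows <- (i - 1) * nCirc + seq_len(nCirc)
    dirs <- outer(cos(theta), fr$n1[i, ]) + outer(sin(theta), fr$n2[i, ])
    radial[rows, ] <- dirs
    verts[rows, ] <- matrix(ci$points[i, ], nCirc, 3, byrow = TRUE) +
      rv[rows] * dirs
  }
  # two triangles per quad, consistently oriented with outward normals
  f1 <- f2 <- matrix(0L, (nA - 1) * nCirc, 3)
  k <- 1L
  for (i in seq_len(nA - 1)) {
    for (j in seq_len(nCirc)) {
      jn <- if (j == nCirc) 1L else j + 1L
      a <- (i - 1L) * nCirc + j
      b <- (i - 1L) * nCirc + jn
      cc <- i * nCirc + j
      dd <- i * nCirc + jn
      f1[k, ] <- c(a, b, cc)
      f2[k, ] <- c(b, dd, cc)
      k <- k + 1L
    }
  }
  surfaceMesh(verts, rbind(f1, f2),
              meta = list(s = svec, theta = tvec, radial = radial,
                          nCirc = nCirc, nRings = nA,
                          displacement = matrix(0, nV, 3)))
}

# Smooth band-limited random radius variation over (arc length, angle):
# a sum of low-order harmonics with seeded random coefficients, scaled to
# the requested standard deviation. Emulates the gentle irregularity of a
# real aortic wall; perfectly smooth tubes are tangentially degenerate.
.wallIrregularity <- function(svec, tvec, L, sd0, seed) {
  set.seed(as.integer(seed))
  K <- 12L
  fk <- sample(1:6, K, replace = TRUE)
  mk <- sample(0:3, K, replace = TRUE)
  ph1 <- stats::runif(K, 0, 2 * pi)
  ph2 <- stats::runif(K, 0, 2 * pi)
  ak <- stats::rnorm(K)
  dr <- numeric(length(svec))
  for (k in seq_len(K))
    dr <- dr + ak[k] * cos(2 * pi * fk[k] * svec / L + ph1[k]) *
          cos(mk[k] * tvec + ph2[k])
  dr / stats::sd(dr) * sd0
}

# radius profile: constant, linear taper c(proximal, distal), or function
.radiusFun <- function(radiusProfile, L) {
  if (is.function(radiusProfile)) return(radiusProfile)
  if (length(radiusProfile) == 1L)
    return(function(s) rep(radiusProfile, length(s)))
  if (length(radiusProfile) == 2L)
    return(function(s) radiusProfile[1] + (radiusProfile[2] - radiusProfile[1]) * s / L)
  stop("radiusProfile must be a constant, a length-2 taper, or a function")
}

# smooth compactly-supported cosine^2 bump, 1 at 0, 0 outside +/- halfWidth
.bump <- function(d, halfWidth) {
  w <- numeric(length(d))
  inside <- abs(d) < halfWidth
  w[inside] <- cos(pi * d[inside] / (2 * halfWidth))^2
  w
}

.applyDisplacement <- function(mesh, disp) {
  meta <- mesh@meta
  meta$displacement <- meta$displacement + disp
  surfaceMesh(mesh@vertices + disp, mesh@faces, meta)
}

#' Fusiform (radial) growth deformation
#'
#' Displaces every vertex outward along its local radial direction by
#' \code{magnitude * w(s)}, with w a smooth compactly supported cosine^2
#' bump centered at \code{centerS} and vanishing outside
#' \code{centerS +/- extent/2}. Mimics typical fusiform aneurysm growth
#' around the full circumference.
#'
#' @param mesh tube mesh from \code{\link{makeTubeMesh}}.
#' @param centerS bump center in arc length (mm).
#' @param extent full axial support of the bump (mm).
#' @param magnitude peak outward displacement (mm, >= 0).
#' @return Deformed \linkS4class{SurfaceMesh}; connectivity and vertex order
#'   are untouched and the analytic displacement accumulates in
#'   \code{meshMeta(mesh)$displacement}.
#' @export
applyRadialBulge <- function(mesh, centerS, extent, magnitude) {
  if (magnitude < 0) stop("magnitude must be >= 0")
  meta <- mesh@meta
  if (is.null(meta$s) || is.null(meta$radial))
    stop("mesh lacks tube coordinates (build it with makeTubeMesh)")
  w <- .bump(meta$s - centerS, extent / 2)
  .applyDisplacement(mesh, magnitude * w * meta$radial)
}

#' Saccular (sculpted) growth deformation
#'
#' Like \code{\link{applyRadialBulge}} but restricted to an angular sector:
#' a separable cosine^2 bump in arc length and in wrapped angular distance
#' from \code{centerTheta}. Mimics eccentric/saccular bulging.
#'
#' @inheritParams applyRadialBulge
#' @param centerTheta angular center of the bulge (radians).
#' @param extentS full axial support (mm).
#' @param extentTheta full angular support (radians).
#' @return Deformed \linkS4class{SurfaceMesh}.
#' @export
applySculptBulge <- function(mesh, centerS, centerTheta, extentS, extentTheta,
                             magnitude) {
  if (magnitude < 0) stop("magnitude must be >= 0")
  meta <- mesh@meta
  if (is.null(meta$s) || is.null(meta$radial))
    stop("mesh lacks tube coordinates (build it with makeTubeMesh)")
  dtheta <- (meta$theta - centerTheta + pi) %% (2 * pi) - pi
  w <- .bump(meta$s - centerS, extentS / 2) * .bump(dtheta, extentTheta / 2)
  .applyDisplacement(mesh, magnitude * w * meta$radial)
}

#' Drag (translate) a region of the tube
#'
#' Translates all vertices whose arc length lies in \code{sRange} rigidly by
#' \code{translation}, blending smoothly to zero over \code{falloff} mm
#' beyond the region. Used to emulate respiratory translation of aortic
#' segments and bending/stretching.
#'
#' @param mesh tube mesh.
#' @param sRange length-2 arc-length interval (mm) that moves rigidly.
#' @param translation length-3 displacement vector (mm).
#' @param falloff blend distance (mm, > 0).
#' @param maxTranslation physiologic cap on |translation| (mm).
#' @return Deformed \linkS4class{SurfaceMesh}.
#' @export
applyDrag <- function(mesh, sRange, translation, falloff = 20,
                      maxTranslation = 15) {
  if (falloff <= 0) stop("falloff must be > 0")
  if (sqrt(sum(translation^2)) > maxTranslation)
    stop("translation exceeds the physiologic cap (", maxTranslation, " mm)")
  meta <- mesh@meta
  if (is.null(meta$s)) stop("mesh lacks tube coordinates")
  d <- pmax(sRange[1] - meta$s, meta$s - sRange[2], 0)
  w <- .bump(d, falloff)
  w[d == 0] <- 1
  .applyDisplacement(mesh, outer(w, as.numeric(translation)))
}

#' Grid specification covering a mesh
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param spacing voxel spacing (mm, scalar or length 3).
#' @param margin padding around the bounding box (mm).
#' @return list(dim, spacing, origin) usable as a rasterization grid.
#' @export
gridForMesh <- function(mesh, spacing = c(1, 1, 1), margin = 10) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  lo <- apply(mesh@vertices, 2, min) - margin
  hi <- apply(mesh@vertices, 2, max) + margin
  dm <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(dim = dm, spacing = as.numeric(spacing), origin = as.numeric(lo))
}

# add fan caps at both tube ends so the lateral surface is watertight
.capTube <- function(mesh) {
  meta <- mesh@meta
  nC <- meta$nCirc; nR <- meta$nRings
  v <- mesh@vertices; f <- mesh@faces
  ring1 <- seq_len(nC)
  ringN <- (nR - 1) * nC + seq_len(nC)
  c1 <- colMeans(v[ring1, , drop = FALSE])
  cN <- colMeans(v[ringN, , drop = FALSE])
  v2 <- rbind(v, c1, cN)
  i1 <- nrow(v) + 1L
  iN <- nrow(v) + 2L
  capf <- NULL
  for (j in seq_len(nC)) {
    jn <- if (j == nC) 1L else j + 1L
    capf <- rbind(capf,
                  c(i1, ring1[jn], ring1[j]),
                  c(iN, ringN[j], ringN[jn]))
  }
  list(vertices = v2, faces = rbind(f, capf))
}

#' Rasterize a tube mesh to a CT-like volume and mask
#'
#' Caps the tube, computes fractional voxel occupancy of the interior
#' (supersampled ray parity in-plane, exact interval coverage through-plane),
#' and maps occupancy to intensity: lumen inside, background outside, with
#' partial-volume antialiasing at the wall. The binary mask thresholds
#' occupancy at 0.5.
#'
#' @param mesh tube mesh (from \code{\link{makeTubeMesh}} or deformed copies).
#' @param grid list(dim, spacing, origin) as from \code{\link{gridForMesh}}.
#' @param model an \linkS4class{IntensityModel}.
#' @return list(image, mask): two \linkS4class{ImageVolume}s on the same grid.
#' @export
rasterizeMesh <- function(mesh, grid, model = intensityModel()) {
  capped <- .capTube(mesh)
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dim - 1) * grid$spacing + grid$spacing / 2
  vlo <- apply(capped$vertices, 2, min)
  vhi <- apply(capped$vertices, 2, max)
  if (any(vlo < lo) || any(vhi > hi))
    stop("grid does not contain the mesh bounding box; enlarge the grid")
  occ <- .voxelize_mesh(capped$vertices,
                        matrix(as.integer(capped$faces), ncol = 3),
                        as.integer(grid$dim), grid$spacing, grid$origin,
                        as.integer(round(model@supersampling)))
  bg <- model@backgroundHU
  if (model@textureSD > 0) {
    set.seed(as.integer(model@seed))
    tex <- array(stats::rnorm(prod(grid$dim)), grid$dim)
    tex <- .gauss_blur3(tex, as.integer(grid$dim),
                        model@textureScale / grid$spacing, TRUE)
    bg <- bg + tex / stats::sd(tex) * model@textureSD
  }
  img <- bg * (1 - occ) + model@lumenHU * occ
  mask <- (occ >= 0.5) * 1.0
  dim(mask) <- grid$dim
  list(image = imageVolume(img, grid$spacing, grid$origin),
       mask = imageVolume(mask, grid$spacing, grid$origin))
}

#' Build a complete growth phantom
#'
#' Creates the candy-cane tube from a \linkS4class{PhantomSpec}, applies the
#' listed deformations in order, and rasterizes the fixed (undeformed)
#' anatomy. Deformation descriptors are lists with a \code{mode} field:
#' \describe{
#'   \item{radial}{\code{centerS}, \code{extent}, \code{magnitude}}
#'   \item{sculpt}{\code{centerS}, \code{centerTheta}, \code{extentS},
#'     \code{extentTheta}, \code{magnitude}}
#'   \item{drag}{\code{sRange}, \code{translation}, \code{falloff}}
#' }
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param gridSpacing rasterization spacing (mm).
#' @param margin grid padding (mm).
#' @param model an \linkS4class{IntensityModel}.
#' @return list(spec, centerline, fixedMesh, deformedMesh, image, mask, grid).
#' @export
makeGrowthPhantom <- function(spec = phantomSpec(), gridSpacing = c(1, 1, 1),
                              margin = 10, model = intensityModel()) {
  cl <- makeCenterline(spec)
  mesh <- makeTubeMesh(cl, spec@lumenRadius, spec@nCirc, spec@axialStep,
                       irregularity = spec@wallIrregularity,
                       seed = spec@seed)
  dmesh <- mesh
  for (d in spec@deformations) {
    dmesh <- switch(d$mode,
      radial = applyRadialBulge(dmesh, d$centerS, d$extent, d$magnitude),
      sculpt = applySculptBulge(dmesh, d$centerS, d$centerTheta, d$extentS,
                                d$extentTheta, d$magnitude),
      drag = applyDrag(dmesh, d$sRange, d$translation,
                       falloff = if (is.null(d$falloff)) 20 else d$falloff),
      stop("unknown deformation mode: ", d$mode))
  }
  grid <- gridForMesh(dmesh, gridSpacing, margin)  # covers deformed too
  ras <- rasterizeMesh(mesh, grid, model)
  list(spec = spec, centerline = cl, fixedMesh = mesh, deformedMesh = dmesh,
       image = ras$image, mask = ras$mask, grid = grid, model = model)
}
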