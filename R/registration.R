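#' Three-stage VDM registration
#'
#' Vascular deformation mapping estimates aortic wall deformation between two
#' CTA volumes with a three-stage registration: (1) rigid alignment driven by
#' normalized cross-correlation within the dilated aortic mask, (2) a heavily
#' regularized B-spline stage (mutual information + bending energy, weight 10,
#' + rigidity penalty, weight 20, on the dilated mask) that implicitly aligns
#' the aortic centerlines while keeping the aorta itself near-rigid, and
#' (3) a fine B-spline stage (mutual information + bending energy, weight 100)
#' that captures wall growth. The composed fixed-to-moving displacement field
#' feeds the mesh-based growth metrics.
#'
#' @name registration
NULL

#' Create a registration stage configuration
#'
#' @param similarity "MI", "NCC" or "SSD".
#' @param bendingWeight weight of the bending-energy penalty.
#' @param rigidityWeight weight of the rigidity penalty.
#' @param controlSpacing B-spline control-point spacing (mm).
#' @param levels multiresolution levels.
#' @param maxIter optimizer iterations per level.
#' @param sampleCap maximum similarity samples per level.
#' @return A \linkS4class{StageConfig}.
#' @export
stageConfig <- function(similarity = "MI", bendingWeight = 0,
                        rigidityWeight = 0, controlSpacing = 10,
                        levels = 2, maxIter = 60, sampleCap = 16000) {
  new("StageConfig", similarity = similarity, bendingWeight = bendingWeight,
      rigidityWeight = rigidityWeight, controlSpacing = controlSpacing,
      levels = levels, maxIter = maxIter, sampleCap = sampleCap)
}

#' Default VDM pipeline configuration
#'
#' Stage weights follow the published pipeline: centerline alignment uses
#' MI with bending weight 10 and rigidity weight 20 on a 10 mm control grid;
#' the final stage uses MI with bending weight 100 on a 6 mm control grid.
#'
#' @param centerline,final \linkS4class{StageConfig}s for the two B-spline
#'   stages.
#' @param maskDilation rigidity-map dilation radius (voxels).
#' @param simMargin margin (mm) around the dilated mask bounding box that
#'   defines the similarity sampling region.
#' @param nbins joint-histogram bins for MI.
#' @param replicates number of disjoint-sample replicate solves averaged at
#'   the finest level of each deformable stage; averaging cancels the
#'   imprint of image noise on the recovered field.
#' @param shellWidth half-widths (mm) of the boundary shells around the
#'   fixed mask from which similarity samples are drawn, for the
#'   centerline-alignment and final stages respectively. Concentrating
#'   samples at the vessel wall is where the alignment information lives;
#'   the wider centerline-stage shell preserves capture range for
#'   respiratory-scale displacement.
#' @param seed seed for the sub-voxel sample jitter.
#' @return list of configuration entries consumed by \code{\link{runVDM}}.
#' @export
vdmConfig <- function(centerline = stageConfig("MI", bendingWeight = 10,
                                               rigidityWeight = 20,
                                               controlSpacing = 10),
                      final = stageConfig("MI", bendingWeight = 100,
                                          rigidityWeight = 0,
                                          controlSpacing = 6),
                      maskDilation = 5, simMargin = 12, nbins = 48,
                      replicates = 2, shellWidth = c(12, 4), seed = 1L) {
  list(centerline = centerline, final = final, maskDilation = maskDilation,
       simMargin = simMargin, nbins = nbins, replicates = replicates,
       shellWidth = shellWidth, seed = seed)
}

#' Rigidity coefficient map
#'
#' Binary coefficient volume marking tissue that should deform rigidly:
#' the aortic mask dilated by \code{dilation} voxels (Euclidean ball).
#'
#' @param mask binary aortic mask (\linkS4class{ImageVolume}).
#' @param dilation dilation radius in voxels.
#' @return Binary \linkS4class{ImageVolume}.
#' @export
makeRigidityMap <- function(mask, dilation = 5) {
  if (sum(imgData(mask) > 0.5) == 0) stop("empty mask")
  dilateMask(mask, dilation, units = "voxels")
}

#' Normalized cross-correlation between two images
#'
#' Mean-subtracted correlation over the fixed-image domain: invariant to
#' positive affine intensity rescaling of either image.
#'
#' @param fixed,moving \linkS4class{ImageVolume}s.
#' @param transform optional \linkS4class{RigidTransform} mapping fixed-space
#'   sample points into the moving image.
#' @param domain optional binary \linkS4class{ImageVolume} on the fixed grid
#'   restricting the evaluation region (default: whole grid).
#' @return NCC score in [-1, 1].
#' @export
nccScore <- function(fixed, moving, transform = NULL, domain = NULL) {
  pts <- .gridPoints(fixed)
  keep <- if (is.null(domain)) rep(TRUE, nrow(pts)) else as.vector(imgData(domain) > 0.5)
  if (!any(keep)) stop("empty evaluation domain")
  pts <- pts[keep, , drop = FALSE]
  f <- as.vector(imgData(fixed))[keep]
  mp <- if (is.null(transform)) pts else applyRigidTransform(transform, pts)
  m <- sampleVolume(moving, mp, "linear")
  fc <- f - mean(f); mc <- m - mean(m)
  den <- sqrt(sum(fc^2) * sum(mc^2))
  if (den == 0)
    stop("NCC undefined: an image is constant on the domain (sd = 0)")
  sum(fc * mc) / den
}

#' Mutual information between two images
#'
#' Parzen-windowed joint-histogram estimate (linear window on the fixed
#' intensities, cubic B-spline window on the moving intensities), in nats.
#' This is the same estimator the deformable stages optimize.
#'
#' @inheritParams nccScore
#' @param nbins histogram bins per axis.
#' @return MI estimate (nats, >= 0 up to estimator bias).
#' @export
mutualInformation <- function(fixed, moving, transform = NULL, domain = NULL,
                              nbins = 32) {
  pts <- .gridPoints(fixed)
  keep <- if (is.null(domain)) rep(TRUE, nrow(pts)) else as.vector(imgData(domain) > 0.5)
  if (!any(keep)) stop("empty evaluation domain")
  pts <- pts[keep, , drop = FALSE]
  f <- as.vector(imgData(fixed))[keep]
  mp <- if (is.null(transform)) pts else applyRigidTransform(transform, pts)
  m <- sampleVolume(moving, mp, "linear")
  if (diff(range(f)) == 0 || diff(range(m)) == 0)
    stop("MI undefined: constant image on the domain")
  .mi_parzen(f, m, as.integer(nbins), min(f), max(f), min(m), max(m))
}

# second derivatives of a dense field component by central differences;
# returns list of 6 interior arrays (xx, yy, zz, xy, xz, yz)
.hessianComponent <- function(u, sp) {
  d <- dim(u)
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  ctr <- u[ix, iy, iz]
  hxx <- (u[ix + 1, iy, iz] - 2 * ctr + u[ix - 1, iy, iz]) / sp[1]^2
  hyy <- (u[ix, iy + 1, iz] - 2 * ctr + u[ix, iy - 1, iz]) / sp[2]^2
  hzz <- (u[ix, iy, iz + 1] - 2 * ctr + u[ix, iy, iz - 1]) / sp[3]^2
  hxy <- (u[ix + 1, iy + 1, iz] - u[ix + 1, iy - 1, iz] -
          u[ix - 1, iy + 1, iz] + u[ix - 1, iy - 1, iz]) / (4 * sp[1] * sp[2])
  hxz <- (u[ix + 1, iy, iz + 1] - u[ix + 1, iy, iz - 1] -
          u[ix - 1, iy, iz + 1] + u[ix - 1, iy, iz - 1]) / (4 * sp[1] * sp[3])
  hyz <- (u[ix, iy + 1, iz + 1] - u[ix, iy + 1, iz - 1] -
          u[ix, iy - 1, iz + 1] + u[ix, iy - 1, iz - 1]) / (4 * sp[2] * sp[3])
  list(hxx, hyy, hzz, hxy, hxz, hyz)
}

.interiorDomain <- function(field, domain) {
  d <- dim(field)
  keep <- if (is.null(domain)) array(TRUE, d) else imgData(domain) > 0.5
  keep[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE]
}

#' Bending energy of a displacement field
#'
#' Mean squared Frobenius norm of the transform's second spatial
#' derivatives (full Hessian; mixed terms counted twice), evaluated by
#' central differences on interior voxels. Zero exactly for any affine
#' field, and quadratic in the field amplitude.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param domain optional binary \linkS4class{ImageVolume} restricting the
#'   neighborhood set.
#' @return Nonnegative scalar penalty.
#' @export
bendingEnergy <- function(field, domain = NULL) {
  sp <- spacing(field)
  keep <- .interiorDomain(field, domain)
  mult <- c(1, 1, 1, 2, 2, 2)
  acc <- 0
  for (c in 1:3) {
    h <- .hessianComponent(field@field[, , , c], sp)
    for (q in 1:6) acc <- acc + mult[q] * sum(h[[q]][keep]^2)
  }
  acc / sum(keep)
}

#' Rigidity penalty of a displacement field
#'
#' Coefficient-weighted mean of three terms on the transform Jacobian
#' J = I + grad u: linearity (squared second derivatives), orthonormality
#' ||J'J - I||_F^2 and properness (det J - 1)^2. Zero exactly for any
#' globally rigid motion (translation or rotation).
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param coeffs binary rigidity coefficient map
#'   (\linkS4class{ImageVolume}); default all ones.
#' @return Nonnegative scalar penalty.
#' @export
rigidityPenalty <- function(field, coeffs = NULL) {
  sp <- spacing(field)
  d <- dim(field)
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  keep <- .interiorDomain(field, coeffs)
  n <- sum(keep)
  if (n == 0) stop("empty rigidity domain")
  # Jacobian entries on the interior
  J <- vector("list", 9)
  k <- 1
  for (c in 1:3) {
    u <- field@field[, , , c]
    J[[k]] <- (u[ix + 1, iy, iz] - u[ix - 1, iy, iz]) / (2 * sp[1]) + (c == 1)
    J[[k + 1]] <- (u[ix, iy + 1, iz] - u[ix, iy - 1, iz]) / (2 * sp[2]) + (c == 2)
    J[[k + 2]] <- (u[ix, iy, iz + 1] - u[ix, iy, iz - 1]) / (2 * sp[3]) + (c == 3)
    k <- k + 3
  }
  # OC: sum_ij (J^T J - I)_ij^2 ; PC: (det J - 1)^2 ; LN: Hessian norm
  oc <- 0
  for (i in 1:3) for (j in 1:3) {
    a <- J[[3 * 0 + i]] * 0
    for (c in 0:2) a <- a + J[[3 * c + i]] * J[[3 * c + j]]
    if (i == j) a <- a - 1
    oc <- oc + sum(a[keep]^2)
  }
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
         J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
         J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  pc <- sum((det[keep] - 1)^2)
  mult <- c(1, 1, 1, 2, 2, 2)
  ln <- 0
  for (c in 1:3) {
    h <- .hessianComponent(field@field[, , , c], sp)
    for (q in 1:6) ln <- ln + mult[q] * sum(h[[q]][keep]^2)
  }
  (ln + oc + pc) / n
}

# ---- B-spline FFD engine --------------------------------------------------

# control lattice covering [lo, hi] with full cubic support plus margin
.ffdGrid <- function(lo, hi, spc) {
  if (length(spc) == 1L) spc <- rep(spc, 3L)
  gorig <- lo - 2 * spc
  nc <- as.integer(ceiling((hi - gorig) / spc)) + 4L
  list(gorig = as.numeric(gorig), gspc = as.numeric(spc), nc = nc)
}

.ffdEval <- function(ffd, pts) {
  .ffd_eval_points(ffd$coef, ffd$gorig, ffd$gspc, as.integer(ffd$nc), rbind(pts))
}

# logical array marking the bounding box of `mask` expanded by margin (mm)
.bboxRegion <- function(mask, margin) {
  d <- dim(mask); sp <- spacing(mask)
  idx <- which(imgData(mask) > 0.5, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  mv <- ceiling(margin / sp)
  lo <- pmax(apply(idx, 2, min) - mv, 1)
  hi <- pmin(apply(idx, 2, max) + mv, d)
  reg <- array(FALSE, d)
  reg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  reg
}

# deterministic striding of voxel indices: stride in voxels then cap evenly
.strideIndices <- function(regionArray, d, stride, cap) {
  idx <- which(regionArray)
  if (stride > 1) {
    k0 <- (idx - 1) %/% (d[1] * d[2])
    r <- (idx - 1) %% (d[1] * d[2])
    j0 <- r %/% d[1]
    i0 <- r %% d[1]
    idx <- idx[i0 %% stride == 0 & j0 %% stride == 0 & k0 %% stride == 0]
  }
  if (length(idx) > cap) idx <- idx[unique(round(seq(1, length(idx), length.out = cap)))]
  idx
}

# binary shell of given half-width (mm) around a mask boundary
.maskShell <- function(mask, width) {
  dOut <- distanceTransform(mask, "mm")
  inv <- imageVolume(1 - (imgData(mask) > 0.5), spacing(mask), origin(mask))
  dIn <- distanceTransform(inv, "mm")
  imgData(dOut) <= width & imgData(dIn) <= width
}

# Core multiresolution B-spline registration between two volumes on the
# same grid: one control lattice at controlSpacing (covering the whole
# fixed grid), warm-started across image-resolution levels, so the
# penalties always act on the full field. Similarity samples are drawn
# from simRegion at sub-voxel jittered positions (defeats grid-locking
# artifacts of linear interpolation); at the finest level the solve can be
# replicated on disjoint sample subsets and coefficient-averaged, which
# cancels the imprint of image noise. Returns the FFD and cost traces.
.ffdRegister <- function(fixed, moving, metric = c("MI", "SSD"),
                         controlSpacing = 10, beWeight = 0, rigWeight = 0,
                         rigMask = NULL, simRegion = NULL, levels = 2,
                         maxIter = 60, sampleCap = 16000, nbins = 32,
                         factr = 1e9, replicates = 1, jitter = TRUE,
                         seed = 1L, initDisp = c(0, 0, 0)) {
  metric <- match.arg(metric)
  d <- dim(fixed); sp <- spacing(fixed); or <- origin(fixed)
  stopifnot(.sameGrid(fixed, moving))
  if (is.null(simRegion)) simRegion <- array(TRUE, d)
  ffd <- .ffdGrid(or, or + (d - 1) * sp, controlSpacing)
  # a constant control field is an exact (penalty-free) translation: used
  # to seed the optimization with a known bulk offset of the vessel
  ffd$coef <- rep(as.numeric(initDisp), each = prod(ffd$nc))
  aidx <- which(simRegion, arr.ind = TRUE)
  lo <- or + (apply(aidx, 2, min) - 1) * sp
  hi <- or + (apply(aidx, 2, max) - 1) * sp
  # bending-energy samples: control-spacing-pitch lattice over the region
  # (the integrand varies at the control scale, so this pitch suffices)
  bePts <- as.matrix(expand.grid(
    seq(lo[1], hi[1], by = ffd$gspc[1]),
    seq(lo[2], hi[2], by = ffd$gspc[2]),
    seq(lo[3], hi[3], by = ffd$gspc[3])))
  # rigidity samples: strided voxels of the coefficient map
  rigPts <- matrix(0, 0, 3)
  if (rigWeight > 0 && !is.null(rigMask)) {
    ridx <- .strideIndices(imgData(rigMask) > 0.5, d, 2L, 4000L)
    rig <- arrayInd(ridx, d)
    rigPts <- sweep(sweep(rig - 1, 2, sp, "*"), 2, or, "+")
  }
  noBase <- matrix(0, 0, 3)
  trace <- list()
  for (lev in seq_len(levels)) {
    stride <- 2^(levels - lev)
    if (stride > 1) {
      fv <- gaussianSmooth(fixed, 0.5 * stride, "voxels", renorm = TRUE)
      mv <- gaussianSmooth(moving, 0.5 * stride, "voxels", renorm = TRUE)
    } else {
      fv <- fixed; mv <- moving
    }
    mgrad <- .gradient_volume(imgData(mv), as.integer(d), sp)
    mrange <- range(imgData(mv))
    metricCode <- if (metric == "SSD") 0L else 1L
    nrep <- if (lev == levels) as.integer(replicates) else 1L
    pool <- .strideIndices(simRegion, d, stride, sampleCap * nrep)
    warm <- ffd$coef
    acc <- numeric(length(warm))
    lastTr <- NULL
    for (j in seq_len(nrep)) {
      sidx <- if (nrep == 1L) pool else pool[seq(j, length(pool), by = nrep)]
      sarr <- arrayInd(sidx, d)
      simPts <- sweep(sweep(sarr - 1, 2, sp, "*"), 2, or, "+")
      if (jitter) {
        set.seed(as.integer(seed) + 97L * lev + j)
        simPts <- simPts +
          matrix(stats::runif(length(simPts), -0.5, 0.5), ncol = 3) %*% diag(sp)
        fvals <- sampleVolume(fv, simPts, "linear")
      } else {
        fvals <- as.vector(imgData(fv))[sidx]
      }
      frange <- range(fvals)
      if (diff(frange) == 0 || diff(mrange) == 0)
        stop("constant image in registration domain")
      # for SSD normalize intensities so penalty weights are scale-free
      scl <- if (metric == "SSD") 1 / diff(frange) else 1
      mvArr <- imgData(mv) * scl
      mgradArr <- mgrad * scl
      lastGrad <- NULL
      obj <- function(p) {
        r <- .ffd_cost_grad(p, ffd$gorig, ffd$gspc, as.integer(ffd$nc),
                            simPts, fvals * scl, mvArr, as.integer(d), sp, or,
                            mgradArr, metricCode, as.integer(nbins),
                            frange[1] * scl, frange[2] * scl,
                            mrange[1] * scl, mrange[2] * scl,
                            bePts, beWeight, rigPts, rigWeight, noBase)
        lastGrad <<- r$grad
        r$value
      }
      grd <- function(p) lastGrad
      opt <- stats::optim(warm, fn = obj, gr = grd, method = "L-BFGS-B",
                          control = list(maxit = maxIter, factr = factr))
      acc <- acc + opt$par
      lastTr <- c(value = opt$value, convergence = opt$convergence)
    }
    ffd$coef <- acc / nrep
    trace[[lev]] <- lastTr
  }
  ffd$trace <- trace
  ffd
}

# evaluate an FFD (plus optional rigid tail) as a dense field on a grid
.ffdToField <- function(ffd, refVol, meta = list()) {
  pts <- .gridPoints(refVol)
  u <- .ffdEval(ffd, pts)
  displacementField(array(u, c(dim(refVol), 3)), spacing(refVol),
                    origin(refVol), meta = meta)
}

# ---- stages ---------------------------------------------------------------

#' Rigid alignment stage
#'
#' Maximizes NCC over a 6-parameter rigid transform (per-axis Euler
#' rotations about the fixed-mask centroid plus translation). Initialized
#' from the mask centroid offset, then refined on smoothed and raw
#' intensities. The metric is evaluated by default over the background
#' (the complement of the dilated aortic mask): patient position is defined
#' by the static anatomy around the vessel, which distinguishes a bulk
#' change in table/patient position (the entire scene moves; the rigid
#' stage must follow) from physiologic displacement of the aorta itself
#' (the background stays put; the rigid stage must not follow, or aortic
#' motion would be silently removed from the measured deformation). The
#' masks provide the initialization and the rotation center.
#'
#' @param fixed,moving images (\linkS4class{ImageVolume}).
#' @param fixedMask,movingMask binary aortic masks.
#' @param maskDilation dilation (voxels) separating vessel from background.
#' @param maxIter optimizer iterations per refinement pass.
#' @param domain "background" (default: mask complement), "image" (whole
#'   volume) or "mask" (dilated-mask NCC domain).
#' @return A \linkS4class{RigidTransform} mapping fixed-space points to
#'   moving-space points, with attribute \code{ncc} (final score).
#' @export
rigidStage <- function(fixed, moving, fixedMask, movingMask,
                       maskDilation = 5, maxIter = 150,
                       domain = c("background", "image", "mask")) {
  domain <- match.arg(domain)
  if (sum(imgData(fixedMask)) == 0 || sum(imgData(movingMask)) == 0)
    stop("empty mask")
  d <- dim(fixed); sp <- spacing(fixed); or <- origin(fixed)
  reg <- switch(domain,
    mask = imgData(dilateMask(fixedMask, maskDilation, "voxels")) > 0.5,
    background = {
      # exclude the vessel in BOTH frames: a displaced aorta intruding into
      # fixed-background sample positions would otherwise dominate the NCC
      # (its contrast dwarfs the soft-tissue texture) and drag the
      # alignment along with the vessel
      fx <- imgData(dilateMask(fixedMask, maskDilation + 3, "voxels")) > 0.5
      mvps <- .gridPoints(fixed)
      mv <- sampleVolume(dilateMask(movingMask, maskDilation + 3, "voxels"),
                         mvps, "nearest") > 0.5
      dim(mv) <- d
      !fx & !mv
    },
    image = array(TRUE, d))
  sidx <- .strideIndices(reg, d, 1L, 12000L)
  sarr <- arrayInd(sidx, d)
  pts <- sweep(sweep(sarr - 1, 2, sp, "*"), 2, or, "+")
  # sub-voxel jitter: keeps interpolation-induced noise smoothing uniform
  # in the transform parameters (no lattice-locking of the NCC optimum)
  set.seed(7L)
  pts <- pts + matrix(stats::runif(length(pts), -0.5, 0.5), ncol = 3) %*% diag(sp)
  centroidOf <- function(m) {
    w <- which(imgData(m) > 0.5, arr.ind = TRUE)
    origin(m) + (colMeans(w) - 1) * spacing(m)
  }
  ctr <- centroidOf(fixedMask)
  t0 <- centroidOf(movingMask) - ctr
  par <- c(0, 0, 0, t0)
  nccOf <- function(par, mov, fvals) {
    tr <- rigidTransform(eulerRotation(par[1:3]), par[4:6], ctr)
    m <- sampleVolume(mov, applyRigidTransform(tr, pts), "linear")
    fc <- fvals - mean(fvals); mc <- m - mean(m)
    den <- sqrt(sum(fc^2) * sum(mc^2))
    if (den == 0) return(0)
    sum(fc * mc) / den
  }
  for (sm in c(2, 0)) {
    fv <- if (sm > 0) gaussianSmooth(fixed, sm, "voxels", renorm = TRUE) else fixed
    mv <- if (sm > 0) gaussianSmooth(moving, sm, "voxels", renorm = TRUE) else moving
    fvals <- sampleVolume(fv, pts, "linear")
    opt <- stats::optim(par, function(p) -nccOf(p, mv, fvals), method = "BFGS",
                        control = list(maxit = maxIter, reltol = 1e-10,
                                       parscale = c(0.02, 0.02, 0.02, 1, 1, 1)))
    par <- opt$par
  }
  fvals <- sampleVolume(fixed, pts, "linear")
  before <- nccOf(c(0, 0, 0, t0), moving, fvals)
  after <- nccOf(par, moving, fvals)
  if (after < before - 1e-6)
    warning("rigid stage did not improve NCC beyond centroid initialization")
  tr <- rigidTransform(eulerRotation(par[1:3]), par[4:6], ctr)
  attr(tr, "ncc") <- after
  tr
}

#' Centerline alignment stage
#'
#' Highly regularized B-spline registration (default: MI similarity,
#' bending-energy weight 10, rigidity weight 20 on the dilated aortic mask)
#' that absorbs bulk and respiratory displacement of the aorta while keeping
#' the vessel locally rigid, implicitly aligning the aortic centerlines.
#'
#' @param fixed,moving rigidly pre-aligned images on the same grid.
#' @param rigidityMap binary coefficient map (see
#'   \code{\link{makeRigidityMap}}).
#' @param cfg a \linkS4class{StageConfig}.
#' @param simMargin sampling-region margin (mm) around the rigidity map.
#' @param nbins MI histogram bins.
#' @param samplingRegion optional logical array (fixed-grid) of candidate
#'   similarity sample voxels; defaults to the rigidity-map bounding box.
#' @param replicates finest-level replicate solves (coefficient-averaged).
#' @param seed seed for the sub-voxel sample jitter.
#' @param initDisp length-3 initial translation (mm) seeded into the
#'   B-spline (typically the mask-centroid offset of the vessel, which
#'   gives the stage capture range for respiratory-scale displacement).
#' @return A \linkS4class{DisplacementField}; attribute \code{ffd} carries
#'   the underlying B-spline for exact composition.
#' @export
centerlineAlignmentStage <- function(fixed, moving, rigidityMap,
                                     cfg = stageConfig("MI", 10, 20, 10),
                                     simMargin = 12, nbins = 32,
                                     samplingRegion = NULL, replicates = 1,
                                     seed = 1L, initDisp = c(0, 0, 0)) {
  if (is.null(samplingRegion)) samplingRegion <- .bboxRegion(rigidityMap, simMargin)
  ffd <- .ffdRegister(fixed, moving, metric = cfg@similarity,
                      controlSpacing = cfg@controlSpacing,
                      beWeight = cfg@bendingWeight,
                      rigWeight = cfg@rigidityWeight, rigMask = rigidityMap,
                      simRegion = samplingRegion, levels = cfg@levels,
                      maxIter = cfg@maxIter, sampleCap = cfg@sampleCap,
                      nbins = nbins, replicates = replicates, seed = seed,
                      initDisp = initDisp)
  fld <- .ffdToField(ffd, fixed, meta = list(stage = "centerline",
                                             trace = ffd$trace))
  attr(fld, "ffd") <- ffd
  fld
}

#' Final deformable registration stage
#'
#' Fine B-spline registration (default: MI similarity, bending-energy
#' weight 100, 6 mm control spacing) capturing local wall deformation.
#'
#' @inheritParams centerlineAlignmentStage
#' @param samplingMask binary map whose bounding box (plus margin) defines
#'   the similarity sampling region.
#' @return A \linkS4class{DisplacementField} with attribute \code{ffd}.
#' @export
finalDirStage <- function(fixed, moving, samplingMask,
                          cfg = stageConfig("MI", 100, 0, 6),
                          simMargin = 12, nbins = 32, samplingRegion = NULL,
                          replicates = 1, seed = 1L) {
  if (is.null(samplingRegion)) samplingRegion <- .bboxRegion(samplingMask, simMargin)
  ffd <- .ffdRegister(fixed, moving, metric = cfg@similarity,
                      controlSpacing = cfg@controlSpacing,
                      beWeight = cfg@bendingWeight, rigWeight = 0,
                      simRegion = samplingRegion, levels = cfg@levels,
                      maxIter = cfg@maxIter, sampleCap = cfg@sampleCap,
                      nbins = nbins, replicates = replicates, seed = seed)
  fld <- .ffdToField(ffd, fixed, meta = list(stage = "final", trace = ffd$trace))
  attr(fld, "ffd") <- ffd
  fld
}

#' Run the full VDM registration pipeline
#'
#' Clamps negative HU, performs rigid alignment, the regularized centerline
#' alignment and the fine deformable stage, and composes the three into one
#' fixed-to-moving displacement field on the fixed grid. Fully deterministic
#' for identical inputs.
#'
#' @param fixed,moving CT-like images (any grids; the moving image is
#'   resampled through the current transform between stages).
#' @param fixedMask,movingMask binary aortic masks on the respective grids.
#' @param cfg configuration from \code{\link{vdmConfig}}.
#' @param includeRigid compose the rigid alignment into the returned field
#'   (for resampling the raw moving image); the default FALSE returns the
#'   deformable (growth) field in rigid-normalized space, which is what the
#'   mesh metrics should see.
#' @return A \linkS4class{DisplacementField} on the fixed grid; \code{meta}
#'   holds the rigid transform and per-stage cost traces.
#' @export
runVDM <- function(fixed, moving, fixedMask, movingMask, cfg = vdmConfig(),
                   includeRigid = FALSE) {
  fixed <- clampNegative(fixed)
  moving <- clampNegative(moving)
  rigid <- rigidStage(fixed, moving, fixedMask, movingMask,
                      maskDilation = cfg$maskDilation)
  pts <- .gridPoints(fixed)
  d <- dim(fixed)
  resample <- function(worldPts) {
    vals <- sampleVolume(moving, worldPts, "cubic")
    imageVolume(array(vals, d), spacing(fixed), origin(fixed))
  }
  movingR <- resample(applyRigidTransform(rigid, pts))
  rigMap <- makeRigidityMap(fixedMask, cfg$maskDilation)
  reps <- if (is.null(cfg$replicates)) 1 else cfg$replicates
  shw <- if (is.null(cfg$shellWidth)) c(12, 4) else cfg$shellWidth
  sd0 <- if (is.null(cfg$seed)) 1L else cfg$seed
  # residual offset of the vessel after rigid alignment, from the mask
  # centroids: seeds the centerline stage (physiologic displacement of the
  # aorta can exceed the B-spline optimization's blind capture range)
  centroidOf <- function(m) {
    w <- which(imgData(m) > 0.5, arr.ind = TRUE)
    origin(m) + (colMeans(w) - 1) * spacing(m)
  }
  cRes <- applyRigidTransform(invertRigidTransform(rigid),
                              centroidOf(movingMask)) - centroidOf(fixedMask)
  f2 <- centerlineAlignmentStage(fixed, movingR, rigMap, cfg$centerline,
                                 simMargin = cfg$simMargin, nbins = cfg$nbins,
                                 samplingRegion = .maskShell(fixedMask, shw[1]),
                                 replicates = reps, seed = sd0,
                                 initDisp = as.numeric(cRes))
  ffd2 <- attr(f2, "ffd")
  y2 <- pts + .ffdEval(ffd2, pts)
  moving2 <- resample(applyRigidTransform(rigid, y2))
  f3 <- finalDirStage(fixed, moving2, rigMap, cfg$final,
                      simMargin = cfg$simMargin, nbins = cfg$nbins,
                      samplingRegion = .maskShell(fixedMask, shw[2]),
                      replicates = reps, seed = sd0 + 1L)
  ffd3 <- attr(f3, "ffd")
  # deformable map: x -> T2( T3(x) ), in rigid-normalized moving space.
  # The rigid stage is alignment, not growth: bulk repositioning of the
  # patient must not enter the wall-deformation metrics, so the returned
  # field excludes it (the transform itself travels in meta$rigid; compose
  # with includeRigid = TRUE to resample the raw moving image).
  y3 <- pts + .ffdEval(ffd3, pts)
  y23 <- y3 + .ffdEval(ffd2, y3)
  total <- if (includeRigid) applyRigidTransform(rigid, y23) - pts else y23 - pts
  displacementField(array(total, c(d, 3)), spacing(fixed), origin(fixed),
                    meta = list(rigid = rigid, includesRigid = includeRigid,
                                trace = list(centerline = f2@meta$trace,
                                             final = f3@meta$trace)))
}
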