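#' Image-quality and motion perturbations
#'
#' The robustness experiments perturb the fixed and synthetic moving images
#' of each phantom pair - Gaussian noise (calibrated by contrast-to-noise
#' ratio), slice-thickness resampling, and bulk rigid motion - rerun the
#' full VDM pipeline, and compare errors against the unperturbed run. The
#' ground-truth field is never touched; only the images entering the
#' registration change.
#'
#' @name perturbations
NULL

#' Add i.i.d. Gaussian noise to an image
#'
#' @param img an \linkS4class{ImageVolume}.
#' @param sigma noise standard deviation (HU).
#' @param seed integer seed (deterministic output for a given seed).
#' @return Noisy \linkS4class{ImageVolume}.
#' @export
addGaussianNoise <- function(img, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  d <- dim(img)
  set.seed(as.integer(seed))
  n <- array(stats::rnorm(prod(d), 0, sigma), d)
  imageVolume(imgData(img) + n, spacing(img), origin(img))
}

#' Automatic background region of interest
#'
#' A reproducible stand-in for manually drawn mediastinal-fat ROIs on
#' synthetic phantoms: all voxels whose distance to the aortic mask lies in
#' [inner, outer] mm (a shell adjacent to, but clear of, the vessel wall).
#'
#' @param mask binary aortic mask.
#' @param inner,outer shell distances (mm).
#' @return Binary \linkS4class{ImageVolume}.
#' @export
defaultBackgroundROI <- function(mask, inner = 6, outer = 18) {
  d <- distanceTransform(mask, "mm")
  roi <- imgData(d) >= inner & imgData(d) <= outer & is.finite(imgData(d))
  imageVolume(roi * 1.0, spacing(mask), origin(mask))
}

#' Contrast-to-noise ratio
#'
#' CNR = (mean_aorta - mean_bg) / sqrt(sd_aorta^2 + sd_bg^2), with the
#' aortic ROI taken as the mask eroded by \code{erosion} voxels and the
#' background ROI supplied (or auto-generated adjacent to the vessel).
#'
#' @param img image (\linkS4class{ImageVolume}).
#' @param mask binary aortic mask.
#' @param bgROI binary background ROI; default
#'   \code{\link{defaultBackgroundROI}}.
#' @param erosion aortic-ROI erosion radius (voxels).
#' @return CNR (dimensionless scalar).
#' @export
computeCNR <- function(img, mask, bgROI = NULL, erosion = 3) {
  roi <- erodeMask(mask, erosion, "voxels")
  if (sum(imgData(roi)) == 0) stop("aortic ROI empty after erosion")
  if (is.null(bgROI)) bgROI <- defaultBackgroundROI(mask)
  if (sum(imgData(bgROI)) == 0) stop("background ROI empty")
  a <- imgData(img)[imgData(roi) > 0.5]
  b <- imgData(img)[imgData(bgROI) > 0.5]
  den <- sqrt(stats::var(a) + stats::var(b))
  if (!is.finite(den) || den == 0)
    stop("CNR undefined: zero intensity variance in the ROIs")
  (mean(a) - mean(b)) / den
}

#' Noise level matching a target CNR
#'
#' Solves for the additive Gaussian sigma that brings the image pair to a
#' target contrast-to-noise ratio, accounting for any baseline ROI
#' variance: sigma^2 = ((contrast/CNR)^2 - var_a0 - var_b0) / 2.
#'
#' @param img,mask,bgROI,erosion as in \code{\link{computeCNR}}.
#' @param targetCNR desired CNR after noise addition.
#' @return sigma in HU (>= 0).
#' @export
sigmaForCNR <- function(img, mask, targetCNR, bgROI = NULL, erosion = 3) {
  roi <- erodeMask(mask, erosion, "voxels")
  if (is.null(bgROI)) bgROI <- defaultBackgroundROI(mask)
  a <- imgData(img)[imgData(roi) > 0.5]
  b <- imgData(img)[imgData(bgROI) > 0.5]
  contrast <- mean(a) - mean(b)
  s2 <- ((contrast / targetCNR)^2 - stats::var(a) - stats::var(b)) / 2
  if (s2 <= 0)
    stop("target CNR unreachable: baseline noise already exceeds it")
  sqrt(s2)
}

#' Resample an image to a thicker slice profile
#'
#' Box-average (slice-sensitivity-profile) downsampling along z to the
#' requested slice thickness; in-plane sampling is unchanged and intensity
#' mass is conserved up to edge effects.
#'
#' @param img an \linkS4class{ImageVolume}.
#' @param thickness target slice thickness (mm, >= native z spacing).
#' @return Resampled \linkS4class{ImageVolume} (z spacing = thickness).
#' @export
resampleSliceThickness <- function(img, thickness) {
  sp <- spacing(img)
  if (thickness < sp[3] - 1e-9) stop("thickness below native z spacing")
  if (abs(thickness - sp[3]) < 1e-9) return(img)
  d <- dim(img)
  extent <- d[3] * sp[3]
  nzo <- max(1L, as.integer(floor(extent / thickness + 1e-9)))
  # overlap weights between input slice k (extent [(k-1)h, kh]) and output
  # slice q (extent [(q-1)T, qT]), both measured from the volume edge
  W <- matrix(0, d[3], nzo)
  for (q in seq_len(nzo)) {
    lo <- (q - 1) * thickness; hi <- q * thickness
    k0 <- max(1L, floor(lo / sp[3]) + 1L)
    k1 <- min(d[3], ceiling(hi / sp[3]))
    for (k in k0:k1) {
      ov <- min(hi, k * sp[3]) - max(lo, (k - 1) * sp[3])
      if (ov > 0) W[k, q] <- ov / thickness
    }
  }
  a <- imgData(img)
  dim(a) <- c(d[1] * d[2], d[3])
  out <- a %*% W
  dim(out) <- c(d[1], d[2], nzo)
  newOrigin <- origin(img)
  newOrigin[3] <- origin(img)[3] - sp[3] / 2 + thickness / 2
  imageVolume(out, c(sp[1], sp[2], thickness), newOrigin)
}

#' Apply a random bulk rigid motion to an image and mask
#'
#' Draws one rigid motion - per-axis rotations uniform in
#' [-rotationBound, +rotationBound] degrees and a translation of magnitude
#' \code{translation} mm with random per-axis direction signs - and
#' resamples image and mask onto an output grid padded to contain the moved
#' anatomy. The generating transform is returned for verification.
#'
#' @param img,mask \linkS4class{ImageVolume}s on a common grid.
#' @param translation translation magnitude (mm); 0 gives identity.
#' @param rotationBound per-axis rotation bound (degrees).
#' @param seed integer seed.
#' @param pad extra margin (mm) around the transformed mask bounding box.
#' @return list(image, mask, transform): the transform maps original
#'   coordinates to perturbed coordinates.
#' @export
applyBulkMotion <- function(img, mask, translation, rotationBound = 5,
                            seed = 1L, pad = 12) {
  set.seed(as.integer(seed))
  ang <- stats::runif(3, -rotationBound, rotationBound) * pi / 180
  signs <- sample(c(-1, 1), 3, replace = TRUE)
  if (translation == 0 && rotationBound == 0) {
    tr <- rigidTransform()
    return(list(image = img, mask = mask, transform = tr))
  }
  tvec <- signs * translation / sqrt(3)
  w <- which(imgData(mask) > 0.5, arr.ind = TRUE)
  ctr <- origin(mask) + (colMeans(w) - 1) * spacing(mask)
  tr <- rigidTransform(eulerRotation(ang), tvec, ctr)
  # output grid: original extent union transformed-volume corner extent + pad
  d <- dim(img); sp <- spacing(img); or <- origin(img)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
  cw <- sweep(sweep(corners, 2, sp, "*"), 2, or, "+")
  cwt <- applyRigidTransform(tr, cw)
  lo <- pmin(apply(cw, 2, min), apply(cwt, 2, min)) - pad
  hi <- pmax(apply(cw, 2, max), apply(cwt, 2, max)) + pad
  nd <- as.integer(ceiling((hi - lo) / sp)) + 1L
  outGrid <- imageVolume(array(0, nd), sp, lo)
  pts <- .gridPoints(outGrid)
  inv <- invertRigidTransform(tr)
  src <- applyRigidTransform(inv, pts)
  iv <- sampleVolume(img, src, "cubic")
  mv <- (sampleVolume(mask, src, "linear") >= 0.5) * 1.0
  list(image = imageVolume(array(iv, nd), sp, lo),
       mask = imageVolume(array(mv, nd), sp, lo),
       transform = tr)
}
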