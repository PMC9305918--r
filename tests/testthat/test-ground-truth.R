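test_that("boundary images are binary vertex occupancy with set semantics", {
  grid <- list(dim = c(10L, 10L, 10L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  one <- surfaceMesh(rbind(c(4, 4, 4)), rbind(c(1, 1, 1)))
  b <- meshToBoundaryImage(one, grid)
  expect_identical(sum(imgData(b)), 1)
  two <- surfaceMesh(rbind(c(4.1, 4, 4), c(3.9, 4, 4)), rbind(c(1, 2, 1)))
  expect_identical(sum(imgData(meshToBoundaryImage(two, grid))), 1)
  expect_error(meshToBoundaryImage(
    surfaceMesh(rbind(c(40, 0, 0)), rbind(c(1, 1, 1))), grid), "outside")

  tube <- cylFixture()$mesh
  tg <- gridForMesh(tube, 1, 5)
  bt <- meshToBoundaryImage(tube, tg)
  n <- nrow(vertices(tube))
  expect_lte(sum(imgData(bt)), n)
  expect_gte(sum(imgData(bt)), n / 8)
})

test_that("boundary blurring is an impulse-preserving, mass-conserving filter", {
  z <- imageVolume(array(0, c(24, 24, 24)))
  expect_identical(max(abs(imgData(blurBoundary(z, 3)))), 0)
  imp <- z
  imp@data[12, 12, 12] <- 1
  b <- blurBoundary(imp, 2)
  expect_identical(which.max(imgData(b)), which.max(imp@data))
  expect_lt(abs(sum(imgData(b)) - 1), 1e-3)
  expect_error(blurBoundary(imp, 0), "sigma")
})

test_that("self-registration of identical boundary images is near identity", {
  ph <- tinyPhantom()
  grid <- list(dim = dim(ph$image), spacing = spacing(ph$image),
               origin = origin(ph$image))
  B <- blurBoundary(meshToBoundaryImage(ph$fixedMesh, grid, 0.75), 2)
  fld <- registerBoundaries(B, B, maxIter = 60)
  expect_lt(max(abs(fieldArray(fld))), 0.05)
})

test_that("warping images with fields follows the stated conventions", {
  set.seed(3)
  img <- imageVolume(array(rnorm(16^3), c(16, 16, 16)))
  zero <- displacementField(array(0, c(16, 16, 16, 3)))
  expect_identical(imgData(warpImage(zero, img, "linear")), imgData(img))
  # constant field on a constant image stays constant
  const <- imageVolume(array(7, c(16, 16, 16)))
  shift <- displacementField(array(rep(c(5, 0, 0), each = 16^3),
                                   c(16, 16, 16, 3)))
  expect_identical(unique(as.vector(imgData(warpImage(shift, const, "linear")))), 7)
})

test_that("mesh warping respects identity, rigid translation and domains", {
  m <- cylFixture()$mesh
  grid <- gridForMesh(m, 2, 10)
  zero <- displacementField(array(0, c(grid$dim, 3)), grid$spacing, grid$origin)
  expect_equal(vertices(warpMesh(zero, m)), vertices(m))
  tr <- zero
  tr@field[, , , 1] <- 2.5
  tr@field[, , , 3] <- -1
  w <- warpMesh(tr, m)
  expect_equal(vertices(w) - vertices(m),
               matrix(c(2.5, 0, -1), nrow(vertices(m)), 3, byrow = TRUE),
               tolerance = 1e-6)
  far <- surfaceMesh(rbind(c(1e4, 0, 0)), rbind(c(1, 1, 1)))
  expect_error(warpMesh(zero, far), "outside")
})

test_that("ground-truth synthesis recovers analytic displacements", {
  ph <- studyPhantom()
  gt <- studyGroundTruth()
  dv <- sqrt(rowSums((vertices(gt$gtMesh) - vertices(ph$deformedMesh))^2))
  expect_lt(quantile(dv, 0.99), 0.5)
  # field at the bump apex within 0.3 mm of the analytic displacement
  disp <- meshMeta(ph$deformedMesh)$displacement
  apex <- which.max(sqrt(rowSums(disp^2)))
  u <- fieldAtPoints(gt$field, vertices(ph$fixedMesh)[apex, , drop = FALSE])
  expect_lt(sqrt(sum((u - disp[apex, ])^2)), 0.3)
  # no folding on the dilated mask
  jd <- jacobianDeterminant(gt$field)
  dil <- dilateMask(ph$mask, 5)
  expect_gt(min(imgData(jd)[imgData(dil) > 0.5]), 0)
  # two routes to the moving mask agree
  rd <- rasterizeMesh(ph$deformedMesh, ph$grid)
  a <- imgData(gt$movingMask) > 0.5
  b <- imgData(rd$mask) > 0.5
  expect_gt(2 * sum(a & b) / (sum(a) + sum(b)), 0.98)
  expect_true(gt$field@meta$converged)
})

test_that("bending energy of the ground-truth field falls as bumps widen", {
  # study-scale phantoms; both extents representable on the 8 mm lattice.
  # Evaluated over the bump neighborhood: elsewhere the field carries only
  # the registration's noise floor, which would dilute the comparison.
  be <- sapply(c(16, 40), function(ext) {
    spec <- phantomSpec(deformations = list(list(mode = "radial",
                                                 centerS = 150, extent = ext,
                                                 magnitude = 3)))
    p <- makeGrowthPhantom(spec, gridSpacing = c(1.25, 1.25, 1))
    g <- makeGroundTruth(p$fixedMesh, p$deformedMesh, p$image, p$mask)
    s <- meshMeta(p$fixedMesh)$s
    near <- vertices(p$fixedMesh)[abs(s - 150) < ext / 2 + 10, ]
    lo <- apply(near, 2, min) - 5; hi <- apply(near, 2, max) + 5
    gp <- vdmkit:::.gridPoints(p$mask)
    loc <- array(gp[, 1] >= lo[1] & gp[, 1] <= hi[1] &
                 gp[, 2] >= lo[2] & gp[, 2] <= hi[2] &
                 gp[, 3] >= lo[3] & gp[, 3] <= hi[3], dim(p$mask))
    dil <- imgData(dilateMask(p$mask, 5)) > 0.5
    bendingEnergy(g$field, imageVolume((loc & dil) * 1, spacing(p$mask),
                                       origin(p$mask)))
  })
  expect_true(all(is.finite(be)))
  expect_lt(be[2], be[1])
})

test_that("ground-truth synthesis is deterministic", {
  ph <- tinyPhantom()
  g1 <- makeGroundTruth(ph$fixedMesh, ph$deformedMesh, ph$image, ph$mask)
  g2 <- makeGroundTruth(ph$fixedMesh, ph$deformedMesh, ph$image, ph$mask)
  expect_identical(fieldArray(g1$field), fieldArray(g2$field))
})
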