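test_that("negative HU clamping is exact and idempotent", {
  img <- imageVolume(array(c(-1000, -1, 0, 40, 350), c(5, 1, 1)))
  out <- clampNegative(img)
  expect_identical(as.vector(imgData(out)), c(0, 0, 0, 40, 350))
  pos <- imageVolume(array(runif(27, 1, 100), c(3, 3, 3)))
  expect_identical(imgData(clampNegative(pos)), imgData(pos))
})

test_that("NCC is a correlation: self-score one, affine-invariant, sign-aware", {
  set.seed(4)
  img <- imageVolume(array(rnorm(12^3), c(12, 12, 12)))
  expect_equal(nccScore(img, img), 1, tolerance = 1e-12)
  aff <- imageVolume(3 * imgData(img) + 17, spacing(img), origin(img))
  expect_equal(nccScore(img, aff), 1, tolerance = 1e-12)
  neg <- imageVolume(-imgData(img), spacing(img), origin(img))
  expect_equal(nccScore(img, neg), -1, tolerance = 1e-12)
  flat <- imageVolume(array(5, c(12, 12, 12)))
  expect_error(nccScore(flat, img), "constant")
})

test_that("mutual information behaves like an information measure", {
  # MI(X, X) = H(X): exercised on a discrete 8-level image whose values are
  # far apart relative to the Parzen window, so smoothing bias is small
  set.seed(5)
  lv <- seq(0, 700, by = 100)
  v <- array(sample(lv, 20^3, replace = TRUE), c(20, 20, 20))
  img <- imageVolume(v)
  mi <- mutualInformation(img, img, nbins = 32)
  h <- local({
    p <- table(v) / length(v)
    -sum(p * log(p))
  })
  expect_gt(mi, 0)
  expect_lt(abs(mi - h) / h, 0.1)
  # independent volumes carry (almost) no mutual information
  set.seed(6)
  other <- imageVolume(array(rnorm(64^3), c(64, 64, 64)))
  set.seed(7)
  other2 <- imageVolume(array(rnorm(64^3), c(64, 64, 64)))
  expect_lt(mutualInformation(other, other2), 0.05 * log(2))
  # invariance under a monotone intensity remapping of the moving image
  # (texture-free fixture: binning effects are smallest on a clean pair)
  ph <- tinyPhantom()
  base <- rasterizeMesh(ph$fixedMesh, ph$grid, intensityModel(textureSD = 0))$image
  remap <- imageVolume(sqrt(imgData(base) + 10) * 25, spacing(base),
                       origin(base))
  m1 <- mutualInformation(base, base)
  m2 <- mutualInformation(base, remap)
  expect_lt(abs(m2 - m1) / m1, 0.02)
})

# naive loop-based oracle for the bending integrand on a dense field
.bendingOracle <- function(field) {
  u <- field@field; sp <- spacing(field); d <- dim(u)[1:3]
  acc <- 0; n <- 0
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    for (c in 1:3) {
      hxx <- (u[i + 1, j, k, c] - 2 * u[i, j, k, c] + u[i - 1, j, k, c]) / sp[1]^2
      hyy <- (u[i, j + 1, k, c] - 2 * u[i, j, k, c] + u[i, j - 1, k, c]) / sp[2]^2
      hzz <- (u[i, j, k + 1, c] - 2 * u[i, j, k, c] + u[i, j, k - 1, c]) / sp[3]^2
      hxy <- (u[i + 1, j + 1, k, c] - u[i + 1, j - 1, k, c] -
              u[i - 1, j + 1, k, c] + u[i - 1, j - 1, k, c]) / (4 * sp[1] * sp[2])
      hxz <- (u[i + 1, j, k + 1, c] - u[i + 1, j, k - 1, c] -
              u[i - 1, j, k + 1, c] + u[i - 1, j, k - 1, c]) / (4 * sp[1] * sp[3])
      hyz <- (u[i, j + 1, k + 1, c] - u[i, j + 1, k - 1, c] -
              u[i, j - 1, k + 1, c] + u[i, j - 1, k - 1, c]) / (4 * sp[2] * sp[3])
      acc <- acc + hxx^2 + hyy^2 + hzz^2 + 2 * (hxy^2 + hxz^2 + hyz^2)
    }
    n <- n + 1
  }
  acc / n
}

test_that("bending energy vanishes on affine fields and matches its oracle", {
  d <- c(16, 16, 16)
  pts <- vdmkit:::.gridPoints(imageVolume(array(0, d)))
  A <- matrix(c(0.1, 0.02, 0, -0.01, 0.05, 0.03, 0, 0.01, -0.02), 3, 3)
  uA <- pts %*% t(A) + matrix(c(1, -2, 0.5), nrow(pts), 3, byrow = TRUE)
  affine <- displacementField(array(uA, c(d, 3)))
  expect_lt(bendingEnergy(affine), 1e-10)

  # u_x = x^2 on a unit grid: second derivative 2 everywhere, penalty 4
  quad <- displacementField(array(c(pts[, 1]^2, 0 * pts[, 1], 0 * pts[, 1]),
                                  c(d, 3)))
  expect_equal(bendingEnergy(quad), 4, tolerance = 1e-10)
  # quadratic scaling in the field amplitude
  quad3 <- displacementField(3 * quad@field)
  expect_equal(bendingEnergy(quad3), 9 * bendingEnergy(quad), tolerance = 1e-10)

  set.seed(8)
  smooth <- displacementField(array(
    as.vector(vdmkit:::.gauss_blur3(array(rnorm(prod(d) * 3), c(d, 3))[, , , 1],
                                    as.integer(d), c(2, 2, 2), FALSE)) |>
      rep(3), c(d, 3)))
  expect_lt(abs(bendingEnergy(smooth) - .bendingOracle(smooth)) /
            .bendingOracle(smooth), 0.01)
})

test_that("rigidity penalty is zero for rigid motion, exact for scaling", {
  d <- c(12, 12, 12)
  pts <- vdmkit:::.gridPoints(imageVolume(array(0, d)))
  tr <- displacementField(array(rep(c(3, -1, 2), each = prod(d)), c(d, 3)))
  expect_lt(rigidityPenalty(tr), 1e-10)

  R <- eulerRotation(c(0, 0, 10 * pi / 180))
  uR <- pts %*% t(R) - pts
  rot <- displacementField(array(uR, c(d, 3)))
  expect_lt(rigidityPenalty(rot), 1e-8)

  uS <- 0.1 * pts   # isotropic scaling by 1.1
  sc <- displacementField(array(uS, c(d, 3)))
  closedForm <- 3 * 0.21^2 + (1.1^3 - 1)^2   # OC + PC, LN = 0
  expect_equal(rigidityPenalty(sc), closedForm, tolerance = 1e-8)
})

test_that("rigidity map is a ball dilation of the mask", {
  m <- imageVolume(array(0, c(9, 9, 9)))
  m@data[5, 5, 5] <- 1
  d1 <- makeRigidityMap(m, 1)
  expect_identical(sum(imgData(d1)), 7)   # 6-cross plus center
  expect_identical(imgData(makeRigidityMap(m, 0)), imgData(m))
  big <- makeRigidityMap(m, 3)
  expect_true(all(imgData(big)[imgData(m) > 0.5] == 1))
  expect_error(makeRigidityMap(imageVolume(array(0, c(4, 4, 4)))), "empty")
})

test_that("rigid stage recovers synthetic rigid motions", {
  ph <- studyPhantom()
  gt <- studyGroundTruth()
  for (lvl in c(20, 60)) {
    bm <- applyBulkMotion(gt$movingImage, gt$movingMask, lvl,
                          rotationBound = 5, seed = 11 + lvl)
    rt <- rigidStage(clampNegative(ph$image), clampNegative(bm$image),
                     ph$mask, bm$mask)
    pts <- vertices(ph$fixedMesh)[seq(1, nrow(vertices(ph$fixedMesh)), 50), ]
    err <- applyRigidTransform(rt, pts) - applyRigidTransform(bm$transform, pts)
    expect_lt(max(sqrt(rowSums(err^2))), 0.5)
    ang <- function(R) acos(pmin(1, (sum(diag(R)) - 1) / 2)) * 180 / pi
    dR <- t(rt@rotation) %*% bm$transform@rotation
    expect_lt(ang(dR), 0.2)
  }
  self <- rigidStage(ph$image, ph$image, ph$mask, ph$mask)
  expect_lt(sqrt(sum(self@translation^2)), 0.1)
})

test_that("the composed VDM field is deterministic and does not fold", {
  ph <- tinyPhantom()
  gt <- memo("tinyGT", makeGroundTruth(ph$fixedMesh, ph$deformedMesh,
                                       ph$image, ph$mask))
  f1 <- memo("tinyVDM", runVDM(ph$image, gt$movingImage, ph$mask, gt$movingMask))
  f2 <- runVDM(ph$image, gt$movingImage, ph$mask, gt$movingMask)
  expect_identical(fieldArray(f1), fieldArray(f2))
  jd <- jacobianDeterminant(f1)
  dil <- dilateMask(ph$mask, 5)
  expect_gt(min(imgData(jd)[imgData(dil) > 0.5]), 0)
})

test_that("the rigidity penalty keeps the aorta near-rigid when enabled", {
  ph <- tinyPhantom()
  gt <- memo("tinyGT", makeGroundTruth(ph$fixedMesh, ph$deformedMesh,
                                       ph$image, ph$mask))
  rigMap <- makeRigidityMap(ph$mask, 5)
  ocOf <- function(w) {
    f <- centerlineAlignmentStage(clampNegative(ph$image),
                                  clampNegative(gt$movingImage), rigMap,
                                  stageConfig("MI", 10, w, 10),
                                  samplingRegion = vdmkit:::.maskShell(ph$mask, 12))
    rigidityPenalty(f, rigMap)
  }
  expect_lt(ocOf(20), ocOf(0))
})
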