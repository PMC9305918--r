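test_that("diameter profile is exact on a cylinder and under shear", {
  fx <- cylFixture(nCirc = 48, axialStep = 1)
  pr <- diameterProfile(fx$mesh, fx$centerline, 0.5)
  ok <- !is.na(pr@d) & pr@stations > 5 & pr@stations < 95
  expect_true(any(ok))
  expect_lt(max(abs(pr@d[ok] - 30)), 0.1)
  expect_equal(unique(round(diff(pr@stations), 9)), 0.5)

  # x-stretched tube: elliptical section a = 20, b = 15, max chord 40
  sheared <- surfaceMesh(vertices(fx$mesh) %*% diag(c(4 / 3, 1, 1)),
                         faces(fx$mesh))
  ps <- diameterProfile(sheared, fx$centerline, 1)
  oks <- !is.na(ps@d) & ps@stations > 5 & ps@stations < 95
  expect_lt(max(abs(ps@d[oks] - 40)) / 40, 0.005)
})

test_that("a radial bulge adds twice its magnitude to the diameter", {
  fx <- cylFixture(nCirc = 48, axialStep = 1)
  b <- applyRadialBulge(fx$mesh, 50, 30, 2)
  pr <- diameterProfile(fx$mesh, fx$centerline, 0.5)
  pb <- diameterProfile(b, fx$centerline, 0.5)
  i <- which.min(abs(pr@stations - 50))
  expect_lt(abs(pb@d[i] - pr@d[i] - 4), 0.2)
  mc <- maxDiameterChange(pr, pb)
  expect_lt(abs(mc$location - 50), 2)
  expect_lt(abs(mc$magnitude - 4), 0.2)
})

test_that("max diameter change is plain arithmetic with deterministic ties", {
  p1 <- new("DiameterProfile", stations = c(0, 0.5, 1), d = c(30, 30, 30))
  p2 <- new("DiameterProfile", stations = c(0, 0.5, 1), d = c(30.1, 32.3, 30.7))
  mc <- maxDiameterChange(p1, p2)
  expect_equal(mc$magnitude, 2.3)
  expect_equal(mc$location, 0.5)
  expect_equal(maxDiameterChange(p1, p1)$magnitude, 0)
  tie <- new("DiameterProfile", stations = c(0, 0.5, 1), d = c(32, 30, 32))
  expect_equal(maxDiameterChange(p1, tie)$location, 0)   # first maximum
  bad <- new("DiameterProfile", stations = c(0, 1, 2), d = c(30, 30, 30))
  expect_error(maxDiameterChange(p1, bad), "stations")
})

test_that("centerline extraction recovers canonical geometries", {
  # straight cylinder: collinear with the axis
  fx <- cylFixture(nCirc = 32, axialStep = 1.5)
  msk <- memo("cylMask", rasterizeMesh(fx$mesh, gridForMesh(fx$mesh, 1, 5))$mask)
  ec <- extractCenterline(msk)
  expect_lt(max(sqrt(ec@points[, 1]^2 + ec@points[, 2]^2)), 0.5)

  # torus section (arch-only phantom): curvature radius within 5%
  spec <- phantomSpec(ascendingLength = 25, archRadius = 30,
                      descendingLength = 25, lumenRadius = 9)
  cl <- makeCenterline(spec)
  tube <- makeTubeMesh(cl, 9, 32, 1.5)
  tmask <- rasterizeMesh(tube, gridForMesh(tube, 1, 5))$mask
  et <- extractCenterline(tmask)
  onArch <- abs(et@points[, 3] - 30) < 25 & et@points[, 3] > 26
  archPts <- et@points[onArch, c(1, 3)]
  # algebraic circle fit in the arch plane
  A <- cbind(2 * archPts, 1)
  b <- rowSums(archPts^2)
  sol <- qr.solve(A, b)
  rfit <- sqrt(sol[3] + sum(sol[1:2]^2))
  expect_lt(abs(rfit - 30) / 30, 0.05)

  # generated candy-cane: mean distance to the generating curve < 1 mm
  ph <- studyPhantom()
  ecl <- memo("studyCenterline", extractCenterline(ph$mask))
  dmin <- apply(ecl@points, 1, function(p)
    sqrt(min(colSums((t(ph$centerline@points) - p)^2))))
  expect_lt(mean(dmin), 1)
})

test_that("profiles are invariant when mesh and centerline move together", {
  fx <- cylFixture(nCirc = 32, axialStep = 1.5)
  pr <- diameterProfile(fx$mesh, fx$centerline, 2)
  tr <- rigidTransform(eulerRotation(c(0.2, 0.1, -0.3)), c(7, -4, 11))
  mmesh <- surfaceMesh(applyRigidTransform(tr, vertices(fx$mesh)), faces(fx$mesh))
  mcl <- new("CenterlineCurve",
             points = applyRigidTransform(tr, fx$centerline@points),
             arcLength = fx$centerline@arcLength,
             tangents = fx$centerline@tangents %*% t(tr@rotation))
  pm <- diameterProfile(mmesh, mcl, 2)
  ok <- !is.na(pr@d) & !is.na(pm@d)
  expect_lt(max(abs(pr@d[ok] - pm@d[ok])), 0.01)
})

test_that("refining the station spacing never loses the detected maximum", {
  fx <- cylFixture(nCirc = 32, axialStep = 1.5)
  b <- applyRadialBulge(fx$mesh, 50, 24, 1.5)
  coarse <- maxDiameterChange(diameterProfile(fx$mesh, fx$centerline, 2),
                              diameterProfile(b, fx$centerline, 2))
  fine <- maxDiameterChange(diameterProfile(fx$mesh, fx$centerline, 1),
                            diameterProfile(b, fx$centerline, 1))
  expect_gte(fine$magnitude, coarse$magnitude - 1e-9)
})

test_that("VDM diameter change vanishes for a zero field", {
  fx <- cylFixture(nCirc = 32, axialStep = 1.5)
  grid <- gridForMesh(fx$mesh, 2, 10)
  zero <- displacementField(array(0, c(grid$dim, 3)), grid$spacing, grid$origin)
  mc <- vdmDiameterChange(fx$mesh, zero, fx$centerline, step = 2)
  expect_equal(mc$magnitude, 0)
})
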