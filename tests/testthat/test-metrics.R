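test_that("area ratio is exact under identity and similarity scaling", {
  m <- cylFixture(nCirc = 32, axialStep = 2)$mesh
  expect_equal(areaRatio(m, m), rep(1, nrow(faces(m))), tolerance = 1e-12)
  k <- 1.3
  scaled <- surfaceMesh(k * sweep(vertices(m), 2, c(5, -2, 8), "+"), faces(m))
  expect_equal(areaRatio(m, scaled), rep(k^2, nrow(faces(m))), tolerance = 1e-9)
  bad <- surfaceMesh(vertices(m) * 0, faces(m))
  expect_error(areaRatio(bad, m), "zero-area")
})

test_that("cylinder dilation gives the analytic circumferential stretch", {
  fx <- cylFixture(nCirc = 64, axialStep = 1)
  m <- fx$mesh
  s <- meshMeta(m)$s
  rad <- meshMeta(m)$radial
  dil <- surfaceMesh(vertices(m) + 1.5 * rad, faces(m), meshMeta(m))
  f <- faces(m)
  interior <- s[f[, 1]] > 10 & s[f[, 1]] < 90
  ar <- areaRatio(m, dil)
  expect_equal(ar[interior], rep(16.5 / 15, sum(interior)), tolerance = 0.005)
  # DiN equals the dilation on lateral vertices
  din <- deformationInNormal(m, dil)
  lat <- s > 10 & s < 90
  expect_equal(din[lat], rep(1.5, sum(lat)), tolerance = 0.015)
  # pure tangential slide (rotation about the axis) has zero DiN
  th <- 2 * pi / 64
  rot <- surfaceMesh(vertices(m) %*% t(eulerRotation(c(0, 0, th))), faces(m))
  expect_lt(max(abs(deformationInNormal(m, rot)[lat])), 0.08)
})

test_that("vertex normals match analytic directions on canonical shapes", {
  m <- cylFixture(nCirc = 64, axialStep = 0.75)$mesh
  n <- vertexNormals(m)
  s <- meshMeta(m)$s
  rad <- meshMeta(m)$radial
  lat <- s > 5 & s < 95
  ang <- acos(pmin(1, rowSums(n * rad)))[lat] * 180 / pi
  expect_lt(max(ang), 1)

  sph <- sphereMesh()
  ns <- vertexNormals(sph)
  dirs <- vertices(sph) / sqrt(rowSums(vertices(sph)^2))
  expect_lt(max(acos(pmin(1, rowSums(ns * dirs))) * 180 / pi), 1)

  # flat patch: interior vertex normal equals the face normal exactly
  flat <- surfaceMesh(cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5), 0),
                      rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5)))
  nf <- vertexNormals(flat)
  expect_equal(nf[5, ], c(0, 0, 1), tolerance = 1e-12)
})

test_that("sphere scaling oracle: AR = k^2 and DiN = (k-1) r", {
  sph <- sphereMesh(r = 10)
  k <- 1.07
  grown <- surfaceMesh(k * vertices(sph), faces(sph))
  expect_equal(areaRatio(sph, grown), rep(k^2, nrow(faces(sph))),
               tolerance = 1e-9)
  din <- deformationInNormal(sph, grown)
  expect_equal(din, rep((k - 1) * 10, length(din)), tolerance = 0.02)
})

test_that("face-to-vertex interpolation is an area-weighted partition", {
  m <- cylFixture(nCirc = 32, axialStep = 2)$mesh
  const <- interpolateFaceToVertex(rep(3.5, nrow(faces(m))), m)
  expect_equal(const, rep(3.5, nrow(vertices(m))), tolerance = 1e-12)
  one <- rep(0, nrow(faces(m))); one[10] <- 1
  v <- interpolateFaceToVertex(one, m)
  touched <- sort(unique(as.vector(faces(m)[10, ])))
  expect_identical(sort(which(v != 0)), touched)
})

test_that("growth metrics are invariant under a common rigid motion", {
  ph <- tinyPhantom()
  g0 <- computeGrowthMetrics(ph$fixedMesh, ph$deformedMesh)
  tr <- rigidTransform(eulerRotation(c(0.3, -0.2, 0.5)), c(10, -5, 3), c(1, 2, 3))
  mv <- function(m) surfaceMesh(applyRigidTransform(tr, vertices(m)), faces(m))
  g1 <- computeGrowthMetrics(mv(ph$fixedMesh), mv(ph$deformedMesh))
  expect_equal(g1@ar, g0@ar, tolerance = 1e-9)
  expect_equal(g1@din, g0@din, tolerance = 1e-9)
})

test_that("error summaries match a sort-based oracle and hand values", {
  ph <- tinyPhantom()
  gt <- computeGrowthMetrics(ph$fixedMesh, ph$deformedMesh)
  zero <- growthAbsoluteError(gt, gt, ph$fixedMesh, 1e-3)
  expect_true(all(zero$summary[, c("p99", "p95", "median", "mean")] == 0))

  meas <- gt
  set.seed(9)
  meas@din <- gt@din + rnorm(length(gt@din), 0, 0.1)
  meas@ar <- gt@ar * exp(rnorm(length(gt@ar), 0, 0.02))
  e <- growthAbsoluteError(gt, meas, ph$fixedMesh, 1e-3)
  oA <- summaryOracle(e$arErrors)
  oD <- summaryOracle(e$dinErrors)
  sA <- e$summary[e$summary$metric == "AR", ]
  sD <- e$summary[e$summary$metric == "DiN", ]
  expect_equal(unlist(sA[c("p99", "p95", "median", "mean", "sd")]),
               unlist(oA), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unlist(sD[c("p99", "p95", "median", "mean", "sd")]),
               unlist(oD), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(sD$p99 >= sD$p95 && sD$p95 >= sD$median)

  # hand-built 5-element case
  hand <- summaryOracle(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(hand$median, 0.3)
  expect_equal(hand$mean, 0.3)
})

test_that("relative error follows the perturbation convention", {
  expect_equal(growthRelativeError(0.2, 0.2, 1.5), 0)
  expect_equal(growthRelativeError(0.3, 0.2, 2.0), 5)
  expect_error(growthRelativeError(0.3, 0.2, 0), "zero")
})

test_that("empty deformed regions are rejected", {
  m <- cylFixture(nCirc = 32, axialStep = 2)$mesh
  g <- computeGrowthMetrics(m, m)
  expect_error(growthAbsoluteError(g, g, m, 1e-3), "empty")
})
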