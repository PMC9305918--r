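test_that("centerline geometry matches analytic segment lengths", {
  straight <- makeCenterline(phantomSpec(ascendingLength = 100, archRadius = 0,
                                         descendingLength = 0))
  expect_equal(max(straight@arcLength), 100, tolerance = 1e-9)

  arch <- makeCenterline(phantomSpec(ascendingLength = 0, archRadius = 30,
                                     descendingLength = 0))
  expect_lt(abs(max(arch@arcLength) - pi * 30), 0.1)

  cc <- makeCenterline(phantomSpec())
  expect_equal(sqrt(rowSums(cc@tangents^2)), rep(1, nrow(cc@tangents)),
               tolerance = 1e-9)
  # non-self-intersection: non-adjacent samples further apart than a lumen
  p <- cc@points[seq(1, nrow(cc@points), by = 8), ]
  dd <- as.matrix(dist(p))
  k <- nrow(p)
  far <- abs(row(dd) - col(dd)) > 8   # skip near-diagonal (adjacent) pairs
  expect_gt(min(dd[far]), 2 * 12)
})

test_that("tube mesh has analytic lateral area, converging with refinement", {
  cl <- cylFixture()$centerline
  analytic <- 2 * pi * 15 * 100
  areas <- sapply(c(8, 16, 32, 64), function(nc) {
    m <- makeTubeMesh(cl, 15, nc, 1)
    sum(vdmkit:::.faceAreasAndNormals(m)$areas)
  })
  expect_lt(abs(areas[4] - analytic) / analytic, 0.005)
  # monotone convergence toward the analytic value from below
  expect_true(all(diff(areas) > 0))
  expect_true(all(areas < analytic))
})

test_that("tube faces are consistently oriented with outward normals", {
  m <- cylFixture()$mesh
  fa <- vdmkit:::.faceAreasAndNormals(m)
  rad <- meshMeta(m)$radial
  f <- faces(m)
  faceRadial <- (rad[f[, 1], ] + rad[f[, 2], ] + rad[f[, 3], ]) / 3
  expect_true(all(rowSums(fa$normals * faceRadial) > 0))
})

test_that("radial bulge displaces the apex exactly and is compactly supported", {
  m <- cylFixture()$mesh
  expect_equal(vertices(applyRadialBulge(m, 50, 30, 0)), vertices(m))

  b <- applyRadialBulge(m, 50, 30, 2.5)
  expect_identical(faces(b), faces(m))
  s <- meshMeta(m)$s
  apex <- which(abs(s - 50) < 1e-9)
  rdist <- sqrt(rowSums((vertices(b)[apex, , drop = FALSE] -
                         cbind(0, 0, s[apex]))^2))
  expect_equal(rdist, rep(17.5, length(apex)), tolerance = 1e-9)
  outside <- abs(s - 50) >= 15
  expect_equal(vertices(b)[outside, ], vertices(m)[outside, ])
  # analytic displacement bounded by the requested magnitude, equal at apex
  disp <- sqrt(rowSums(meshMeta(b)$displacement^2))
  expect_lte(max(disp), 2.5 + 1e-12)
  expect_equal(max(disp[apex]), 2.5, tolerance = 1e-12)
})

test_that("sculpt bulge is exact at its center and zero outside the sector", {
  m <- cylFixture()$mesh
  expect_equal(vertices(applySculptBulge(m, 50, 0, 30, pi, 0)), vertices(m))
  b <- applySculptBulge(m, 50, 0, 30, pi, 2)
  s <- meshMeta(m)$s; th <- meshMeta(m)$theta
  ctr <- which(abs(s - 50) < 1e-9 & abs(th) < 1e-9)
  expect_length(ctr, 1L)
  d <- vertices(b)[ctr, ] - vertices(m)[ctr, ]
  expect_equal(sqrt(sum(d^2)), 2, tolerance = 1e-9)
  dtheta <- (th + pi) %% (2 * pi) - pi
  outside <- abs(s - 50) >= 15 | abs(dtheta) >= pi / 2
  expect_equal(vertices(b)[outside, ], vertices(m)[outside, ])
})

test_that("drag translates the core rigidly with monotone blend", {
  m <- cylFixture()$mesh
  expect_equal(vertices(applyDrag(m, c(20, 60), c(0, 0, 0))), vertices(m))
  tr <- c(3, -2, 5)
  b <- applyDrag(m, c(20, 60), tr, falloff = 15)
  s <- meshMeta(m)$s
  core <- s >= 20 & s <= 60
  expect_equal(vertices(b)[core, ] - vertices(m)[core, ],
               matrix(tr, sum(core), 3, byrow = TRUE), tolerance = 1e-12)
  # blend zone: displacement magnitude non-increasing with distance
  zone <- s > 60 & s < 75
  zd <- sqrt(rowSums((vertices(b) - vertices(m))[zone, ]^2))
  ord <- order(s[zone])
  expect_true(all(diff(zd[ord]) <= 1e-9))
  expect_error(applyDrag(m, c(20, 60), tr, falloff = 0), "falloff")
  expect_error(applyDrag(m, c(20, 60), c(20, 0, 0)), "physiologic")
})

test_that("rasterization reproduces the analytic cylinder volume", {
  cyl <- cylFixture()$mesh
  grid <- gridForMesh(cyl, spacing = 0.64, margin = 6)
  ras <- rasterizeMesh(cyl, grid, intensityModel(textureSD = 0))
  vol <- sum(imgData(ras$mask)) * prod(spacing(ras$mask))
  expect_lt(abs(vol - pi * 15^2 * 100) / (pi * 15^2 * 100), 0.02)
  # constant interior, background elsewhere
  ctr <- round(dim(ras$image) / 2)
  expect_identical(imgData(ras$image)[ctr[1], ctr[2], ctr[3]], 350)
  expect_identical(imgData(ras$image)[1, 1, 1], 40)
  expect_error(rasterizeMesh(cyl, gridForMesh(cyl, 0.64, margin = -20)),
               "bounding box")
})

test_that("boundary antialiasing error shrinks with supersampling", {
  cyl <- makeTubeMesh(cylFixture()$centerline, 15, 32, 2)
  grid <- gridForMesh(cyl, spacing = 2, margin = 6)
  ref <- rasterizeMesh(cyl, grid, intensityModel(supersampling = 8))$image
  errFor <- function(ss) {
    img <- rasterizeMesh(cyl, grid, intensityModel(supersampling = ss))$image
    boundary <- imgData(ref) > 45 & imgData(ref) < 345
    mean(abs(imgData(img) - imgData(ref))[boundary])
  }
  expect_lt(errFor(4), errFor(1))
})

test_that("deformation operators never touch connectivity", {
  ph <- tinyPhantom()
  expect_identical(faces(ph$deformedMesh), faces(ph$fixedMesh))
  # mask of deformed equals mask of fixed outside the deformation support
  rd <- rasterizeMesh(ph$deformedMesh, ph$grid)
  disp <- meshMeta(ph$deformedMesh)$displacement
  moved <- vertices(ph$fixedMesh)[rowSums(abs(disp)) > 0, , drop = FALSE]
  lo <- apply(moved, 2, min) - 3; hi <- apply(moved, 2, max) + 3
  pts <- vdmkit:::.gridPoints(ph$mask)
  outside <- pts[, 1] < lo[1] | pts[, 1] > hi[1] | pts[, 2] < lo[2] |
             pts[, 2] > hi[2] | pts[, 3] < lo[3] | pts[, 3] > hi[3]
  expect_identical(as.vector(imgData(rd$mask))[outside],
                   as.vector(imgData(ph$mask))[outside])
})

test_that("radius profiles support constants, tapers and functions", {
  cl <- cylFixture()$centerline
  mT <- makeTubeMesh(cl, c(14, 10), 16, 2)
  s <- meshMeta(mT)$s
  r <- sqrt(rowSums((vertices(mT) - cbind(0, 0, s))^2))
  expect_equal(r, 14 + (10 - 14) * s / 100, tolerance = 1e-9)
  expect_error(makeTubeMesh(cl, function(s) s - 50, 16, 2), "positive")
})
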