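test_that("gaussian noise has the requested statistics and is seeded", {
  img <- imageVolume(array(100, c(64, 64, 64)))
  expect_identical(imgData(addGaussianNoise(img, 0)), imgData(img))
  n1 <- addGaussianNoise(img, 150, seed = 3)
  expect_lt(abs(sd(imgData(n1)) - 150) / 150, 0.01)
  n2 <- addGaussianNoise(img, 150, seed = 3)
  expect_identical(imgData(n1), imgData(n2))
  expect_false(identical(imgData(addGaussianNoise(img, 150, seed = 4)),
                         imgData(n1)))
  expect_error(addGaussianNoise(img, -1), "sigma")
})

test_that("CNR matches its closed form on constructed ROIs", {
  d <- c(30, 30, 30)
  mask <- imageVolume(array(0, d))
  mask@data[6:25, 6:25, 6:25] <- 1
  roi <- erodeMask(mask, 3, "voxels")
  bg <- imageVolume(array(0, d))
  bg@data[1:4, , ] <- 1
  img <- imageVolume(array(0, d))
  fill <- function(n, mu, sd0) {
    x <- rnorm(n)
    (x - mean(x)) / sd(x) * sd0 + mu   # exact sample moments
  }
  set.seed(10)
  img@data[imgData(roi) > 0.5] <- fill(sum(imgData(roi)), 300, 100)
  img@data[imgData(bg) > 0.5] <- fill(sum(imgData(bg)), 0, 100)
  expect_lt(abs(computeCNR(img, mask, bg) - 300 / sqrt(20000)), 0.01)
  # zero-variance ROIs are an error, not a division by zero
  flat <- imageVolume(array(5, d))
  expect_error(computeCNR(flat, mask, bg), "variance")
})

test_that("CNR decreases monotonically with added noise and sigmaForCNR inverts it", {
  ph <- tinyPhantom()
  # the clean textured phantom has a finite, large CNR
  expect_gt(computeCNR(ph$image, ph$mask), 5)
  cnrs <- sapply(c(30, 60, 90, 120), function(sg)
    computeCNR(addGaussianNoise(ph$image, sg, seed = 2), ph$mask))
  expect_true(all(diff(cnrs) < 0))
  sg <- sigmaForCNR(ph$image, ph$mask, 2.66)
  got <- computeCNR(addGaussianNoise(ph$image, sg, seed = 2), ph$mask)
  expect_lt(abs(got - 2.66) / 2.66, 0.05)
  noisy <- addGaussianNoise(ph$image, 120, seed = 3)
  expect_error(sigmaForCNR(noisy, ph$mask, 1e6), "unreachable")
})

test_that("slice-profile resampling conserves intensity mass", {
  img <- imageVolume(array(rep(40, 20^3), c(20, 20, 20)),
                     spacing = c(1, 1, 1))
  expect_identical(imgData(resampleSliceThickness(img, 1)), imgData(img))
  out <- resampleSliceThickness(img, 2)
  expect_identical(unique(as.vector(imgData(out))), 40)
  expect_equal(spacing(out)[3], 2)
  # a thin bright band keeps its integrated mass
  band <- img
  band@data[, , 10] <- 500
  b2 <- resampleSliceThickness(band, 2)
  massIn <- sum(imgData(band) - 40) * 1
  massOut <- sum(imgData(b2) - 40) * 2
  expect_lt(abs(massOut - massIn) / massIn, 0.01)
  expect_error(resampleSliceThickness(img, 0.5), "below native")
})

test_that("bulk motion is seeded, invertible and identity at level zero", {
  ph <- tinyPhantom()
  id <- applyBulkMotion(ph$image, ph$mask, 0, rotationBound = 0, seed = 5)
  expect_identical(imgData(id$image), imgData(ph$image))
  expect_equal(id$transform@rotation, diag(3))
  b1 <- applyBulkMotion(ph$image, ph$mask, 20, seed = 6)
  b2 <- applyBulkMotion(ph$image, ph$mask, 20, seed = 6)
  expect_identical(b1$transform@translation, b2$transform@translation)
  expect_identical(imgData(b1$image), imgData(b2$image))
  expect_equal(sqrt(sum(b1$transform@translation^2)), 20, tolerance = 1e-9)
  # the mask content survives the move (same voxel count within tolerance)
  expect_lt(abs(sum(imgData(b1$mask)) - sum(imgData(ph$mask))) /
            sum(imgData(ph$mask)), 0.05)
})
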