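# Shared fixtures, all generated in code and memoized across test files.
.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# straight cylinder r = 15 mm, length 100 mm
cylFixture <- function(nCirc = 48, axialStep = 1) {
  key <- paste0("cyl_", nCirc, "_", axialStep)
  memo(key, {
    spec <- phantomSpec(ascendingLength = 100, archRadius = 0,
                        descendingLength = 0)
    cl <- makeCenterline(spec)
    list(centerline = cl,
         mesh = makeTubeMesh(cl, 15, nCirc, axialStep))
  })
}

# UV-sphere mesh for normal/metric oracles
sphereMesh <- function(r = 10, nTheta = 24, nPhi = 16) {
  memo(paste0("sphere_", r), {
    phi <- seq(0, pi, length.out = nPhi)[-c(1, nPhi)]
    theta <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
    v <- rbind(c(0, 0, r),
               do.call(rbind, lapply(phi, function(p)
                 cbind(r * sin(p) * cos(theta), r * sin(p) * sin(theta),
                       r * cos(p)))),
               c(0, 0, -r))
    n <- length(phi)
    idx <- function(i, j) 1L + (i - 1L) * nTheta + ((j - 1L) %% nTheta) + 1L - 1L
    f <- NULL
    for (j in seq_len(nTheta)) {   # polar caps
      f <- rbind(f, c(1L, 1L + j, 1L + (j %% nTheta) + 1L))
      base <- 1L + (n - 1L) * nTheta
      f <- rbind(f, c(nrow(v), base + (j %% nTheta) + 1L, base + j))
    }
    for (i in seq_len(n - 1L)) for (j in seq_len(nTheta)) {
      a <- 1L + (i - 1L) * nTheta + j
      b <- 1L + (i - 1L) * nTheta + (j %% nTheta) + 1L
      cc <- 1L + i * nTheta + j
      dd <- 1L + i * nTheta + (j %% nTheta) + 1L
      f <- rbind(f, c(a, b, cc), c(b, dd, cc))
    }
    # enforce outward orientation (convex body: normal and position agree)
    m <- surfaceMesh(v, f)
    fn <- vdmkit:::.faceAreasAndNormals(m)$normals
    ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
    flip <- rowSums(fn * ctr) < 0
    f[flip, ] <- f[flip, c(1, 3, 2)]
    surfaceMesh(v, f)
  })
}

# the standard desk-scale study phantom used across registration tests
studyPhantom <- function() {
  memo("studyPhantom",
       makeStudyPhantom("descending", "radial", 2.5, seed = 2,
                        gridSpacing = c(1.25, 1.25, 1)))
}

studyGroundTruth <- function() {
  memo("studyGT", {
    ph <- studyPhantom()
    makeGroundTruth(ph$fixedMesh, ph$deformedMesh, ph$image, ph$mask)
  })
}

studyVDM <- function() {
  memo("studyVDM", {
    ph <- studyPhantom()
    gt <- studyGroundTruth()
    runVDM(ph$image, gt$movingImage, ph$mask, gt$movingMask)
  })
}

# small, fast phantom for determinism/integration checks
tinyPhantom <- function() {
  memo("tinyPhantom", {
    spec <- phantomSpec(ascendingLength = 20, archRadius = 15,
                        descendingLength = 25, lumenRadius = 8, nCirc = 24,
                        deformations = list(list(mode = "radial", centerS = 55,
                                                 extent = 20, magnitude = 2)))
    makeGrowthPhantom(spec, gridSpacing = c(1.5, 1.5, 1.5), margin = 8)
  })
}

# the shared n = 10 population study (acceptance criteria 3, 4, 6)
populationStudy <- function() {
  memo("population",
       runPopulationStudy(nPhantoms = 10, seed = 1, keepData = TRUE))
}

# naive percentile/summary oracle: plain sort-based statistics
summaryOracle <- function(x) {
  xs <- sort(x)
  q <- function(p) stats::quantile(xs, p, names = FALSE)
  list(p99 = q(0.99), p95 = q(0.95), median = stats::median(xs),
       mean = mean(xs), sd = stats::sd(xs))
}
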