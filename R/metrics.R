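#' Mesh-based aortic growth metrics
#'
#' Growth between two corresponding surfaces is quantified by the per-face
#' area ratio AR (deformed area over fixed area; 1 means no areal change)
#' and the per-vertex deformation in the normal direction DiN: the signed
#' projection of the vertex displacement onto the fixed-surface outward
#' normal, in millimeters, with outward growth positive.
#'
#' @name growthMetrics
NULL

.faceAreasAndNormals <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh)
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  list(areas = nrm / 2, normals = cr / pmax(nrm, 1e-300))
}

#' Per-face area ratio between corresponding meshes
#'
#' @param fixed,deformed \linkS4class{SurfaceMesh}es with identical
#'   connectivity (positional vertex correspondence).
#' @return numeric vector: deformed face area / fixed face area.
#' @export
areaRatio <- function(fixed, deformed) {
  if (!identical(faces(fixed), faces(deformed)))
    stop("meshes do not share connectivity")
  af <- .faceAreasAndNormals(fixed)$areas
  ad <- .faceAreasAndNormals(deformed)$areas
  zero <- which(af <= 0)
  if (length(zero))
    stop("zero-area fixed face(s): ", paste(utils::head(zero, 5), collapse = ", "))
  ad / af
}

#' Angle-weighted outward vertex normals
#'
#' Average of incident face normals weighted by the face corner angle at
#' the vertex, normalized to unit length. Requires consistently oriented
#' (outward) faces.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return N x 3 matrix of unit normals.
#' @export
vertexNormals <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh)
  fn <- .faceAreasAndNormals(mesh)$normals
  n <- matrix(0, nrow(v), 3)
  corner <- function(i0, i1, i2) {
    e1 <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    e2 <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      pmax(sqrt(rowSums(e1^2) * rowSums(e2^2)), 1e-300)
    acos(pmin(1, pmax(-1, cosang)))
  }
  w1 <- corner(f[, 1], f[, 2], f[, 3])
  w2 <- corner(f[, 2], f[, 3], f[, 1])
  w3 <- corner(f[, 3], f[, 1], f[, 2])
  for (c in 1:3) {
    acc <- rowsum(c(fn[, c] * w1, fn[, c] * w2, fn[, c] * w3),
                  c(f[, 1], f[, 2], f[, 3]),
                  reorder = FALSE)
    n[as.integer(rownames(acc)), c] <- n[as.integer(rownames(acc)), c] + acc
  }
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(v))
    stop("isolated vertices present: ",
         paste(utils::head(setdiff(seq_len(nrow(v)), used), 5), collapse = ", "))
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Deformation in the normal direction (DiN)
#'
#' Signed projection of the per-vertex displacement onto the fixed-surface
#' outward normal; outward growth positive, in millimeters.
#'
#' @param fixed,deformed corresponding \linkS4class{SurfaceMesh}es.
#' @param normals optional precomputed fixed-surface normals.
#' @return numeric vector, one value per vertex (mm).
#' @export
deformationInNormal <- function(fixed, deformed, normals = NULL) {
  if (!identical(faces(fixed), faces(deformed)))
    stop("meshes do not share connectivity")
  if (is.null(normals)) normals <- vertexNormals(fixed)
  rowSums((vertices(deformed) - vertices(fixed)) * normals)
}

#' Interpolate per-face values onto vertices
#'
#' Area-weighted mean of the values on faces incident to each vertex
#' (weights sum to one per vertex).
#'
#' @param values numeric vector, one value per face.
#' @param mesh the \linkS4class{SurfaceMesh} the values live on.
#' @return numeric vector, one value per vertex.
#' @export
interpolateFaceToVertex <- function(values, mesh) {
  f <- faces(mesh)
  if (length(values) != nrow(f)) stop("one value per face required")
  areas <- .faceAreasAndNormals(mesh)$areas
  vidx <- c(f[, 1], f[, 2], f[, 3])
  w <- rep(areas, 3)
  num <- rowsum(w * rep(values, 3), vidx, reorder = TRUE)
  den <- rowsum(w, vidx, reorder = TRUE)
  out <- numeric(nrow(vertices(mesh)))
  out[as.integer(rownames(num))] <- num / den
  out
}

#' Compute growth metrics between two corresponding meshes
#'
#' @param fixed,deformed corresponding \linkS4class{SurfaceMesh}es.
#' @return A \linkS4class{GrowthMetrics}: per-face AR, per-vertex DiN,
#'   AR interpolated onto vertices, and per-vertex displacement magnitude.
#' @export
computeGrowthMetrics <- function(fixed, deformed) {
  ar <- areaRatio(fixed, deformed)
  din <- deformationInNormal(fixed, deformed)
  disp <- sqrt(rowSums((vertices(deformed) - vertices(fixed))^2))
  new("GrowthMetrics", ar = ar, din = din,
      arOnVertices = interpolateFaceToVertex(ar, fixed), displacement = disp)
}

setMethod("show", "GrowthMetrics", function(object) {
  cat(sprintf("GrowthMetrics: %d faces, %d vertices\n", length(object@ar),
              length(object@din)))
  cat(sprintf("  AR  median %.3f, 99th pct %.3f\n", stats::median(object@ar),
              stats::quantile(object@ar, 0.99)))
  cat(sprintf("  DiN median %.3f mm, 99th pct %.3f mm\n",
              stats::median(object@din), stats::quantile(object@din, 0.99)))
})

.summaryRow <- function(err, metric, threshold) {
  data.frame(metric = metric, n = length(err), p99 = unname(stats::quantile(err, 0.99)),
             p95 = unname(stats::quantile(err, 0.95)), median = stats::median(err),
             mean = mean(err), sd = stats::sd(err), threshold = threshold)
}

#' Absolute error between ground-truth and measured growth metrics
#'
#' Element-wise |GT - measured| restricted to the deformed region: vertices
#' whose ground-truth |DiN| exceeds \code{threshold} mm, and faces with at
#' least one incident vertex in that region. Summaries (99th/95th
#' percentile, median, mean, sd) are returned per metric.
#'
#' @param gt,measured \linkS4class{GrowthMetrics} on the same meshes.
#' @param mesh the fixed \linkS4class{SurfaceMesh} (for face incidence).
#' @param threshold deformed-region threshold on |GT DiN| (mm).
#' @return list(summary = two-row data.frame (AR, DiN), arErrors, dinErrors,
#'   vertexRegion, faceRegion).
#' @export
growthAbsoluteError <- function(gt, measured, mesh, threshold = 1e-3) {
  if (length(gt@ar) != length(measured@ar) ||
      length(gt@din) != length(measured@din))
    stop("metric lengths differ; not the same meshes")
  vreg <- abs(gt@din) > threshold
  f <- faces(mesh)
  freg <- vreg[f[, 1]] | vreg[f[, 2]] | vreg[f[, 3]]
  if (!any(vreg)) stop("empty deformed region at threshold ", threshold)
  arErr <- abs(gt@ar - measured@ar)[freg]
  dinErr <- abs(gt@din - measured@din)[vreg]
  list(summary = rbind(.summaryRow(arErr, "AR", threshold),
                       .summaryRow(dinErr, "DiN", threshold)),
       arErrors = arErr, dinErrors = dinErr,
       vertexRegion = vreg, faceRegion = freg)
}

#' Relative error of a perturbed measurement
#'
#' Convention used in the robustness experiments:
#' (err_perturbed - err_original) / GT 99th percentile, in percent, where
#' the errors are 99th-percentile absolute errors within the deformed
#' region.
#'
#' @param errPerturbed,errOriginal scalar error values (same units as the
#'   metric).
#' @param gt99 99th percentile of the ground-truth metric within the
#'   deformed region (AR as-is, dimensionless; DiN in mm).
#' @return relative error in percent.
#' @export
growthRelativeError <- function(errPerturbed, errOriginal, gt99) {
  if (gt99 == 0) stop("ground-truth 99th percentile is zero")
  100 * (errPerturbed - errOriginal) / gt99
}
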