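#' File input/output
#'
#' Volumes are stored as NIfTI-1 (via RNifti) with axis-aligned geometry;
#' displacement fields as 5D NIfTI vector images (fixed-to-moving, mm).
#' Meshes are stored as PLY (ascii or binary little-endian, with optional
#' per-vertex scalar fields) or STL; STL has no indexed vertices, so
#' correspondence is lost on re-read (duplicate vertices are welded).
#'
#' @name io
NULL

.niftiAffine <- function(spacing, origin) {
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  aff
}

#' Write an image volume to NIfTI
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param path output path (.nii or .nii.gz).
#' @param datatype "float" or "uint8" (for masks).
#' @return invisibly, the path.
#' @export
writeVolume <- function(vol, path, datatype = c("float", "uint8")) {
  datatype <- match.arg(datatype)
  img <- RNifti::asNifti(imgData(vol))
  aff <- structure(.niftiAffine(spacing(vol), origin(vol)), code = 2L)
  img <- RNifti::`qform<-`(img, value = aff)
  img <- RNifti::`sform<-`(img, value = aff)
  RNifti::pixdim(img) <- spacing(vol)
  RNifti::writeNifti(img, path,
                     datatype = if (datatype == "uint8") "uint8" else "float")
  invisible(path)
}

#' Read an image volume from NIfTI
#'
#' Requires an axis-aligned affine (no rotation/shear); flips are rejected
#' with an error rather than silently reoriented.
#'
#' @param path NIfTI file (.nii / .nii.gz).
#' @return An \linkS4class{ImageVolume}.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  offdiag <- aff[1:3, 1:3]; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-4 || any(diag(aff[1:3, 1:3]) <= 0))
    stop("only axis-aligned, positively oriented NIfTI volumes are supported; ",
         "offending affine column(s): ",
         paste(which(colSums(abs(offdiag)) > 1e-4), collapse = ", "))
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  imageVolume(arr, diag(aff[1:3, 1:3]), aff[1:3, 4])
}

#' Write/read a displacement field as a 5D NIfTI vector image
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param path .nii / .nii.gz path.
#' @return invisibly the path / the field.
#' @export
writeField <- function(field, path) {
  arr <- field@field
  dim(arr) <- c(dim(field), 1L, 3L)
  img <- RNifti::asNifti(arr)
  aff <- structure(.niftiAffine(spacing(field), origin(field)), code = 2L)
  img <- RNifti::`qform<-`(img, value = aff)
  img <- RNifti::`sform<-`(img, value = aff)
  RNifti::pixdim(img) <- c(spacing(field), 1, 1)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname writeField
#' @export
readField <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- array(as.numeric(img), dim(img))
  d <- dim(arr)
  if (length(d) == 5L) dim(arr) <- c(d[1:3], d[5])
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("not a 3-component displacement field")
  displacementField(arr, diag(aff[1:3, 1:3]), aff[1:3, 4])
}

# ---- PLY ------------------------------------------------------------------

#' Write a mesh to PLY
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output .ply path.
#' @param fields named list of per-vertex numeric vectors stored as extra
#'   vertex properties (e.g. \code{list(din = ...)}).
#' @param binary write binary little-endian (default) or ascii.
#' @return invisibly, the path.
#' @export
writeMesh <- function(mesh, path, fields = list(), binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") return(.writeSTL(mesh, path))
  v <- vertices(mesh); f <- faces(mesh)
  for (nm in names(fields))
    if (length(fields[[nm]]) != nrow(v)) stop("field '", nm, "' length mismatch")
  fmt <- if (binary) "binary_little_endian" else "ascii"
  hdr <- c("ply", paste("format", fmt, "1.0"),
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           vapply(names(fields), function(n) paste("property double", n), ""),
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  vdat <- cbind(v, do.call(cbind, c(fields, list(deparse.level = 0))))
  if (binary) {
    writeBin(as.vector(t(vdat)), con, size = 8, endian = "little")
    fdat <- t(cbind(3L, f - 1L))
    for (r in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[r, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    writeLines(apply(vdat, 1, paste, collapse = " "), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read a mesh from PLY or STL
#'
#' PLY preserves vertex order (and therefore correspondence); STL welds
#' exactly duplicated vertices, so correspondence with the written mesh is
#' not preserved.
#'
#' @param path .ply or .stl file.
#' @return A \linkS4class{SurfaceMesh}; extra PLY vertex properties are
#'   returned in \code{meshMeta(mesh)}.
#' @export
readMesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") return(.readSTL(path))
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ascii lines
  hdr <- character(0)
  repeat {
    ln <- readLines(con, 1)
    hdr <- c(hdr, ln)
    if (identical(ln, "end_header")) break
    if (length(hdr) > 200) stop("malformed PLY header")
  }
  fmt <- strsplit(grep("^format", hdr, value = TRUE), " ")[[1]][2]
  els <- grep("^element", hdr)
  parseEl <- function(i) {
    parts <- strsplit(hdr[i], " ")[[1]]
    to <- c(els[els > i], length(hdr))[1]
    props <- grep("^property", hdr[(i + 1):(to - 1)], value = TRUE)
    list(name = parts[2], n = as.integer(parts[3]), props = props)
  }
  elements <- lapply(els, parseEl)
  names(elements) <- vapply(elements, `[[`, "", "name")
  ve <- elements$vertex; fe <- elements$face
  if (is.null(ve) || is.null(fe)) stop("PLY lacks vertex/face elements")
  pnames <- vapply(strsplit(ve$props, " "), function(p) p[length(p)], "")
  ptypes <- vapply(strsplit(ve$props, " "), function(p) p[2], "")
  if (any(grepl("^property list", ve$props))) stop("list vertex properties unsupported")
  np <- length(pnames)
  if (fmt == "ascii") {
    txt <- readLines(con)
    vdat <- matrix(scan(text = txt[seq_len(ve$n)], quiet = TRUE), ve$n, np,
                   byrow = TRUE)
    flines <- strsplit(trimws(txt[ve$n + seq_len(fe$n)]), "\\s+")
    fcounts <- vapply(flines, function(x) as.integer(x[1]), 0L)
    if (any(fcounts != 3L)) stop("non-triangular faces in PLY")
    fdat <- t(vapply(flines, function(x) as.integer(x[2:4]), integer(3))) + 1L
  } else {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    sz <- sizes[ptypes]
    if (any(is.na(sz))) stop("unsupported PLY vertex property type")
    if (length(unique(sz)) != 1L) stop("mixed vertex property sizes unsupported")
    vdat <- matrix(readBin(con, "double", n = ve$n * np, size = sz[1],
                           endian = endian), ve$n, np, byrow = TRUE)
    fdat <- matrix(0L, fe$n, 3)
    for (r in seq_len(fe$n)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3L) stop("non-triangular faces in PLY")
      fdat[r, ] <- readBin(con, "integer", 3, size = 4, endian = endian) + 1L
    }
  }
  meta <- list()
  if (np > 3)
    for (i in 4:np) meta[[pnames[i]]] <- vdat[, i]
  surfaceMesh(vdat[, 1:3], fdat, meta)
}

.writeSTL <- function(mesh, path) {
  warning("STL stores unindexed triangles; vertex correspondence is lost on re-read")
  v <- vertices(mesh); f <- faces(mesh)
  fn <- .faceAreasAndNormals(mesh)$normals
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (r in seq_len(nrow(f))) {
    writeBin(as.numeric(c(fn[r, ], v[f[r, 1], ], v[f[r, 2], ], v[f[r, 3], ])),
             con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

.readSTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  tri <- matrix(0, nf * 3, 3)
  for (r in seq_len(nf)) {
    vals <- readBin(con, "double", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    tri[3 * r - 2:0, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  key <- apply(signif(tri, 10), 1, paste, collapse = "_")
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  fidx <- matrix(match(key, key[uk]), ncol = 3, byrow = TRUE)
  surfaceMesh(verts, fidx)
}

# ---- phantom spec YAML ----------------------------------------------------

#' Serialize/deserialize a phantom specification as YAML
#'
#' Only constant lumen radii round-trip (a radius function has no file
#' representation).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param path YAML file path.
#' @return the path / the \linkS4class{PhantomSpec}.
#' @export
writePhantomSpec <- function(spec, path) {
  if (is.function(spec@lumenRadius))
    stop("a functional radius profile cannot be serialized; use a constant")
  lst <- list(ascendingLength = spec@ascendingLength,
              archRadius = spec@archRadius,
              descendingLength = spec@descendingLength,
              lumenRadius = spec@lumenRadius, nCirc = spec@nCirc,
              axialStep = spec@axialStep, sampleStep = spec@sampleStep,
              deformations = spec@deformations,
              wallIrregularity = spec@wallIrregularity, seed = spec@seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(phantomSpec, lst)
}

#' Export growth metrics for rendering and analysis
#'
#' Writes per-face AR and per-vertex DiN as CSV, and a PLY of the fixed
#' mesh carrying the vertex fields (DiN and vertex-interpolated AR) for
#' heatmap rendering.
#'
#' @param metrics a \linkS4class{GrowthMetrics}.
#' @param mesh the fixed \linkS4class{SurfaceMesh}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
exportGrowthMetrics <- function(metrics, mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(face_id = seq_along(metrics@ar), ar = metrics@ar),
                   file.path(dir, "area_ratio.csv"), row.names = FALSE)
  utils::write.csv(data.frame(vertex_id = seq_along(metrics@din),
                              din_mm = metrics@din,
                              ar_vertex = metrics@arOnVertices),
                   file.path(dir, "din.csv"), row.names = FALSE)
  writeMesh(mesh, file.path(dir, "fixed_with_metrics.ply"),
            fields = list(din = metrics@din, ar = metrics@arOnVertices))
  invisible(dir)
}
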