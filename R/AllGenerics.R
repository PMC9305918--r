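#' @rdname ImageVolume-accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname ImageVolume-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname ImageVolume-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname SurfaceMesh-accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname SurfaceMesh-accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname SurfaceMesh-accessors
#' @export
setGeneric("meshMeta", function(x) standardGeneric("meshMeta"))

#' @rdname DisplacementField-accessors
#' @export
setGeneric("fieldArray", function(x) standardGeneric("fieldArray"))
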