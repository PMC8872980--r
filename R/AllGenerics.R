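#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' @rdname accessors
#' @export
setGeneric("rasterStep", function(x) standardGeneric("rasterStep"))

#' @rdname accessors
#' @export
setGeneric("sectionThickness",
           function(x) standardGeneric("sectionThickness"))

#' @rdname accessors
#' @export
setGeneric("tissueDensity", function(x) standardGeneric("tissueDensity"))

#' @rdname accessors
#' @export
setGeneric("pixelGrid", function(x) standardGeneric("pixelGrid"))

#' @rdname accessors
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))

#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("channelImage", function(x, ...) standardGeneric("channelImage"))

#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname accessors
#' @export
setGeneric("regionMask", function(x, ...) standardGeneric("regionMask"))

#' Tissue mass under one pixel
#'
#' @param grid a \linkS4class{PixelGrid} (or an object carrying one).
#' @return pixel tissue mass in grams.
#' @export
setGeneric("pixelTissueMass", function(grid) standardGeneric("pixelTissueMass"))
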