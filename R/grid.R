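#' Construct a PixelGrid
#'
#' @param nRows,nCols grid dimensions (pixels).
#' @param rasterStep lateral raster step in micrometres.
#' @param sectionThickness section thickness in micrometres; cryosections are
#'   cut at 12 um by default.
#' @param tissueDensity tissue density in g cm^-3; rat brain default 1.027.
#' @return a \linkS4class{PixelGrid}.
#' @examples
#' g <- PixelGrid(60, 80, rasterStep = 100)
#' pixelTissueMass(g)
#' @export
PixelGrid <- function(nRows, nCols, rasterStep,
                      sectionThickness = 12, tissueDensity = 1.027) {
  new("PixelGrid",
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      rasterStep = as.numeric(rasterStep),
      sectionThickness = as.numeric(sectionThickness),
      tissueDensity = as.numeric(tissueDensity))
}

#' @rdname accessors
#' @export
setMethod("nRows", "PixelGrid", function(x) x@nRows)

#' @rdname accessors
#' @export
setMethod("nCols", "PixelGrid", function(x) x@nCols)

#' @rdname accessors
#' @export
setMethod("rasterStep", "PixelGrid", function(x) x@rasterStep)

#' @rdname accessors
#' @export
setMethod("sectionThickness", "PixelGrid", function(x) x@sectionThickness)

#' @rdname accessors
#' @export
setMethod("tissueDensity", "PixelGrid", function(x) x@tissueDensity)

# um -> cm
.UM_TO_CM <- 1e-4

#' @describeIn pixelTissueMass mass of tissue under one raster pixel:
#'   rasterStep^2 x thickness x density, converted to grams. At a 100-um
#'   raster, 12-um section and 1.027 g cm^-3 this is 1.2324e-7 g.
#' @export
setMethod("pixelTissueMass", "PixelGrid", function(grid) {
  side <- grid@rasterStep * .UM_TO_CM
  side^2 * (grid@sectionThickness * .UM_TO_CM) * grid@tissueDensity
})

#' @describeIn pixelTissueMass convenience method for a section.
#' @export
setMethod("pixelTissueMass", "SectionDataset",
          function(grid) pixelTissueMass(grid@grid))

setMethod("show", "PixelGrid", function(object) {
  cat(sprintf(
    "PixelGrid: %d x %d px, raster %g um, thickness %g um, density %g g/cm3\n",
    object@nRows, object@nCols, object@rasterStep,
    object@sectionThickness, object@tissueDensity))
})
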