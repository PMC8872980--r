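#' Declared region vocabulary
#'
#' Labels of the annotated regions of a coronal rat brain section at the
#' striatal level: corpus callosum (cc), external capsule (ec), anterior
#' commissure (aca), cingulate cortex (CgCx), motor cortex (MCx),
#' somatosensory cortex (SCx), insular cortex (InCx), piriform cortex (Pir),
#' caudate putamen (CPu), nucleus accumbens (NAc) and lateral septum (LS).
#'
#' @return character vector of labels.
#' @export
regionVocabulary <- function() {
  c("cc", "ec", "aca", "CgCx", "MCx", "SCx", "InCx", "Pir", "CPu", "NAc", "LS")
}

#' Construct a RegionAtlas
#'
#' @param regions named list of logical matrices (mutually disjoint).
#' @param vocabulary admissible labels; defaults to
#'   \code{\link{regionVocabulary}}.
#' @return a \linkS4class{RegionAtlas}.
#' @export
RegionAtlas <- function(regions, vocabulary = regionVocabulary()) {
  new("RegionAtlas", regions = regions, vocabulary = vocabulary)
}

#' @rdname accessors
#' @export
setMethod("regionNames", "RegionAtlas", function(x) names(x@regions))

#' @param label region label.
#' @rdname accessors
#' @export
setMethod("regionMask", "RegionAtlas", function(x, label) {
  if (!label %in% names(x@regions))
    stop("unknown region '", label, "'", call. = FALSE)
  x@regions[[label]]
})

setMethod("show", "RegionAtlas", function(object) {
  px <- vapply(object@regions, sum, numeric(1))
  cat(sprintf("RegionAtlas: %d regions (%s px total)\n",
              length(object@regions), sum(px)))
  print(px)
})

#' Check an atlas against a section
#'
#' Verifies that every region mask matches the section grid and lies inside
#' the tissue mask (every downstream analysis mask must be a subset of the
#' tissue).
#'
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param section a \linkS4class{SectionDataset}.
#' @return invisibly TRUE; errors otherwise.
#' @export
checkAtlas <- function(atlas, section) {
  dims <- dim(section@tissueMask)
  for (lab in regionNames(atlas)) {
    m <- atlas@regions[[lab]]
    if (!identical(dim(m), dims))
      stop("region '", lab, "' shape does not match the section",
           call. = FALSE)
    if (any(m & !section@tissueMask))
      stop("region '", lab, "' extends outside the tissue mask",
           call. = FALSE)
  }
  invisible(TRUE)
}

# rectangle helper on an nr x nc grid
.rectMask <- function(nr, nc, r1, r2, c1, c2) {
  m <- matrix(FALSE, nr, nc)
  m[r1:r2, c1:c2] <- TRUE
  m
}

#' Default coronal tissue mask
#'
#' Elliptical footprint of a coronal section on the default 80 x 100 grid.
#'
#' @param grid a \linkS4class{PixelGrid}; default the package's standard
#'   80 x 100 px grid at a 100-um raster.
#' @return logical matrix.
#' @export
defaultTissueMask <- function(grid = defaultGrid()) {
  nr <- grid@nRows; nc <- grid@nCols
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  a <- 0.875 * nr / 2; b <- 0.92 * nc / 2
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((rows - rc) / a)^2 + ((cols - cc) / b)^2 <= 1
}

#' Default pixel grid
#'
#' 80 x 100 pixels at a 100-um raster step, 12-um section thickness and rat
#' brain tissue density 1.027 g cm^-3 (an 8 x 10 mm field of view).
#'
#' @return a \linkS4class{PixelGrid}.
#' @export
defaultGrid <- function() PixelGrid(80L, 100L, rasterStep = 100)

#' Default region atlas
#'
#' A stylized coronal striatal-level annotation on the default grid: thin
#' white-matter tracts (cc, ec, aca), cortical subregions (CgCx, MCx, SCx,
#' InCx, Pir) and the deep gray structures (CPu, NAc, LS). The shapes are
#' simple geometric surrogates of the manually drawn atlas regions and are
#' mutually disjoint and fully within the default tissue mask.
#'
#' @param grid a \linkS4class{PixelGrid}; the default 80 x 100 grid.
#' @return a \linkS4class{RegionAtlas}.
#' @export
defaultAtlas <- function(grid = defaultGrid()) {
  nr <- grid@nRows; nc <- grid@nCols
  R <- function(...) .rectMask(nr, nc, ...)
  regions <- list(
    CgCx = R(14, 19, 44, 56),
    MCx  = R(16, 22, 28, 40),
    SCx  = R(16, 22, 60, 72),
    cc   = R(26, 27, 22, 78),
    ec   = R(29, 44, 14, 16) | R(29, 44, 84, 86),
    InCx = R(38, 46, 9, 13) | R(38, 46, 87, 91),
    CPu  = R(32, 48, 24, 37) | R(32, 48, 63, 76),
    LS   = R(32, 43, 47, 54),
    aca  = R(48, 51, 38, 41) | R(48, 51, 59, 62),
    NAc  = R(50, 55, 42, 46) | R(50, 55, 54, 58),
    Pir  = R(50, 55, 17, 21) | R(50, 55, 79, 83)
  )
  RegionAtlas(regions[regionVocabulary()])
}

#' Region area weights over the tissue
#'
#' Pixel-count weights of each atlas region plus the unannotated remainder
#' ("background") of the tissue, as fractions of the tissue area.
#'
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param tissue logical tissue mask.
#' @return named numeric vector summing to one, with a "background" entry.
#' @export
regionAreaWeights <- function(atlas, tissue = defaultTissueMask()) {
  px <- vapply(atlas@regions, function(m) sum(m & tissue), numeric(1))
  bg <- sum(tissue) - sum(px)
  w <- c(px, background = bg) / sum(tissue)
  w
}
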