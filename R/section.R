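#' Construct a ChannelImage
#'
#' @param analyteId identifier of the measured species.
#' @param intensities non-negative numeric matrix.
#' @param group drug group (defaults to analyteId).
#' @param role "analyte", "internal_standard" or "metabolite".
#' @return a \linkS4class{ChannelImage}.
#' @export
ChannelImage <- function(analyteId, intensities, group = analyteId,
                         role = c("analyte", "internal_standard",
                                  "metabolite")) {
  role <- match.arg(role)
  storage.mode(intensities) <- "double"
  new("ChannelImage", analyteId = analyteId, group = group, role = role,
      intensities = intensities)
}

#' Construct a SectionDataset
#'
#' @param grid a \linkS4class{PixelGrid}.
#' @param channels list of \linkS4class{ChannelImage} objects.
#' @param tissueMask logical matrix; if NULL, derived by thresholding total
#'   ion intensity (see \code{\link{deriveTissueMask}}).
#' @param condition "in_vivo", "brain_slice" or "control".
#' @param subjectId,replicateId identifiers.
#' @return a \linkS4class{SectionDataset}.
#' @export
SectionDataset <- function(grid, channels, tissueMask = NULL,
                           condition = c("in_vivo", "brain_slice", "control"),
                           subjectId = "s1", replicateId = "r1") {
  condition <- match.arg(condition)
  names(channels) <- vapply(channels, function(ch) ch@analyteId, character(1))
  if (is.null(tissueMask))
    tissueMask <- deriveTissueMask(channels, grid)
  new("SectionDataset", grid = grid, channels = channels,
      tissueMask = tissueMask, condition = condition,
      subjectId = subjectId, replicateId = replicateId)
}

#' Derive a tissue mask by total-ion thresholding
#'
#' Marks as tissue the pixels whose summed channel intensity exceeds the given
#' quantile of the positive total-ion distribution. Used when no explicit mask
#' accompanies the data.
#'
#' @param channels list of \linkS4class{ChannelImage} objects (or a
#'   \linkS4class{SectionDataset}).
#' @param grid the \linkS4class{PixelGrid}.
#' @param quantile threshold quantile, default 0.1.
#' @return logical matrix.
#' @export
deriveTissueMask <- function(channels, grid, quantile = 0.1) {
  if (is(channels, "SectionDataset")) {
    grid <- channels@grid
    channels <- channels@channels
  }
  tic <- Reduce(`+`, lapply(channels, function(ch) ch@intensities))
  thr <- stats::quantile(tic[tic > 0], probs = quantile, names = FALSE)
  tic > thr
}

#' @rdname accessors
#' @export
setMethod("pixelGrid", "SectionDataset", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("tissueMask", "SectionDataset", function(x) x@tissueMask)

#' @rdname accessors
#' @export
setMethod("condition", "SectionDataset", function(x) x@condition)

#' @rdname accessors
#' @export
setMethod("channelNames", "SectionDataset", function(x) names(x@channels))

#' @param analyteId which channel to return.
#' @rdname accessors
#' @export
setMethod("channelImage", "SectionDataset", function(x, analyteId) {
  if (!analyteId %in% names(x@channels))
    stop("no channel '", analyteId, "' in section", call. = FALSE)
  x@channels[[analyteId]]
})

# find the channel of a role within an analyte group
.findChannel <- function(section, group, role) {
  for (ch in section@channels)
    if (ch@group == group && ch@role == role) return(ch)
  NULL
}

setMethod("show", "SectionDataset", function(object) {
  cat(sprintf("SectionDataset (%s) subject=%s replicate=%s\n",
              object@condition, object@subjectId, object@replicateId))
  show(object@grid)
  cat(sprintf("  %d channels: %s\n", length(object@channels),
              paste(names(object@channels), collapse = ", ")))
  cat(sprintf("  tissue pixels: %d\n", sum(object@tissueMask)))
})

#' Whole-section analysis mask
#'
#' The "entire coronal section" region used for whole-section statistics: the
#' tissue mask minus (dilated) calibration-spot footprints, so spotted
#' standards never contaminate section-level means.
#'
#' @param section a \linkS4class{SectionDataset}.
#' @param layout optional \linkS4class{CalibrationLayout} whose spots are
#'   excluded.
#' @param dilatePx extra exclusion margin around each spot, in pixels.
#' @return logical matrix.
#' @export
analysisMask <- function(section, layout = NULL, dilatePx = 1) {
  mask <- section@tissueMask
  if (!is.null(layout) && nrow(layout@spots) > 0) {
    for (i in seq_len(nrow(layout@spots))) {
      sp <- layout@spots[i, ]
      rad <- spotRadiusPx(sp$areaMm2, section@grid) + dilatePx
      mask <- mask & !.discMask(section@grid, sp$row, sp$col, rad)
    }
  }
  if (!any(mask))
    stop("degenerate input: analysis mask is empty", call. = FALSE)
  mask
}

# disc of given pixel radius centred at (r0, c0)
.discMask <- function(grid, r0, c0, radiusPx) {
  rows <- matrix(seq_len(grid@nRows), grid@nRows, grid@nCols)
  cols <- matrix(seq_len(grid@nCols), grid@nRows, grid@nCols, byrow = TRUE)
  (rows - r0)^2 + (cols - c0)^2 <= radiusPx^2
}

#' Spot radius in pixels
#'
#' Radius of a circular calibration spot of the recorded area, expressed in
#' raster pixels.
#'
#' @param areaMm2 spot area in mm^2.
#' @param grid a \linkS4class{PixelGrid}.
#' @return radius in pixels.
#' @export
spotRadiusPx <- function(areaMm2, grid) {
  radiusUm <- sqrt(areaMm2 / pi) * 1000
  radiusUm / grid@rasterStep
}

#' Pixel mask of one calibration spot
#'
#' @param layout a \linkS4class{CalibrationLayout}.
#' @param i spot index.
#' @param grid a \linkS4class{PixelGrid}.
#' @return logical matrix.
#' @export
spotMask <- function(layout, i, grid) {
  sp <- layout@spots[i, ]
  .discMask(grid, sp$row, sp$col, spotRadiusPx(sp$areaMm2, grid))
}
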