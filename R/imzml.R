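# Minimal imzML ingestion: continuous- and processed-mode files with
# externally stored binary arrays (the ibd companion file). Only what is
# needed to turn per-pixel spectra into per-channel extracted-ion images:
# pixel positions, array offsets/lengths, 32/64-bit float encodings.

.IMZML_ACC <- list(
  positionX = "IMS:1000050", positionY = "IMS:1000051",
  extOffset = "IMS:1000102", extLength = "IMS:1000103",
  continuous = "IMS:1000030", processed = "IMS:1000031",
  float32 = "MS:1000521", float64 = "MS:1000523",
  mzArray = "MS:1000514", intensityArray = "MS:1000515")

.cvValue <- function(node, accession) {
  cv <- xml2::xml_find_first(
    node, sprintf(".//*[local-name()='cvParam'][@accession='%s']",
                  accession))
  if (inherits(cv, "xml_missing")) return(NULL)
  xml2::xml_attr(cv, "value")
}

.hasCv <- function(node, accession) {
  !inherits(xml2::xml_find_first(
    node, sprintf(".//*[local-name()='cvParam'][@accession='%s']",
                  accession)), "xml_missing")
}

# data type of a referenceable param group or binaryDataArray node
.binSize <- function(node) {
  if (.hasCv(node, .IMZML_ACC$float64)) 8
  else if (.hasCv(node, .IMZML_ACC$float32)) 4
  else stop("unsupported binary encoding in imzML", call. = FALSE)
}

.readIbd <- function(con, offset, n, size) {
  seek(con, where = offset, origin = "start")
  readBin(con, "double", n = n, size = size, endian = "little")
}

#' Read an imzML file into a SectionDataset
#'
#' Ingests a continuous- or processed-mode imzML/ibd pair and extracts one
#' image per requested channel by summing, in each pixel's spectrum, the
#' intensities whose m/z falls inside the channel's extraction window.
#' Default window widths follow common practice for high-resolution drug
#' imaging: 1 mDa for analyte and metabolite channels and 1.5 mDa for the
#' deuterated internal standard.
#'
#' @param path path to the .imzML file; the .ibd companion is expected next
#'   to it.
#' @param channels data.frame with columns analyteId, group, role, mz and
#'   optionally window (full window width in Da).
#' @param rasterStep raster step in micrometres (imzML metadata is not
#'   relied upon; default 100).
#' @param sectionThickness,tissueDensity forwarded to the
#'   \linkS4class{PixelGrid}.
#' @param condition,subjectId,replicateId section metadata.
#' @param tissueMask optional explicit mask; derived from total ion
#'   intensity otherwise.
#' @return a \linkS4class{SectionDataset}.
#' @export
readImzML <- function(path, channels, rasterStep = 100,
                      sectionThickness = 12, tissueDensity = 1.027,
                      condition = "control", subjectId = "s1",
                      replicateId = "r1", tissueMask = NULL) {
  if (!"window" %in% names(channels))
    channels$window <- ifelse(channels$role == "internal_standard",
                              0.0015, 0.001)
  doc <- xml2::read_xml(path)
  ibdPath <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibdPath))
    stop("structural error: missing ibd companion '", ibdPath, "'",
         call. = FALSE)
  continuous <- .hasCv(doc, .IMZML_ACC$continuous)

  # encoding per referenceable param group (mzArray / intensityArray)
  groups <- xml2::xml_find_all(
    doc, "//*[local-name()='referenceableParamGroup']")
  sizes <- list()
  for (g in groups)
    sizes[[xml2::xml_attr(g, "id")]] <- .binSize(g)

  spectra <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  if (length(spectra) == 0)
    stop("structural error: imzML holds no spectra", call. = FALSE)

  info <- lapply(spectra, function(sp) {
    x <- as.integer(.cvValue(sp, .IMZML_ACC$positionX))
    y <- as.integer(.cvValue(sp, .IMZML_ACC$positionY))
    arrs <- xml2::xml_find_all(sp, ".//*[local-name()='binaryDataArray']")
    ref <- vapply(arrs, function(a) {
      r <- xml2::xml_find_first(
        a, ".//*[local-name()='referenceableParamGroupRef']")
      if (!inherits(r, "xml_missing")) xml2::xml_attr(r, "ref")
      else if (.hasCv(a, .IMZML_ACC$mzArray)) "mzArray"
      else "intensityArray"
    }, character(1))
    get <- function(which) {
      a <- arrs[[match(which, ref)]]
      list(offset = as.numeric(.cvValue(a, .IMZML_ACC$extOffset)),
           n = as.numeric(.cvValue(a, .IMZML_ACC$extLength)),
           size = if (!is.null(sizes[[which]])) sizes[[which]]
                  else .binSize(a))
    }
    list(x = x, y = y, mz = get("mzArray"), int = get("intensityArray"))
  })

  nCols <- max(vapply(info, `[[`, integer(1), "x"))
  nRows <- max(vapply(info, `[[`, integer(1), "y"))
  grid <- PixelGrid(nRows, nCols, rasterStep, sectionThickness,
                    tissueDensity)
  images <- lapply(seq_len(nrow(channels)),
                   function(i) matrix(0, nRows, nCols))

  con <- file(ibdPath, "rb")
  on.exit(close(con))
  mzShared <- NULL
  for (sp in info) {
    if (continuous) {
      if (is.null(mzShared))
        mzShared <- .readIbd(con, sp$mz$offset, sp$mz$n, sp$mz$size)
      mz <- mzShared
    } else {
      mz <- .readIbd(con, sp$mz$offset, sp$mz$n, sp$mz$size)
    }
    intens <- .readIbd(con, sp$int$offset, sp$int$n, sp$int$size)
    if (length(mz) != length(intens))
      stop("structural error: m/z and intensity lengths differ",
           call. = FALSE)
    for (i in seq_len(nrow(channels))) {
      half <- channels$window[i] / 2
      sel <- abs(mz - channels$mz[i]) <= half
      if (any(sel))
        images[[i]][sp$y, sp$x] <- sum(intens[sel])
    }
  }

  chans <- lapply(seq_len(nrow(channels)), function(i)
    ChannelImage(channels$analyteId[i], images[[i]],
                 group = channels$group[i], role = channels$role[i]))
  SectionDataset(grid, chans, tissueMask = tissueMask,
                 condition = condition, subjectId = subjectId,
                 replicateId = replicateId)
}
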