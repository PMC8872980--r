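#' @import methods
NULL

#' PixelGrid: geometry of an MSI raster
#'
#' Describes the pixel raster of one imaged section: grid dimensions, raster
#' step (lateral resolution), section thickness, and tissue density. The
#' thickness and density convert a pixel footprint into a tissue mass, which is
#' what links ion intensities to concentrations per gram tissue.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot rasterStep lateral raster step in micrometres.
#' @slot sectionThickness section thickness in micrometres (cryosection
#'   default 12).
#' @slot tissueDensity tissue density in g cm^-3 (rat brain default 1.027).
#' @export
setClass("PixelGrid",
  representation(
    nRows = "integer",
    nCols = "integer",
    rasterStep = "numeric",
    sectionThickness = "numeric",
    tissueDensity = "numeric"
  )
)

setValidity("PixelGrid", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || object@nRows <= 0L)
    msg <- c(msg, "nRows must be a single positive integer")
  if (length(object@nCols) != 1L || object@nCols <= 0L)
    msg <- c(msg, "nCols must be a single positive integer")
  for (s in c("rasterStep", "sectionThickness", "tissueDensity")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (length(msg)) msg else TRUE
})

#' ChannelImage: one ion image
#'
#' A single extracted ion image on a pixel grid. Channels are grouped by drug:
#' each analyte group holds at most one internal-standard (deuterated analog)
#' channel used for pixelwise normalization.
#'
#' @slot analyteId identifier of the measured species (e.g. "risperidone-d4").
#' @slot group drug group the channel belongs to (e.g. "risperidone").
#' @slot role one of "analyte", "internal_standard", "metabolite".
#' @slot intensities non-negative numeric matrix (nRows x nCols).
#' @export
setClass("ChannelImage",
  representation(
    analyteId = "character",
    group = "character",
    role = "character",
    intensities = "matrix"
  )
)

setValidity("ChannelImage", function(object) {
  msg <- character()
  if (!object@role %in% c("analyte", "internal_standard", "metabolite"))
    msg <- c(msg, "role must be analyte, internal_standard or metabolite")
  if (!is.numeric(object@intensities))
    msg <- c(msg, "intensities must be numeric")
  else if (any(!is.finite(object@intensities)) ||
           any(object@intensities < 0))
    msg <- c(msg, "intensities must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' SectionDataset: one imaged tissue section
#'
#' Pixel grid, the per-channel ion images, the tissue mask, and the
#' experimental condition the section came from: an in vivo steady-state
#' infusion brain, an in vitro incubated brain slice, or a drug-naive control.
#'
#' @slot grid a \linkS4class{PixelGrid}.
#' @slot channels named list of \linkS4class{ChannelImage} objects.
#' @slot tissueMask logical matrix marking on-tissue pixels.
#' @slot condition one of "in_vivo", "brain_slice", "control".
#' @slot subjectId,replicateId character identifiers.
#' @export
setClass("SectionDataset",
  representation(
    grid = "PixelGrid",
    channels = "list",
    tissueMask = "matrix",
    condition = "character",
    subjectId = "character",
    replicateId = "character"
  )
)

setValidity("SectionDataset", function(object) {
  msg <- character()
  dims <- c(object@grid@nRows, object@grid@nCols)
  if (!is.logical(object@tissueMask) ||
      !identical(dim(object@tissueMask), as.integer(dims)))
    msg <- c(msg, "tissueMask must be a logical matrix matching the grid")
  if (!object@condition %in% c("in_vivo", "brain_slice", "control"))
    msg <- c(msg, "condition must be in_vivo, brain_slice or control")
  roles <- character(); groups <- character()
  for (ch in object@channels) {
    if (!is(ch, "ChannelImage")) {
      msg <- c(msg, "channels must be ChannelImage objects"); break
    }
    if (!identical(dim(ch@intensities), as.integer(dims)))
      msg <- c(msg, sprintf("channel '%s' shape does not match the grid",
                            ch@analyteId))
    roles <- c(roles, ch@role); groups <- c(groups, ch@group)
  }
  isg <- groups[roles == "internal_standard"]
  if (anyDuplicated(isg))
    msg <- c(msg, "at most one internal_standard channel per analyte group")
  if (length(msg)) msg else TRUE
})

#' RegionAtlas: named region masks
#'
#' Mutually disjoint boolean masks for annotated brain regions, labelled from a
#' declared vocabulary (default: the coronal striatal-level regions cc, ec,
#' aca, CgCx, MCx, SCx, InCx, Pir, CPu, NAc, LS).
#'
#' @slot regions named list of logical matrices, all the same shape.
#' @slot vocabulary admissible region labels.
#' @export
setClass("RegionAtlas",
  representation(regions = "list", vocabulary = "character")
)

setValidity("RegionAtlas", function(object) {
  msg <- character()
  if (is.null(names(object@regions)) || any(names(object@regions) == ""))
    msg <- c(msg, "regions must be a named list")
  if (!all(names(object@regions) %in% object@vocabulary))
    msg <- c(msg, "region labels must come from the declared vocabulary")
  d <- NULL
  for (m in object@regions) {
    if (!is.logical(m) || !is.matrix(m)) {
      msg <- c(msg, "region masks must be logical matrices"); break
    }
    if (is.null(d)) d <- dim(m)
    else if (!identical(dim(m), d)) {
      msg <- c(msg, "all region masks must share one shape"); break
    }
  }
  if (length(object@regions) > 1L && !length(msg)) {
    tot <- Reduce(`+`, object@regions)
    if (max(tot) > 1L) msg <- c(msg, "region masks must be mutually disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' CalibrationLayout: on-tissue standard spots
#'
#' Positions and composition of calibration-standard spots deposited on
#' control tissue: spot centre (pixel coordinates), spot area, standard
#' concentration and spotted volume.
#'
#' @slot spots data.frame with columns spotId, row, col, areaMm2,
#'   concentration (ng mL^-1), volumeNl, group.
#' @export
setClass("CalibrationLayout", representation(spots = "data.frame"))

setValidity("CalibrationLayout", function(object) {
  sp <- object@spots
  need <- c("spotId", "row", "col", "areaMm2", "concentration",
            "volumeNl", "group")
  if (!all(need %in% names(sp)))
    return(paste("spots must have columns:", paste(need, collapse = ", ")))
  num <- c("row", "col", "areaMm2", "concentration", "volumeNl")
  for (cn in num)
    if (any(!is.finite(sp[[cn]]) | sp[[cn]] < 0))
      return(sprintf("column '%s' must be non-negative and finite", cn))
  if (any(sp$areaMm2 <= 0) || any(sp$volumeNl <= 0))
    return("spot area and volume must be positive")
  TRUE
})

#' CalibrationCurve: fitted on-tissue calibration
#'
#' Linear calibration of IS-normalized intensity against tissue-equivalent
#' concentration, with the figures of merit used for method acceptance:
#' coefficient of determination, regression F-test p-value, limit of detection
#' (3.3 sigma / S, sigma the standard error of the intercept) and the lower
#' limit of quantification (lowest nonzero standard, in tissue units).
#'
#' @slot analyte analyte group the curve belongs to.
#' @slot slope,intercept fitted coefficients (intensity per ng g^-1;
#'   intensity).
#' @slot sigmaIntercept standard error of the intercept.
#' @slot rSquared,fTestP fit diagnostics.
#' @slot lod,lloq detection and quantification limits in ng g^-1.
#' @slot weighting "none" or "inverse_x2".
#' @slot accepted logical acceptance flag.
#' @slot points the fitted (concentration, intensity) table.
#' @export
setClass("CalibrationCurve",
  representation(
    analyte = "character",
    slope = "numeric",
    intercept = "numeric",
    sigmaIntercept = "numeric",
    rSquared = "numeric",
    fTestP = "numeric",
    lod = "numeric",
    lloq = "numeric",
    weighting = "character",
    accepted = "logical",
    points = "data.frame"
  )
)

#' DrugProfile: ground-truth generator parameters for one drug
#'
#' Steady-state unbound plasma and buffer concentrations, unbound plasma
#' fraction, per-region true Kp,uu,ROI and Vu,ROI, the background (unannotated
#' tissue) truths, and the detection response factors of the analyte and its
#' deuterated internal standard.
#'
#' @slot name drug name.
#' @slot cuPlasmaSs,cuBufferSs unbound steady-state concentrations (ng mL^-1).
#' @slot fuPlasma unbound fraction in plasma, in (0, 1].
#' @slot regionTruth data.frame(region, kpuu, vu) of per-region ground truth
#'   (vu in mL g^-1).
#' @slot kpuuBrain whole-brain Kp,uu ground truth.
#' @slot kpuuBackground,vuBackground truths for unannotated tissue.
#' @slot responseFactor,isResponseFactor detector response (intensity per gram
#'   analyte).
#' @slot isAmountPerPixel sprayed internal-standard amount per pixel (grams).
#' @export
setClass("DrugProfile",
  representation(
    name = "character",
    cuPlasmaSs = "numeric",
    cuBufferSs = "numeric",
    fuPlasma = "numeric",
    regionTruth = "data.frame",
    kpuuBrain = "numeric",
    kpuuBackground = "numeric",
    vuBackground = "numeric",
    responseFactor = "numeric",
    isResponseFactor = "numeric",
    isAmountPerPixel = "numeric"
  )
)

setValidity("DrugProfile", function(object) {
  msg <- character()
  pos <- c("cuPlasmaSs", "cuBufferSs", "kpuuBrain", "kpuuBackground",
           "vuBackground", "responseFactor", "isResponseFactor",
           "isAmountPerPixel")
  for (s in pos) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (object@fuPlasma <= 0 || object@fuPlasma > 1)
    msg <- c(msg, "fuPlasma must lie in (0, 1]")
  rt <- object@regionTruth
  if (!all(c("region", "kpuu", "vu") %in% names(rt)))
    msg <- c(msg, "regionTruth needs columns region, kpuu, vu")
  else if (any(rt$kpuu <= 0) || any(rt$vu <= 0) || any(!is.finite(rt$vu)))
    msg <- c(msg, "regionTruth kpuu and vu must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' NoiseModel: measurement-noise parameters for the generator
#'
#' Emulates the main nuisance processes of MALDI-MSI acquisition that the
#' internal-standard normalization is designed to cancel: pixelwise
#' multiplicative detection noise, a smooth multiplicative gain field shared
#' between channels of a section (matrix/spray inhomogeneity), extra
#' heterogeneity of the sprayed internal-standard layer, and an additive
#' chemical background.
#'
#' @slot pixelCv lognormal coefficient of variation of per-pixel detection
#'   noise.
#' @slot gainAmplitude amplitude of the smooth spatial gain field (must be
#'   < 1; gain lies in [1 - a, 1 + a]).
#' @slot isSprayCv extra lognormal CV applied to the IS channel only.
#' @slot background mean of the additive background intensity.
#' @export
setClass("NoiseModel",
  representation(
    pixelCv = "numeric",
    gainAmplitude = "numeric",
    isSprayCv = "numeric",
    background = "numeric"
  )
)

setValidity("NoiseModel", function(object) {
  for (s in c("pixelCv", "gainAmplitude", "isSprayCv", "background")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      return(sprintf("%s must be a single non-negative number", s))
  }
  if (object@gainAmplitude >= 1) return("gainAmplitude must be < 1")
  TRUE
})
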