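#' Construct a NoiseModel
#'
#' @param pixelCv per-pixel lognormal detection-noise CV (default 0.15).
#' @param gainAmplitude amplitude of the smooth multiplicative gain field
#'   shared by all channels of a section (default 0.2).
#' @param isSprayCv extra heterogeneity of the sprayed internal-standard
#'   layer (default 0.05; IS response RSDs below 6 percent are typical of an
#'   accepted run).
#' @param background mean additive background intensity (default 0.5).
#' @return a \linkS4class{NoiseModel}.
#' @export
NoiseModel <- function(pixelCv = 0.15, gainAmplitude = 0.2,
                       isSprayCv = 0.05, background = 0.5) {
  new("NoiseModel", pixelCv = pixelCv, gainAmplitude = gainAmplitude,
      isSprayCv = isSprayCv, background = background)
}

#' A noise-free NoiseModel
#'
#' All noise components zero; the generator then realizes the forward model
#' exactly, so the quantitation chain must invert it exactly.
#'
#' @return a \linkS4class{NoiseModel}.
#' @export
noiseFree <- function() NoiseModel(0, 0, 0, 0)

#' Construct a DrugProfile
#'
#' Regional ground truths are given for the atlas vocabulary; the truths for
#' unannotated tissue ("background") complete the section. See
#' \code{\link{defaultProfiles}} for the packaged drugs.
#'
#' @param name drug name.
#' @param cuPlasmaSs,cuBufferSs unbound steady-state plasma and buffer
#'   concentrations (ng mL^-1).
#' @param fuPlasma unbound fraction in plasma.
#' @param regionTruth data.frame(region, kpuu, vu).
#' @param kpuuBrain whole-brain Kp,uu ground truth.
#' @param kpuuBackground,vuBackground truths for unannotated tissue.
#' @param responseFactor,isResponseFactor detector response factors
#'   (intensity per gram analyte).
#' @param isAmountPerPixel internal-standard amount deposited per pixel (g).
#' @return a \linkS4class{DrugProfile}.
#' @export
DrugProfile <- function(name, cuPlasmaSs, cuBufferSs, fuPlasma,
                        regionTruth, kpuuBrain,
                        kpuuBackground = kpuuBrain,
                        vuBackground,
                        responseFactor = 1e15,
                        isResponseFactor = 1e15,
                        isAmountPerPixel = 1e-13) {
  new("DrugProfile", name = name, cuPlasmaSs = cuPlasmaSs,
      cuBufferSs = cuBufferSs, fuPlasma = fuPlasma,
      regionTruth = regionTruth, kpuuBrain = kpuuBrain,
      kpuuBackground = kpuuBackground, vuBackground = vuBackground,
      responseFactor = responseFactor, isResponseFactor = isResponseFactor,
      isAmountPerPixel = isAmountPerPixel)
}

setMethod("show", "DrugProfile", function(object) {
  cat(sprintf(
    "DrugProfile '%s': Kp,uu,brain = %.3g, Cu,plasma = %g, Cu,buffer = %g, fu = %g\n",
    object@name, object@kpuuBrain, object@cuPlasmaSs, object@cuBufferSs,
    object@fuPlasma))
  print(object@regionTruth, row.names = FALSE)
})

# region-level relative Kp,uu patterns; white-matter tracts carry half the
# gray-matter binding (vu multiplier 0.5) so their total concentrations are
# lower in both conditions
.profileSpecs <- function() {
  list(
    risperidone = list(
      kpuuBrain = 0.10, vuGray = 8, cuBuffer = 200, fu = 0.10,
      insularFold = 1.3,
      kpuu = c(cc = 0.07, ec = 0.09, aca = 0.115, CgCx = 0.10, MCx = 0.08,
               SCx = 0.09, InCx = 0.10, Pir = 0.12, CPu = 0.10, NAc = 0.10,
               LS = 0.095)),
    clozapine = list(
      kpuuBrain = 0.31, vuGray = 20, cuBuffer = 65, fu = 0.13,
      insularFold = 1.2,
      kpuu = c(cc = 0.30, ec = 0.31, aca = 0.36, CgCx = 0.31, MCx = 0.30,
               SCx = 0.32, InCx = 0.31, Pir = 0.24, CPu = 0.30, NAc = 0.31,
               LS = 0.29)),
    olanzapine = list(
      kpuuBrain = 0.82, vuGray = 15, cuBuffer = 62, fu = 0.23,
      insularFold = 1.5,
      kpuu = c(cc = 0.60, ec = 0.75, aca = 1.15, CgCx = 0.85, MCx = 0.80,
               SCx = 1.05, InCx = 0.82, Pir = 0.90, CPu = 0.85, NAc = 0.80,
               LS = 0.45))
  )
}

#' Packaged drug profiles
#'
#' Ground-truth profiles for risperidone, clozapine and olanzapine. The
#' whole-brain Kp,uu values are 0.10, 0.31 and 0.82; risperidone's motor and
#' piriform cortex truths are 0.08 and 0.12; and the insular-cortex total
#' concentration sits 1.3-, 1.2- and 1.5-fold above the whole-section mean
#' for the three drugs. Two quantities are solved at construction so these
#' constraints hold exactly under the default atlas geometry: the
#' unannotated-tissue Kp,uu (area-weighted mean over the tissue equals the
#' whole-brain value) and the insular-cortex Vu (the stated concentration
#' fold). White-matter regions carry lower Vu, giving them lower total
#' concentrations in both the in vivo and the brain-slice condition.
#'
#' @param atlas atlas defining region areas (default \code{defaultAtlas()}).
#' @param tissue tissue mask (default \code{defaultTissueMask()}).
#' @return named list of \linkS4class{DrugProfile} objects.
#' @export
defaultProfiles <- function(atlas = defaultAtlas(),
                            tissue = defaultTissueMask()) {
  w <- regionAreaWeights(atlas, tissue)
  specs <- .profileSpecs()
  out <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    kpuu <- sp$kpuu
    labs <- names(kpuu)
    wReg <- w[labs]
    wBg <- w[["background"]]
    # background Kp,uu: area-weighted tissue mean equals the whole-brain value
    kpuuBg <- (sp$kpuuBrain - sum(wReg * kpuu)) / wBg
    stopifnot(kpuuBg > 0)
    vu <- rep(sp$vuGray, length(labs))
    names(vu) <- labs
    vu[c("cc", "ec", "aca")] <- 0.5 * sp$vuGray
    # insular-cortex Vu: in vivo concentration fold over the whole-section
    # mean equals the stated excess
    f <- sp$insularFold
    wI <- wReg[["InCx"]]
    contrib <- wReg * kpuu * vu
    Tother <- sum(contrib[labs != "InCx"]) + wBg * kpuuBg * sp$vuGray
    vu[["InCx"]] <- f * Tother / (kpuu[["InCx"]] * (1 - f * wI))
    out[[nm]] <- DrugProfile(
      name = nm,
      cuPlasmaSs = sp$cuBuffer,  # dosing matched so CF = 1 by default
      cuBufferSs = sp$cuBuffer,
      fuPlasma = sp$fu,
      regionTruth = data.frame(region = labs, kpuu = unname(kpuu),
                               vu = unname(vu)),
      kpuuBrain = sp$kpuuBrain,
      kpuuBackground = kpuuBg,
      vuBackground = sp$vuGray)
  }
  out
}

#' True regional concentrations implied by a profile
#'
#' The generator's forward model at the region level: in vivo
#' C = Kp,uu x Vu x Cu,plasma; brain slice C = Vu x Cu,buffer; control 0.
#'
#' @param profile a \linkS4class{DrugProfile}.
#' @param condition "in_vivo", "brain_slice" or "control".
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param tissue tissue mask used for area weights.
#' @return data.frame(region, concentration) including "background" and the
#'   area-weighted "whole_section" value, in ng g^-1.
#' @export
regionTruthTable <- function(profile, condition, atlas = defaultAtlas(),
                             tissue = defaultTissueMask()) {
  condition <- match.arg(condition, c("in_vivo", "brain_slice", "control"))
  rt <- profile@regionTruth
  labs <- c(rt$region, "background")
  kpuu <- c(rt$kpuu, profile@kpuuBackground)
  vu <- c(rt$vu, profile@vuBackground)
  conc <- switch(condition,
    in_vivo = kpuu * vu * profile@cuPlasmaSs,
    brain_slice = vu * profile@cuBufferSs,
    control = rep(0, length(labs)))
  w <- regionAreaWeights(atlas, tissue)[labs]
  whole <- sum(w * conc) / sum(w)
  data.frame(region = c(labs, "whole_section"),
             concentration = c(conc, whole))
}

#' Whole-section Kp,uu implied by a profile
#'
#' The estimand the in vivo / brain-slice concentration ratio targets at the
#' whole-section level: a binding-weighted (area x Vu) mean of the regional
#' Kp,uu,ROI values. Under the packaged defaults it lies within about two
#' percent of the profile's nominal whole-brain value.
#'
#' @inheritParams regionTruthTable
#' @return a single number.
#' @export
impliedWholeSectionKpuu <- function(profile, atlas = defaultAtlas(),
                                    tissue = defaultTissueMask()) {
  iv <- regionTruthTable(profile, "in_vivo", atlas, tissue)
  sl <- regionTruthTable(profile, "brain_slice", atlas, tissue)
  cf <- profile@cuBufferSs / profile@cuPlasmaSs
  cf * iv$concentration[iv$region == "whole_section"] /
    sl$concentration[sl$region == "whole_section"]
}
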