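#' Internal-standard normalization
#'
#' Pixelwise ratio of the analyte channel to the deuterated internal-standard
#' channel of the same group. Because matrix/spray gain multiplies both
#' channels identically, the ratio image is free of the spatial gain field.
#' Pixels whose IS intensity falls below a floor (a fraction of the median IS
#' intensity over tissue) are flagged invalid and excluded from region means.
#'
#' @param section a \linkS4class{SectionDataset}.
#' @param analyteId analyte group to normalize.
#' @param isFloorFrac IS validity floor as a fraction of the median on-tissue
#'   IS intensity (default 0.01).
#' @return list(ratio = numeric matrix, valid = logical matrix).
#' @export
normalizeToIS <- function(section, analyteId, isFloorFrac = 0.01) {
  an <- .findChannel(section, analyteId, "analyte")
  is <- .findChannel(section, analyteId, "internal_standard")
  if (is.null(an))
    stop("configuration error: no analyte channel for group '", analyteId,
         "'", call. = FALSE)
  if (is.null(is))
    stop("configuration error: no internal-standard channel for group '",
         analyteId, "'", call. = FALSE)
  floorI <- isFloorFrac * stats::median(is@intensities[section@tissueMask])
  valid <- is@intensities > floorI
  ratio <- matrix(NA_real_, nrow(valid), ncol(valid))
  ratio[valid] <- an@intensities[valid] / is@intensities[valid]
  list(ratio = ratio, valid = valid)
}

#' Tissue-equivalent concentration of a calibration spot
#'
#' Converts a spotted standard (solution concentration x spotted volume over
#' the spot's tissue footprint) into the concentration per gram of tissue
#' that the spot mimics: (conc x volume) / (area x thickness x density).
#' For the 25 ng mL^-1 / 40 nL standard on a 1.0-mm spot on a 12-um section
#' this is about 103 ng g^-1.
#'
#' @param concStd standard concentration in ng mL^-1.
#' @param volumeNl spotted volume in nL.
#' @param areaMm2 spot area in mm^2.
#' @param grid a \linkS4class{PixelGrid} supplying thickness and density.
#' @return tissue-equivalent concentration in ng g^-1.
#' @export
spotTissueEquivalent <- function(concStd, volumeNl, areaMm2, grid) {
  if (any(concStd <= 0) || any(volumeNl <= 0) || any(areaMm2 <= 0))
    stop("domain error: spot inputs must be positive", call. = FALSE)
  ng <- concStd * volumeNl * 1e-6            # nL -> mL
  massG <- areaMm2 * 1e-2 *                  # mm^2 -> cm^2
    (grid@sectionThickness * .UM_TO_CM) * grid@tissueDensity
  ng / massG
}

#' Fit an on-tissue calibration curve
#'
#' Ordinary or 1/x^2-weighted least squares of mean normalized spot intensity
#' against tissue-equivalent concentration. Sigma is the standard error of
#' the intercept, LOD = 3.3 sigma / S, and LLOQ is the lowest nonzero
#' standard in tissue units. The curve is accepted when the regression F-test
#' gives p < 0.05 with a positive slope (weighted curves additionally
#' require R^2 >= 0.99).
#'
#' @param conc tissue-equivalent concentrations (ng g^-1).
#' @param intensity mean normalized intensities.
#' @param weighting "none" or "inverse_x2".
#' @param analyte analyte label carried on the curve.
#' @return a \linkS4class{CalibrationCurve}.
#' @export
fitCalibration <- function(conc, intensity,
                           weighting = c("none", "inverse_x2"),
                           analyte = "analyte") {
  weighting <- match.arg(weighting)
  if (length(conc) != length(intensity))
    stop("conc and intensity lengths differ", call. = FALSE)
  if (length(unique(conc)) < 3)
    stop("insufficient data: need at least 3 distinct concentrations",
         call. = FALSE)
  w <- if (weighting == "inverse_x2") 1 / conc^2 else rep(1, length(conc))
  fit <- stats::lm(intensity ~ conc, weights = w)
  cf <- stats::coef(fit)
  slope <- unname(cf["conc"]); intercept <- unname(cf["(Intercept)"])
  rss <- sum(w * stats::residuals(fit)^2)
  if (rss < 1e-20 * sum(w * intensity^2) || rss == 0) {
    sigma <- 0; fp <- 0; r2 <- 1
  } else {
    sm <- summary(fit)
    sigma <- sm$coefficients["(Intercept)", "Std. Error"]
    fstat <- sm$fstatistic
    fp <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    r2 <- sm$r.squared
  }
  lloq <- min(conc[conc > 0])
  lod <- if (slope > 0) 3.3 * sigma / slope else NA_real_
  accepted <- isTRUE(slope > 0 && fp < 0.05 &&
                     (weighting != "inverse_x2" || r2 >= 0.99))
  new("CalibrationCurve", analyte = analyte, slope = slope,
      intercept = intercept, sigmaIntercept = sigma,
      rSquared = unname(r2), fTestP = unname(fp), lod = unname(lod),
      lloq = lloq, weighting = weighting, accepted = accepted,
      points = data.frame(conc = conc, intensity = intensity))
}

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve [%s]: S = %.4g, intercept = %.4g, R2 = %.5f\n",
    object@analyte, object@slope, object@intercept, object@rSquared))
  cat(sprintf("  F-test p = %.3g, LOD = %.4g, LLOQ = %.4g ng/g, %s, %s\n",
              object@fTestP, object@lod, object@lloq, object@weighting,
              if (object@accepted) "accepted" else "rejected"))
})

#' Fit the calibration curve from a spotted section
#'
#' Normalizes the calibration section to its internal standard, averages the
#' ratio within each spot ROI, converts each standard to tissue-equivalent
#' units, and fits the curve.
#'
#' @param section the calibration \linkS4class{SectionDataset}.
#' @param layout the \linkS4class{CalibrationLayout} used for spotting.
#' @param analyteId analyte group.
#' @param weighting passed to \code{\link{fitCalibration}}.
#' @return a \linkS4class{CalibrationCurve}.
#' @export
calibrateSection <- function(section, layout, analyteId,
                             weighting = c("inverse_x2", "none")) {
  weighting <- match.arg(weighting)
  nrm <- normalizeToIS(section, analyteId)
  sp <- layout@spots
  conc <- numeric(nrow(sp)); intens <- numeric(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    m <- spotMask(layout, i, section@grid) & nrm$valid
    conc[i] <- spotTissueEquivalent(sp$concentration[i], sp$volumeNl[i],
                                    sp$areaMm2[i], section@grid)
    intens[i] <- mean(nrm$ratio[m])
  }
  fitCalibration(conc, intens, weighting = weighting, analyte = analyteId)
}

#' Quantify one region of interest
#'
#' The region's mean normalized intensity is converted through the curve:
#' concentration = (mean intensity - intercept) / slope. Negative estimates
#' are clipped to zero and flagged; estimates below the LLOQ carry a
#' below-LLOQ flag but are reported (downstream ratios propagate the flag
#' rather than dropping the region).
#'
#' @param normalized list(ratio, valid) from \code{\link{normalizeToIS}}.
#' @param mask logical region mask.
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param region label carried into the result.
#' @return data.frame(region, nPixels, meanIntensity, concentration,
#'   belowLloq, clipped).
#' @export
quantifyRegion <- function(normalized, mask, curve, region = "ROI") {
  use <- mask & normalized$valid
  n <- sum(use)
  if (n == 0)
    stop("degenerate input: empty region mask after pixel exclusion",
         call. = FALSE)
  mi <- mean(normalized$ratio[use])
  conc <- (mi - curve@intercept) / curve@slope
  clipped <- conc < 0
  if (clipped) conc <- 0
  data.frame(region = region, nPixels = n, meanIntensity = mi,
             concentration = conc,
             belowLloq = conc < curve@lloq, clipped = clipped)
}

#' Quantify a whole section against an atlas
#'
#' Produces the region-annotated concentration table: one row per atlas
#' region, one for the unannotated tissue ("background") and one for the
#' entire coronal section ("whole_section", computed on the analysis mask
#' that excludes calibration spots).
#'
#' @param section a \linkS4class{SectionDataset}.
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param analyteId analyte group.
#' @param layout optional \linkS4class{CalibrationLayout} excluded from the
#'   whole-section mask.
#' @return data.frame with one row per region plus background and
#'   whole_section; includes condition and subject columns.
#' @export
quantifySection <- function(section, atlas, curve, analyteId,
                            layout = NULL) {
  checkAtlas(atlas, section)
  nrm <- normalizeToIS(section, analyteId)
  whole <- analysisMask(section, layout)
  annotated <- Reduce(`|`, atlas@regions)
  rows <- list()
  for (lab in regionNames(atlas))
    rows[[lab]] <- quantifyRegion(nrm, atlas@regions[[lab]] & whole, curve,
                                  region = lab)
  rows$background <- quantifyRegion(nrm, whole & !annotated, curve,
                                    region = "background")
  rows$whole_section <- quantifyRegion(nrm, whole, curve,
                                       region = "whole_section")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$condition <- section@condition
  out$subjectId <- section@subjectId
  out
}

#' Quality-control evaluation
#'
#' Accuracy (percent bias of the mean from nominal) and precision (percent
#' relative standard deviation) of replicate QC measurements, with pass/fail
#' flags at the given limits (defaults +/-15 percent bias, 15 percent RSD).
#'
#' @param measured replicate measurements (ng g^-1).
#' @param nominal nominal concentration (ng g^-1), positive.
#' @param accuracyLimit allowed absolute percent bias.
#' @param rsdLimit allowed percent RSD.
#' @return data.frame(nominal, n, mean, biasPct, rsdPct, accuracyPass,
#'   precisionPass, pass).
#' @export
qcEvaluate <- function(measured, nominal, accuracyLimit = 15,
                       rsdLimit = 15) {
  if (nominal <= 0)
    stop("domain error: nominal must be positive", call. = FALSE)
  if (length(measured) < 2)
    stop("insufficient data: need at least 2 replicates for RSD",
         call. = FALSE)
  m <- mean(measured)
  bias <- 100 * (m - nominal) / nominal
  rsd <- 100 * stats::sd(measured) / m
  accPass <- abs(bias) <= accuracyLimit
  prePass <- rsd <= rsdLimit
  data.frame(nominal = nominal, n = length(measured), mean = m,
             biasPct = bias, rsdPct = rsd, accuracyPass = accPass,
             precisionPass = prePass, pass = accPass && prePass)
}
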