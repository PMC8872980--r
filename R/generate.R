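# run expr with a local RNG state seeded at `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# deterministic per-component subseed from a master seed (kept below 2^31)
.subseed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * k) %% 2147483587
}

.NG_TO_G <- 1e-9

#' Smooth multiplicative gain field
#'
#' A low-order (quadratic) 2-D polynomial with random coefficients, scaled so
#' the field lies in [1 - amplitude, 1 + amplitude]. One field is shared by
#' all channels of a section, emulating matrix-application and spray
#' inhomogeneity that ratio normalization cancels.
#'
#' @param grid a \linkS4class{PixelGrid}.
#' @param amplitude field amplitude in [0, 1).
#' @param seed integer seed.
#' @return numeric matrix of gains.
#' @export
gainField <- function(grid, amplitude, seed) {
  if (amplitude == 0) return(matrix(1, grid@nRows, grid@nCols))
  .withSeed(seed, {
    u <- matrix(seq(-1, 1, length.out = grid@nRows), grid@nRows, grid@nCols)
    v <- matrix(seq(-1, 1, length.out = grid@nCols), grid@nRows, grid@nCols,
                byrow = TRUE)
    co <- stats::rnorm(5)
    p <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * u^2 + co[5] * v^2
    p <- p / max(abs(p))
    1 + amplitude * p
  })
}

# lognormal multiplicative noise with mean 1 and the given CV
.lognormNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# additive background draws (mean bg, exponential)
.backgroundNoise <- function(n, bg) {
  if (bg == 0) return(rep(0, n))
  stats::rexp(n, rate = 1 / bg)
}

#' True concentration image for a profile
#'
#' @inheritParams regionTruthTable
#' @param tissue logical tissue mask.
#' @return numeric matrix of true concentrations (ng g^-1); zero off tissue.
#' @export
trueConcentrationImage <- function(profile, condition, atlas, tissue) {
  truth <- regionTruthTable(profile, condition, atlas, tissue)
  img <- matrix(0, nrow(tissue), ncol(tissue))
  img[tissue] <- truth$concentration[truth$region == "background"]
  for (lab in regionNames(atlas)) {
    if (!lab %in% profile@regionTruth$region)
      stop("configuration error: profile '", profile@name,
           "' has no ground truth for region '", lab, "'", call. = FALSE)
    img[atlas@regions[[lab]] & tissue] <-
      truth$concentration[truth$region == lab]
  }
  img
}

# forward detection model for one analyte image; returns the two raw channels
.detect <- function(concImg, tissue, profile, noise, gain, seedA, seedIS) {
  # concImg here is the analyte amount per pixel in ng
  n <- length(concImg)
  analyteMass <- concImg * .NG_TO_G  # grams of analyte per pixel
  analyte <- .withSeed(seedA, {
    eps <- .lognormNoise(n, noise@pixelCv)
    bg <- .backgroundNoise(n, noise@background)
    profile@responseFactor * analyteMass * gain * eps + bg
  })
  isCv <- sqrt(noise@pixelCv^2 + noise@isSprayCv^2)
  isImg <- .withSeed(seedIS, {
    epsIS <- .lognormNoise(n, isCv)
    bgIS <- .backgroundNoise(n, noise@background)
    profile@isResponseFactor * profile@isAmountPerPixel * gain * epsIS + bgIS
  })
  list(analyte = analyte, is = isImg)
}

#' Generate a synthetic section
#'
#' Forward model: regional true concentrations follow the steady-state
#' relations C = Kp,uu,ROI x Vu,ROI x Cu,plasma (in vivo),
#' C = Vu,ROI x Cu,buffer (brain slice) and 0 (control). Pixel analyte
#' intensity is response factor x analyte mass in the pixel x gain x
#' multiplicative noise + background; the internal-standard channel shares
#' the same gain field. Identical seeds give bit-identical sections.
#'
#' @param profile a \linkS4class{DrugProfile}.
#' @param condition "in_vivo", "brain_slice" or "control".
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed integer master seed.
#' @param grid a \linkS4class{PixelGrid}.
#' @param tissue logical tissue mask.
#' @param subjectId,replicateId identifiers.
#' @return a \linkS4class{SectionDataset} with an analyte and an
#'   internal-standard channel.
#' @export
generateSection <- function(profile, condition, atlas, noise, seed,
                            grid = defaultGrid(),
                            tissue = defaultTissueMask(grid),
                            subjectId = "s1", replicateId = "r1") {
  condition <- match.arg(condition, c("in_vivo", "brain_slice", "control"))
  concImg <- trueConcentrationImage(profile, condition, atlas, tissue)
  pm <- pixelTissueMass(grid)
  gain <- gainField(grid, noise@gainAmplitude, .subseed(seed, 1))
  ch <- .detect(concImg * pm, tissue, profile, noise, gain,
                .subseed(seed, 2), .subseed(seed, 3))
  analyte <- matrix(ch$analyte, grid@nRows, grid@nCols)
  isImg <- matrix(ch$is, grid@nRows, grid@nCols)
  SectionDataset(
    grid = grid,
    channels = list(
      ChannelImage(profile@name, analyte, group = profile@name,
                   role = "analyte"),
      ChannelImage(paste0(profile@name, "-IS"), isImg, group = profile@name,
                   role = "internal_standard")),
    tissueMask = tissue, condition = condition,
    subjectId = subjectId, replicateId = replicateId)
}

#' Default calibration-spot layout
#'
#' Six calibration standards (25, 50, 100, 250, 500 and 1000 ng mL^-1; 40 nL
#' each) as 1.0-mm-diameter spots, placed deterministically on the lower part
#' of the control tissue so that every spot disc lies fully on tissue and
#' clear of the atlas regions and of the other spots.
#'
#' @param group analyte group the standards belong to.
#' @param concentrations standard concentrations in ng mL^-1.
#' @param volumeNl spotted volume per standard (nL).
#' @param areaMm2 spot area; default a 1.0-mm disc (pi/4 mm^2).
#' @param grid a \linkS4class{PixelGrid}.
#' @param tissue logical tissue mask.
#' @param atlas atlas whose regions the spots must avoid (may be NULL).
#' @return a \linkS4class{CalibrationLayout}.
#' @export
defaultCalibrationLayout <- function(group = "risperidone",
                                     concentrations = c(25, 50, 100, 250,
                                                        500, 1000),
                                     volumeNl = 40,
                                     areaMm2 = pi * 0.5^2,
                                     grid = defaultGrid(),
                                     tissue = defaultTissueMask(grid),
                                     atlas = defaultAtlas(grid)) {
  rad <- spotRadiusPx(areaMm2, grid)
  avoid <- if (is.null(atlas)) matrix(FALSE, grid@nRows, grid@nCols)
           else Reduce(`|`, atlas@regions)
  chosen <- matrix(numeric(0), ncol = 2)
  for (r in seq(grid@nRows, 1)) {
    for (cc in seq_len(grid@nCols)) {
      if (nrow(chosen) >= length(concentrations)) break
      d <- .discMask(grid, r, cc, rad)
      if (any(d & !tissue) || any(d & avoid)) next
      if (nrow(chosen) > 0 &&
          any((chosen[, 1] - r)^2 + (chosen[, 2] - cc)^2 <=
              (2 * rad + 1)^2)) next
      chosen <- rbind(chosen, c(r, cc))
    }
    if (nrow(chosen) >= length(concentrations)) break
  }
  if (nrow(chosen) < length(concentrations))
    stop("could not place ", length(concentrations),
         " calibration spots on the tissue", call. = FALSE)
  new("CalibrationLayout", spots = data.frame(
    spotId = seq_along(concentrations),
    row = chosen[, 1], col = chosen[, 2],
    areaMm2 = areaMm2, concentration = sort(concentrations),
    volumeNl = volumeNl, group = group))
}

#' Generate a calibration section
#'
#' A control (drug-naive) section carrying the spotted calibration standards:
#' spot pixels receive the spot's tissue-equivalent concentration through the
#' same detection model as real tissue, the internal standard is sprayed over
#' the whole section, and the gain field is shared between spots and IS (the
#' standards are spotted before IS spraying).
#'
#' @param profile a \linkS4class{DrugProfile}.
#' @param layout a \linkS4class{CalibrationLayout}.
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed integer seed.
#' @param grid a \linkS4class{PixelGrid}.
#' @param tissue logical tissue mask.
#' @param atlas optional atlas; spot overlap with an annotated region is a
#'   configuration error.
#' @return a control \linkS4class{SectionDataset} with spots.
#' @export
generateCalibration <- function(profile, layout, noise, seed,
                                grid = defaultGrid(),
                                tissue = defaultTissueMask(grid),
                                atlas = NULL) {
  concImg <- matrix(0, grid@nRows, grid@nCols)
  avoid <- if (is.null(atlas)) NULL else Reduce(`|`, atlas@regions)
  for (i in seq_len(nrow(layout@spots))) {
    sp <- layout@spots[i, ]
    d <- spotMask(layout, i, grid)
    if (any(d & !tissue))
      stop("configuration error: spot ", sp$spotId,
           " extends off the tissue", call. = FALSE)
    if (!is.null(avoid) && any(d & avoid))
      stop("configuration error: spot ", sp$spotId,
           " overlaps an annotated region", call. = FALSE)
    concImg[d] <- concImg[d] + spotTissueEquivalent(
      sp$concentration, sp$volumeNl, sp$areaMm2, grid)
  }
  pm <- pixelTissueMass(grid)
  gain <- gainField(grid, noise@gainAmplitude, .subseed(seed, 1))
  ch <- .detect(concImg * pm, tissue, profile, noise, gain,
                .subseed(seed, 2), .subseed(seed, 3))
  SectionDataset(
    grid = grid,
    channels = list(
      ChannelImage(profile@name, matrix(ch$analyte, grid@nRows, grid@nCols),
                   group = profile@name, role = "analyte"),
      ChannelImage(paste0(profile@name, "-IS"),
                   matrix(ch$is, grid@nRows, grid@nCols),
                   group = profile@name, role = "internal_standard")),
    tissueMask = tissue, condition = "control",
    subjectId = "calibration", replicateId = "r1")
}

#' Generate bulk (tabular) samples
#'
#' Lognormal replicates around the profile's steady-state bulk truths:
#' total plasma concentration Cu,plasma / fu,plasma, or the unbound buffer
#' concentration.
#'
#' @param profile a \linkS4class{DrugProfile}.
#' @param matrix "plasma_total" or "buffer_unbound".
#' @param n number of replicates.
#' @param noiseCv lognormal CV of the replicates.
#' @param seed integer seed.
#' @return data.frame(matrix, value, replicateId) with values in ng mL^-1.
#' @export
generateBulk <- function(profile, matrix = c("plasma_total", "buffer_unbound"),
                         n, noiseCv, seed) {
  matrix <- match.arg(matrix)
  truth <- switch(matrix,
    plasma_total = profile@cuPlasmaSs / profile@fuPlasma,
    buffer_unbound = profile@cuBufferSs)
  vals <- .withSeed(seed, truth * .lognormNoise(n, noiseCv))
  data.frame(matrix = matrix, value = vals,
             replicateId = paste0("rep", seq_len(n)))
}

#' Simulate one complete study
#'
#' The packaged study design: paired in vivo (one section per animal) and
#' brain-slice replicate sections, one drug-naive control, one calibration
#' section with spotted standards, and bulk plasma/buffer tables.
#'
#' @param profile a \linkS4class{DrugProfile}.
#' @param nInvivo number of in vivo animals (default 6).
#' @param nSlice number of brain-slice replicates (default 3).
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed integer master seed.
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param grid a \linkS4class{PixelGrid}.
#' @param tissue logical tissue mask.
#' @param layout a \linkS4class{CalibrationLayout}; default placed
#'   automatically.
#' @param bulkCv CV of bulk replicates (default 0.1).
#' @return list with elements invivo (list of sections), slices, control,
#'   calibration, layout, bulk (data.frame) and truth (list of in vivo and
#'   brain-slice \code{\link{regionTruthTable}}s).
#' @export
simulateStudy <- function(profile, nInvivo = 6, nSlice = 3,
                          noise = NoiseModel(), seed = 1,
                          atlas = defaultAtlas(), grid = defaultGrid(),
                          tissue = defaultTissueMask(grid),
                          layout = defaultCalibrationLayout(
                            profile@name, grid = grid, tissue = tissue,
                            atlas = atlas),
                          bulkCv = 0.1) {
  invivo <- lapply(seq_len(nInvivo), function(i)
    generateSection(profile, "in_vivo", atlas, noise, .subseed(seed, 10 + i),
                    grid, tissue, subjectId = paste0("animal", i)))
  slices <- lapply(seq_len(nSlice), function(i)
    generateSection(profile, "brain_slice", atlas, noise,
                    .subseed(seed, 40 + i), grid, tissue,
                    subjectId = paste0("slice", i)))
  control <- generateSection(profile, "control", atlas, noise,
                             .subseed(seed, 70), grid, tissue,
                             subjectId = "control")
  calibration <- generateCalibration(profile, layout, noise,
                                     .subseed(seed, 80), grid, tissue,
                                     atlas = atlas)
  bulk <- rbind(
    generateBulk(profile, "plasma_total", nInvivo, bulkCv,
                 .subseed(seed, 90)),
    generateBulk(profile, "buffer_unbound", nSlice, bulkCv,
                 .subseed(seed, 91)))
  list(invivo = invivo, slices = slices, control = control,
       calibration = calibration, layout = layout, bulk = bulk,
       truth = list(
         in_vivo = regionTruthTable(profile, "in_vivo", atlas, tissue),
         brain_slice = regionTruthTable(profile, "brain_slice", atlas,
                                        tissue)))
}
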