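#' Unbound volume of distribution from slice amount (buffer-film corrected)
#'
#' Brain-slice estimate of Vu,brain correcting for the film of incubation
#' buffer adhering to the slice: (A - Vi C) / (C (1 - Vi)), with Vi the film
#' volume per gram slice (0.094 mL g^-1 by inulin marker).
#'
#' @param aBrainSlice measured amount in the slice (ng g^-1).
#' @param cuBuffer final unbound buffer concentration (ng mL^-1), positive.
#' @param vI adherent buffer-film volume (mL g^-1), in [0, 1).
#' @return Vu,brain in mL g^-1; negative results (drug below the film
#'   content) are returned with a warning flag attribute "flagged".
#' @export
vuBrainFromAmount <- function(aBrainSlice, cuBuffer, vI = 0.094) {
  if (any(cuBuffer <= 0))
    stop("domain error: cuBuffer must be positive", call. = FALSE)
  if (vI < 0 || vI >= 1)
    stop("domain error: vI must lie in [0, 1)", call. = FALSE)
  vu <- (aBrainSlice - vI * cuBuffer) / (cuBuffer * (1 - vI))
  attr(vu, "flagged") <- vu < 0
  vu
}

#' Unbound volume of distribution from slice concentration
#'
#' Film-free form used when slice preparation removes the adherent buffer
#' layer before measurement: Vu,brain = C_tot,slice / C_u,buffer. Equals the
#' amount-based form in the limit Vi -> 0.
#'
#' @param cTotSlice total slice concentration (ng g^-1).
#' @param cuBuffer unbound buffer concentration (ng mL^-1), positive.
#' @return Vu,brain in mL g^-1.
#' @export
vuBrainFromConc <- function(cTotSlice, cuBuffer) {
  if (any(cuBuffer <= 0))
    stop("domain error: cuBuffer must be positive", call. = FALSE)
  cTotSlice / cuBuffer
}

#' Total brain-to-plasma partition coefficient
#'
#' @param cTotBrain total brain concentration (ng g^-1).
#' @param cTotPlasma total plasma concentration (ng mL^-1), positive.
#' @return Kp (dimensionless).
#' @export
kpTotal <- function(cTotBrain, cTotPlasma) {
  if (any(cTotPlasma <= 0))
    stop("domain error: cTotPlasma must be positive", call. = FALSE)
  cTotBrain / cTotPlasma
}

#' Kp,uu by the combinatory mapping approach
#'
#' Reference route combining the total partition coefficient with the
#' unbound distribution volume and the plasma unbound fraction:
#' Kp,uu = Kp / (Vu x fu,plasma).
#'
#' @param kP total partition coefficient.
#' @param vU unbound volume of distribution (mL g^-1), positive.
#' @param fuPlasma unbound plasma fraction in (0, 1].
#' @return Kp,uu (dimensionless).
#' @export
kpuuCma <- function(kP, vU, fuPlasma) {
  if (any(vU <= 0)) stop("domain error: vU must be positive", call. = FALSE)
  if (any(fuPlasma <= 0) || any(fuPlasma > 1))
    stop("domain error: fuPlasma must lie in (0, 1]", call. = FALSE)
  kP / (vU * fuPlasma)
}

#' Buffer-to-plasma correction factor
#'
#' Ratio of the unbound buffer concentration to the unbound plasma
#' concentration, applied to the in vivo / slice concentration ratio when
#' the two unbound concentrations differ.
#'
#' @param cuBuffer unbound buffer concentration (ng mL^-1), positive.
#' @param cuPlasma unbound plasma concentration (ng mL^-1), positive.
#' @return CF (dimensionless).
#' @export
correctionFactor <- function(cuBuffer, cuPlasma) {
  if (any(cuBuffer <= 0) || any(cuPlasma <= 0))
    stop("domain error: concentrations must be positive", call. = FALSE)
  cuBuffer / cuPlasma
}

#' Kp,uu from the in vivo / brain-slice concentration ratio
#'
#' The imaging route: Kp,uu = CF x C_tot,invivo / C_tot,slice, with CF = 1
#' when the unbound plasma and buffer concentrations are matched.
#'
#' @param cTotInvivo total in vivo concentration (ng g^-1).
#' @param cTotSlice total brain-slice concentration (ng g^-1), positive.
#' @param cf correction factor, positive (default 1).
#' @return Kp,uu (dimensionless).
#' @export
kpuuRatio <- function(cTotInvivo, cTotSlice, cf = 1) {
  if (any(cTotSlice <= 0))
    stop("domain error: cTotSlice must be positive", call. = FALSE)
  if (any(cf <= 0)) stop("domain error: cf must be positive", call. = FALSE)
  cf * cTotInvivo / cTotSlice
}

#' Unbound interstitial-fluid concentration
#'
#' Converts a total in vivo concentration into the unbound ISF concentration
#' using the unbound distribution volume: C_u,ISF = C_tot / Vu.
#'
#' @param cTotInvivo total in vivo concentration (ng g^-1).
#' @param vU unbound volume of distribution (mL g^-1), positive.
#' @return unbound ISF concentration (ng mL^-1).
#' @export
unboundIsfConc <- function(cTotInvivo, vU) {
  if (any(vU <= 0)) stop("domain error: vU must be positive", call. = FALSE)
  cTotInvivo / vU
}

#' Classify the dominant BBB transport process
#'
#' Kp,uu below unity indicates net efflux, above unity active uptake, and
#' unity passive transport. With a confidence interval: efflux if the upper
#' bound is below 1, uptake if the lower bound exceeds 1, passive if the
#' interval covers 1. Without an interval, points within a tolerance of 1
#' are indeterminate.
#'
#' @param kpuu point estimate.
#' @param ci length-2 interval (lower, upper) or NULL.
#' @param tolerance half-width of the indeterminate band when no interval is
#'   available (default 0.1).
#' @return one of "efflux", "passive", "uptake", "indeterminate".
#' @export
classifyTransport <- function(kpuu, ci = NULL, tolerance = 0.1) {
  if (!is.null(ci) && all(is.finite(ci))) {
    if (ci[1] > kpuu || ci[2] < kpuu)
      stop("ci must contain the point estimate", call. = FALSE)
    if (ci[2] < 1) return("efflux")
    if (ci[1] > 1) return("uptake")
    return("passive")
  }
  if (abs(kpuu - 1) < tolerance) return("indeterminate")
  if (kpuu < 1) "efflux" else "uptake"
}

# mean slice concentration per region across slice replicates
.sliceMeans <- function(sliceTables) {
  regs <- sliceTables[[1]]$region
  for (tb in sliceTables)
    if (!setequal(tb$region, regs))
      stop("alignment error: slice tables disagree on region labels",
           call. = FALSE)
  mat <- vapply(sliceTables, function(tb)
    tb$concentration[match(regs, tb$region)], numeric(length(regs)))
  flg <- vapply(sliceTables, function(tb)
    tb$belowLloq[match(regs, tb$region)], logical(length(regs)))
  list(region = regs,
       mean = rowMeans(as.matrix(mat)),
       flagged = apply(as.matrix(flg), 1, any))
}

#' Build the regional Kp,uu map
#'
#' Combines per-subject in vivo region tables with brain-slice replicate
#' tables: each animal's regional concentration is divided by the mean slice
#' concentration of that region (slices are unpaired replicates), scaled by
#' the correction factor. Per-region mean, SD and a t-based confidence
#' interval over animals feed the transport classification. Any ratio with a
#' below-LLOQ operand carries an unreliable flag.
#'
#' @param invivoTables list of per-animal data.frames from
#'   \code{\link{quantifySection}}.
#' @param sliceTables list of per-slice data.frames.
#' @param cf correction factor (default 1).
#' @param conf confidence level of the classification interval (default
#'   0.95).
#' @return list(table = per-region summary data.frame, perSubject = matrix
#'   of per-animal Kp,uu, heatmap = one-column matrix of regional means with
#'   the colour limits in attr "limits").
#' @export
buildKpuuMap <- function(invivoTables, sliceTables, cf = 1, conf = 0.95) {
  sl <- .sliceMeans(sliceTables)
  regs <- sl$region
  perSubject <- matrix(NA_real_, length(regs), length(invivoTables),
                       dimnames = list(regs, vapply(invivoTables, function(tb)
                         tb$subjectId[1], character(1))))
  unreliable <- sl$flagged
  names(unreliable) <- regs
  for (j in seq_along(invivoTables)) {
    tb <- invivoTables[[j]]
    if (!setequal(tb$region, regs))
      stop("alignment error: in vivo and slice tables disagree on regions",
           call. = FALSE)
    idx <- match(regs, tb$region)
    perSubject[, j] <- kpuuRatio(tb$concentration[idx], sl$mean, cf = cf)
    unreliable <- unreliable | tb$belowLloq[idx]
  }
  n <- ncol(perSubject)
  mn <- rowMeans(perSubject)
  sd <- apply(perSubject, 1, stats::sd)
  # a single subject carries no dispersion: no interval, point-based class
  tq <- if (n >= 2) stats::qt(1 - (1 - conf) / 2, df = n - 1) else NA_real_
  lo <- mn - tq * sd / sqrt(n)
  hi <- mn + tq * sd / sqrt(n)
  cls <- vapply(seq_along(regs), function(i)
    classifyTransport(mn[i], c(lo[i], hi[i])), character(1))
  tab <- data.frame(region = regs, kpuu = mn, sd = sd, n = n,
                    ciLow = lo, ciHigh = hi, transportClass = cls,
                    unreliable = unname(unreliable))
  rownames(tab) <- NULL
  roiRows <- !tab$region %in% c("whole_section", "background")
  hm <- matrix(tab$kpuu[roiRows], ncol = 1,
               dimnames = list(tab$region[roiRows], "kpuu"))
  attr(hm, "limits") <- range(hm)
  list(table = tab, perSubject = perSubject, heatmap = hm)
}

#' Assemble the full neuroPK result table
#'
#' Joins the imaging route with the bulk measurements: per region it reports
#' the mean in vivo and slice concentrations, Vu (slice / buffer), Kp
#' (in vivo / total plasma), Kp,uu by both the concentration-ratio route and
#' the combinatory mapping route, the unbound ISF concentration, and the
#' transport class.
#'
#' @inheritParams buildKpuuMap
#' @param cTotPlasma mean total plasma concentration (ng mL^-1).
#' @param cuBuffer mean unbound buffer concentration (ng mL^-1).
#' @param fuPlasma unbound plasma fraction.
#' @param cf correction factor; if NULL, computed as
#'   \code{correctionFactor(cuBuffer, fuPlasma * cTotPlasma)}.
#' @return data.frame, one row per region.
#' @export
neuroPKTable <- function(invivoTables, sliceTables, cTotPlasma, cuBuffer,
                         fuPlasma, cf = NULL) {
  if (is.null(cf))
    cf <- correctionFactor(cuBuffer, fuPlasma * cTotPlasma)
  map <- buildKpuuMap(invivoTables, sliceTables, cf = cf)
  sl <- .sliceMeans(sliceTables)
  regs <- sl$region
  ivMat <- vapply(invivoTables, function(tb)
    tb$concentration[match(regs, tb$region)], numeric(length(regs)))
  cInvivo <- rowMeans(as.matrix(ivMat))
  vu <- vuBrainFromConc(sl$mean, cuBuffer)
  kp <- kpTotal(cInvivo, cTotPlasma)
  out <- data.frame(
    region = regs,
    cTotInvivo = cInvivo,
    cTotSlice = sl$mean,
    vU = vu,
    kP = kp,
    kpuuRatio = map$table$kpuu[match(regs, map$table$region)],
    kpuuCma = kpuuCma(kp, vu, fuPlasma),
    cUIsf = unboundIsfConc(cInvivo, vu),
    cf = cf,
    sdKpuu = map$table$sd[match(regs, map$table$region)],
    transportClass = map$table$transportClass[match(regs, map$table$region)],
    unreliable = map$table$unreliable[match(regs, map$table$region)])
  rownames(out) <- NULL
  out
}
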