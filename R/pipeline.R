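#' Run configuration
#'
#' A plain named list serialized as YAML; the seed is recorded in every
#' output directory so any run is reproducible from its emitted config.
#'
#' @param drug one of the packaged drug names (see
#'   \code{\link{defaultProfiles}}).
#' @param nInvivo,nSlice study size (defaults 6 and 3).
#' @param pixelCv,gainAmplitude,isSprayCv,background noise parameters.
#' @param bulkCv CV of bulk replicates.
#' @param weighting calibration weighting ("none" or "inverse_x2").
#' @param alpha significance level for the region comparisons.
#' @param seed integer master seed.
#' @param outDir output directory.
#' @return a run-config list.
#' @export
runConfig <- function(drug = "risperidone", nInvivo = 6, nSlice = 3,
                      pixelCv = 0.15, gainAmplitude = 0.2,
                      isSprayCv = 0.05, background = 0.5, bulkCv = 0.1,
                      weighting = "inverse_x2", alpha = 0.01, seed = 1,
                      outDir = "msikpuu-run") {
  list(drug = drug, nInvivo = nInvivo, nSlice = nSlice, pixelCv = pixelCv,
       gainAmplitude = gainAmplitude, isSprayCv = isSprayCv,
       background = background, bulkCv = bulkCv, weighting = weighting,
       alpha = alpha, seed = seed, outDir = outDir)
}

#' Read / write a run configuration
#'
#' @param config a run-config list.
#' @param path YAML file path.
#' @return \code{writeRunConfig}: invisibly the path; \code{readRunConfig}:
#'   the config list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(runConfig, cfg)
}

.configNoise <- function(config)
  NoiseModel(config$pixelCv, config$gainAmplitude, config$isSprayCv,
             config$background)

.configProfile <- function(config) {
  profiles <- defaultProfiles()
  if (!config$drug %in% names(profiles))
    stop("usage error: unknown drug '", config$drug, "' (available: ",
         paste(names(profiles), collapse = ", "), ")", call. = FALSE)
  profiles[[config$drug]]
}

#' Simulate a study to disk
#'
#' Generates the paired in vivo / brain-slice / control sections, the
#' calibration section, the bulk tables and a ground-truth sidecar, and
#' writes everything (plus the config echo) under the configured output
#' directory.
#'
#' @param config a run-config list from \code{\link{runConfig}}.
#' @return invisibly, the output directory.
#' @export
runSimulate <- function(config = runConfig()) {
  profile <- .configProfile(config)
  study <- simulateStudy(profile, nInvivo = config$nInvivo,
                         nSlice = config$nSlice,
                         noise = .configNoise(config), seed = config$seed,
                         bulkCv = config$bulkCv)
  out <- config$outDir
  dir.create(file.path(out, "sections"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_along(study$invivo))
    saveSection(study$invivo[[i]],
                file.path(out, "sections", sprintf("invivo_%02d", i)))
  for (i in seq_along(study$slices))
    saveSection(study$slices[[i]],
                file.path(out, "sections", sprintf("slice_%02d", i)))
  saveSection(study$control, file.path(out, "sections", "control"))
  saveSection(study$calibration, file.path(out, "sections", "calibration"))
  saveAtlas(defaultAtlas(), file.path(out, "atlas"))
  utils::write.csv(study$layout@spots, file.path(out, "layout.csv"),
                   row.names = FALSE)
  utils::write.csv(study$bulk, file.path(out, "bulk.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  writeRunConfig(config, file.path(out, "config.yaml"))
  invisible(out)
}

.loadStudy <- function(out) {
  config <- readRunConfig(file.path(out, "config.yaml"))
  secDirs <- list.dirs(file.path(out, "sections"), recursive = FALSE)
  sections <- lapply(secDirs, loadSection)
  names(sections) <- basename(secDirs)
  spots <- utils::read.csv(file.path(out, "layout.csv"),
                           stringsAsFactors = FALSE)
  list(config = config, sections = sections,
       atlas = loadAtlas(file.path(out, "atlas")),
       layout = new("CalibrationLayout", spots = spots),
       bulk = readBulkSamples(file.path(out, "bulk.csv")))
}

#' Quantify a simulated or loaded study
#'
#' Fits the calibration curve from the spotted control section, quantifies
#' every section's regions and whole-section value, and writes the region
#' concentration table and the curve report.
#'
#' @param outDir directory produced by \code{\link{runSimulate}}.
#' @return invisibly, the region table (also written to
#'   region_quant.csv).
#' @export
runQuantify <- function(outDir) {
  st <- .loadStudy(outDir)
  drug <- st$config$drug
  curve <- calibrateSection(st$sections[["calibration"]], st$layout, drug,
                            weighting = st$config$weighting)
  if (!curve@accepted)
    stop("validation error: calibration curve rejected (F-test p = ",
         signif(curve@fTestP, 3), ")", call. = FALSE)
  tabs <- list()
  for (nm in names(st$sections)) {
    if (nm == "calibration") next
    tabs[[nm]] <- quantifySection(st$sections[[nm]], st$atlas, curve, drug)
    tabs[[nm]]$section <- nm
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  utils::write.csv(out, file.path(outDir, "region_quant.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(analyte = curve@analyte, slope = curve@slope,
         intercept = curve@intercept, sigmaIntercept = curve@sigmaIntercept,
         rSquared = curve@rSquared, fTestP = curve@fTestP, lod = curve@lod,
         lloq = curve@lloq, weighting = curve@weighting,
         accepted = curve@accepted, seed = st$config$seed),
    file.path(outDir, "curve.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}

# split a region_quant table into per-section region tables by condition
.splitQuant <- function(quant, cond) {
  keep <- quant[quant$condition == cond &
                !quant$region %in% "background", ]
  lapply(split(keep, keep$section), function(d) d)
}

#' NeuroPK estimation and statistics for a quantified study
#'
#' Builds the regional Kp,uu map from the quantified tables, assembles the
#' full neuroPK result table (Vu, Kp, Kp,uu by both routes, unbound ISF
#' concentration, transport class) using the bulk measurements, and runs the
#' normality-gated Dunnett comparison of regional in vivo concentrations
#' against the whole-section reference.
#'
#' @param outDir directory holding region_quant.csv (see
#'   \code{\link{runQuantify}}).
#' @return invisibly, list(neuropk, map, comparisons); also written as CSV.
#' @export
runNeuroPK <- function(outDir) {
  st <- .loadStudy(outDir)
  quant <- utils::read.csv(file.path(outDir, "region_quant.csv"),
                           stringsAsFactors = FALSE)
  invivoTabs <- .splitQuant(quant, "in_vivo")
  sliceTabs <- .splitQuant(quant, "brain_slice")
  if (length(invivoTabs) == 0 || length(sliceTabs) == 0)
    stop("validation error: need quantified tables for both conditions",
         call. = FALSE)
  plasma <- st$bulk$value[st$bulk$matrix == "plasma_total"]
  buffer <- st$bulk$value[st$bulk$matrix == "buffer_unbound"]
  profile <- .configProfile(st$config)
  pk <- neuroPKTable(invivoTabs, sliceTabs,
                     cTotPlasma = mean(plasma), cuBuffer = mean(buffer),
                     fuPlasma = profile@fuPlasma)
  map <- buildKpuuMap(invivoTabs, sliceTabs,
                      cf = pk$cf[1])
  # Dunnett: regional in vivo concentrations vs the whole-section reference
  regs <- setdiff(pk$region, "whole_section")
  groups <- lapply(regs, function(r)
    vapply(invivoTabs, function(tb)
      tb$concentration[tb$region == r], numeric(1)))
  names(groups) <- regs
  reference <- vapply(invivoTabs, function(tb)
    tb$concentration[tb$region == "whole_section"], numeric(1))
  comparisons <- tryCatch({
    gate <- normalityGate(reference)
    cmp <- dunnettVsReference(groups, reference, alpha = st$config$alpha)
    cmp$referenceNormalityP <- gate$p
    cmp
  }, error = function(e) {
    # noiseless or tiny studies have no pooled variance to test against;
    # the map is still valid, the comparison table is just empty
    out <- data.frame(group = character(), estimate = numeric(),
                      reference = numeric(), statistic = numeric(),
                      pAdjusted = numeric(), significant = logical(),
                      referenceNormalityP = numeric())
    attr(out, "note") <- conditionMessage(e)
    out
  })
  utils::write.csv(pk, file.path(outDir, "neuropk.csv"), row.names = FALSE)
  utils::write.csv(data.frame(region = rownames(map$heatmap),
                              kpuu = map$heatmap[, 1],
                              limitLow = attr(map$heatmap, "limits")[1],
                              limitHigh = attr(map$heatmap, "limits")[2]),
                   file.path(outDir, "kpuu_map.csv"), row.names = FALSE)
  utils::write.csv(comparisons, file.path(outDir, "comparisons.csv"),
                   row.names = FALSE)
  invisible(list(neuropk = pk, map = map, comparisons = comparisons))
}
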