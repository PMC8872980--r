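# Small in-code fixtures shared across test files.

# a tiny two-region atlas on an all-tissue grid, for fast unit tests
tinyWorld <- function(nr = 20, nc = 24) {
  grid <- PixelGrid(nr, nc, rasterStep = 100)
  tissue <- matrix(TRUE, nr, nc)
  r1 <- matrix(FALSE, nr, nc); r1[3:6, 3:8] <- TRUE
  r2 <- matrix(FALSE, nr, nc); r2[10:15, 10:20] <- TRUE
  atlas <- RegionAtlas(list(MCx = r1, CPu = r2))
  list(grid = grid, tissue = tissue, atlas = atlas)
}

# a minimal profile with ground truth only for the tiny atlas regions
tinyProfile <- function(kpuuMCx = 0.2, kpuuCPu = 0.4, vu = 10,
                        cu = 100, fu = 0.5) {
  DrugProfile("tinydrug", cuPlasmaSs = cu, cuBufferSs = cu, fuPlasma = fu,
              regionTruth = data.frame(region = c("MCx", "CPu"),
                                       kpuu = c(kpuuMCx, kpuuCPu),
                                       vu = c(vu, vu)),
              kpuuBrain = 0.3, kpuuBackground = 0.3, vuBackground = vu)
}

# run the full estimator chain for one packaged drug and return the map table
runDrugStudy <- function(drug, noise = NoiseModel(), seed = 1,
                         nInvivo = 6, nSlice = 3) {
  atlas <- defaultAtlas()
  profile <- defaultProfiles()[[drug]]
  study <- simulateStudy(profile, nInvivo = nInvivo, nSlice = nSlice,
                         noise = noise, seed = seed)
  curve <- calibrateSection(study$calibration, study$layout, drug)
  ivq <- lapply(study$invivo, quantifySection, atlas = atlas,
                curve = curve, analyteId = drug)
  slq <- lapply(study$slices, quantifySection, atlas = atlas,
                curve = curve, analyteId = drug)
  list(profile = profile, study = study, curve = curve,
       invivo = ivq, slices = slq, map = buildKpuuMap(ivq, slq))
}
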