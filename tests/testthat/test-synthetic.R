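test_that("packaged profiles reproduce the published ground truths", {
  profiles <- defaultProfiles()
  atlas <- defaultAtlas()
  w <- regionAreaWeights(atlas)
  targets <- c(risperidone = 0.10, clozapine = 0.31, olanzapine = 0.82)
  folds <- c(risperidone = 1.3, clozapine = 1.2, olanzapine = 1.5)
  for (nm in names(targets)) {
    pr <- profiles[[nm]]
    rt <- pr@regionTruth
    # area-weighted mean regional Kp,uu over the tissue equals the
    # whole-brain value
    kpuuAll <- c(rt$kpuu[match(setdiff(names(w), "background"), rt$region)],
                 pr@kpuuBackground)
    expect_equal(sum(w * kpuuAll), targets[[nm]], tolerance = 1e-12)
    # all distribution volumes positive and finite
    expect_true(all(rt$vu > 0 & is.finite(rt$vu)))
    # insular-cortex concentration excess over the whole-section mean
    iv <- regionTruthTable(pr, "in_vivo")
    fold <- iv$concentration[iv$region == "InCx"] /
      iv$concentration[iv$region == "whole_section"]
    expect_equal(fold, folds[[nm]], tolerance = 1e-10)
  }
  # printed regional truths for risperidone
  rt <- profiles$risperidone@regionTruth
  expect_equal(rt$kpuu[rt$region == "MCx"], 0.08)
  expect_equal(rt$kpuu[rt$region == "Pir"], 0.12)
  # white matter binds less than gray in every profile
  for (pr in profiles) {
    rt <- pr@regionTruth
    expect_true(all(rt$vu[rt$region %in% c("cc", "ec", "aca")] <
                    rt$vu[rt$region == "CPu"]))
  }
})

test_that("the whole-section ratio estimand stays close to the nominal value", {
  for (pr in defaultProfiles())
    expect_equal(impliedWholeSectionKpuu(pr), pr@kpuuBrain,
                 tolerance = 0.02)
})

test_that("generation is deterministic in the seed", {
  w <- tinyWorld()
  pr <- tinyProfile()
  s1 <- generateSection(pr, "in_vivo", w$atlas, NoiseModel(), seed = 11,
                        grid = w$grid, tissue = w$tissue)
  s2 <- generateSection(pr, "in_vivo", w$atlas, NoiseModel(), seed = 11,
                        grid = w$grid, tissue = w$tissue)
  s3 <- generateSection(pr, "in_vivo", w$atlas, NoiseModel(), seed = 12,
                        grid = w$grid, tissue = w$tissue)
  expect_identical(s1@channels[[1]]@intensities,
                   s2@channels[[1]]@intensities)
  expect_identical(s1@channels[[2]]@intensities,
                   s2@channels[[2]]@intensities)
  expect_false(identical(s1@channels[[1]]@intensities,
                         s3@channels[[1]]@intensities))
})

test_that("noiseless sections invert exactly through the forward model", {
  w <- tinyWorld()
  pr <- tinyProfile()
  pm <- pixelTissueMass(w$grid)
  for (cond in c("in_vivo", "brain_slice", "control")) {
    sec <- generateSection(pr, cond, w$atlas, noiseFree(), seed = 2,
                           grid = w$grid, tissue = w$tissue)
    img <- sec@channels[[1]]@intensities
    truth <- regionTruthTable(pr, cond, w$atlas, w$tissue)
    for (lab in regionNames(w$atlas)) {
      est <- mean(img[w$atlas@regions[[lab]]]) /
        (pr@responseFactor * pm * 1e-9)
      expect_equal(est, truth$concentration[truth$region == lab],
                   tolerance = 1e-12)
    }
  }
})

test_that("in vivo to slice truth ratio reduces to Kp,uu when buffers match", {
  w <- tinyWorld()
  pr <- tinyProfile()  # cuBuffer == cuPlasma
  iv <- regionTruthTable(pr, "in_vivo", w$atlas, w$tissue)
  sl <- regionTruthTable(pr, "brain_slice", w$atlas, w$tissue)
  rt <- pr@regionTruth
  for (lab in rt$region) {
    expect_equal(iv$concentration[iv$region == lab] /
                   sl$concentration[sl$region == lab],
                 rt$kpuu[rt$region == lab], tolerance = 1e-12)
  }
})

test_that("gain fields cancel in the IS-normalized image", {
  w <- tinyWorld()
  pr <- tinyProfile()
  gainy <- NoiseModel(pixelCv = 0, gainAmplitude = 0.3, isSprayCv = 0,
                      background = 0)
  flat <- noiseFree()
  sGain <- generateSection(pr, "in_vivo", w$atlas, gainy, seed = 5,
                           grid = w$grid, tissue = w$tissue)
  sFlat <- generateSection(pr, "in_vivo", w$atlas, flat, seed = 5,
                           grid = w$grid, tissue = w$tissue)
  nGain <- normalizeToIS(sGain, "tinydrug")
  nFlat <- normalizeToIS(sFlat, "tinydrug")
  for (lab in regionNames(w$atlas)) {
    m <- w$atlas@regions[[lab]]
    expect_equal(mean(nGain$ratio[m]), mean(nFlat$ratio[m]),
                 tolerance = 1e-12)
  }
  # within a uniform-truth region the normalized image is flat: no imprint
  # of the gain field survives the ratio
  m <- w$atlas@regions[["CPu"]]
  expect_lt(stats::sd(nGain$ratio[m]) / mean(nGain$ratio[m]), 1e-10)
})

test_that("calibration sections respect linearity and placement rules", {
  w <- tinyWorld()
  pr <- tinyProfile()
  lay <- new("CalibrationLayout", spots = data.frame(
    spotId = 1:2, row = c(5, 15), col = c(18, 5),
    areaMm2 = pi * 0.1^2, concentration = c(100, 100),
    volumeNl = c(40, 80), group = "tinydrug"))
  cal <- generateCalibration(pr, lay, noiseFree(), seed = 3,
                             grid = w$grid, tissue = w$tissue)
  m1 <- spotMask(lay, 1, w$grid); m2 <- spotMask(lay, 2, w$grid)
  i1 <- mean(cal@channels[[1]]@intensities[m1])
  i2 <- mean(cal@channels[[1]]@intensities[m2])
  # doubling the spotted volume doubles the spot intensity
  expect_equal(i2 / i1, 2, tolerance = 1e-12)
  # off-spot analyte intensity is exactly background (zero here)
  off <- !(m1 | m2)
  expect_true(all(cal@channels[[1]]@intensities[off] == 0))
  # a spot overlapping an atlas region is a configuration error
  onRegion <- new("CalibrationLayout", spots = data.frame(
    spotId = 1, row = 4, col = 5, areaMm2 = pi * 0.1^2,
    concentration = 100, volumeNl = 40, group = "tinydrug"))
  expect_error(generateCalibration(pr, onRegion, noiseFree(), seed = 3,
                                   grid = w$grid, tissue = w$tissue,
                                   atlas = w$atlas),
               "configuration error")
  # default layout: six standards, all detectable above background
  atlas <- defaultAtlas()
  profile <- defaultProfiles()$risperidone
  layout <- defaultCalibrationLayout("risperidone")
  calib <- generateCalibration(profile, layout, NoiseModel(), seed = 9,
                               atlas = atlas)
  nrm <- normalizeToIS(calib, "risperidone")
  bgLevel <- mean(nrm$ratio[analysisMask(calib, layout) & nrm$valid])
  for (i in seq_len(6)) {
    m <- spotMask(layout, i, calib@grid) & nrm$valid
    expect_gt(mean(nrm$ratio[m]), 3 * bgLevel)
  }
})

test_that("bulk generation matches its stated distribution", {
  pr <- tinyProfile(cu = 100, fu = 0.5)
  # zero CV: replicates equal the truth exactly
  b <- generateBulk(pr, "plasma_total", n = 4, noiseCv = 0, seed = 1)
  expect_true(all(b$value == 100 / 0.5))
  expect_true(all(generateBulk(pr, "buffer_unbound", 3, 0, 1)$value == 100))
  # fu = 1: total plasma equals unbound plasma
  pr1 <- tinyProfile(cu = 100, fu = 1)
  expect_true(all(generateBulk(pr1, "plasma_total", 3, 0, 1)$value == 100))
  # Monte-Carlo: sample mean lands within 3 cv/sqrt(n) of truth
  b6 <- generateBulk(pr, "buffer_unbound", n = 6, noiseCv = 0.1, seed = 77)
  expect_lt(abs(mean(b6$value) - 100) / 100, 3 * 0.1 / sqrt(6))
})
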