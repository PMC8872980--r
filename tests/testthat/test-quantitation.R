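test_that("IS normalization divides out the internal standard", {
  w <- tinyWorld()
  an <- matrix(runif(20 * 24, 1, 5), 20, 24)
  isI <- matrix(4, 20, 24)
  sec <- SectionDataset(w$grid, list(
    ChannelImage("d", an, group = "d"),
    ChannelImage("d-IS", isI, group = "d", role = "internal_standard")),
    tissueMask = w$tissue, condition = "in_vivo")
  nrm <- normalizeToIS(sec, "d")
  expect_equal(nrm$ratio, an / 4, tolerance = 1e-15)
  # scaling both channels by the same field leaves the ratio unchanged
  gain <- matrix(seq(0.7, 1.3, length.out = 20 * 24), 20, 24)
  sec2 <- SectionDataset(w$grid, list(
    ChannelImage("d", an * gain, group = "d"),
    ChannelImage("d-IS", isI * gain, group = "d",
                 role = "internal_standard")),
    tissueMask = w$tissue, condition = "in_vivo")
  expect_equal(normalizeToIS(sec2, "d")$ratio, nrm$ratio,
               tolerance = 1e-12)
  # missing IS channel is a configuration error
  sec3 <- SectionDataset(w$grid, list(ChannelImage("d", an, group = "d")),
                         tissueMask = w$tissue, condition = "in_vivo")
  expect_error(normalizeToIS(sec3, "d"), "configuration error")
  # pixels under the IS floor are invalidated
  isLow <- isI; isLow[1, 1] <- 1e-6
  sec4 <- SectionDataset(w$grid, list(
    ChannelImage("d", an, group = "d"),
    ChannelImage("d-IS", isLow, group = "d",
                 role = "internal_standard")),
    tissueMask = w$tissue, condition = "in_vivo")
  nrm4 <- normalizeToIS(sec4, "d")
  expect_false(nrm4$valid[1, 1])
  expect_true(is.na(nrm4$ratio[1, 1]))
})

test_that("spot tissue-equivalent conversion reproduces the worked example", {
  g <- PixelGrid(10, 10, 100, sectionThickness = 12, tissueDensity = 1.027)
  # 25 ng/mL x 40 nL on a 1.0-mm spot of a 12-um section: about 103 ng/g
  v <- spotTissueEquivalent(25, 40, pi * 0.5^2, g)
  expect_equal(v, 103, tolerance = 0.01)
  # linear in volume, proportional in concentration
  expect_equal(spotTissueEquivalent(25, 80, pi * 0.5^2, g), 2 * v)
  expect_equal(spotTissueEquivalent(100, 40, pi * 0.5^2, g), 4 * v)
  expect_error(spotTissueEquivalent(25, 40, 0, g), "domain error")
})

test_that("calibration fitting matches exact data and a closed-form oracle", {
  conc <- c(25, 50, 100, 250, 500, 1000)
  # exact linear data
  cv <- fitCalibration(conc, 0.02 * conc, weighting = "none")
  expect_equal(cv@slope, 0.02, tolerance = 1e-12)
  expect_equal(cv@intercept, 0, tolerance = 1e-12)
  expect_equal(cv@rSquared, 1)
  expect_equal(cv@lod, 0)
  expect_equal(cv@lloq, 25)
  expect_true(cv@accepted)
  expect_error(fitCalibration(c(1, 2), c(1, 2)), "insufficient data")
  # fixed noisy points against the weighted normal equations
  y <- c(0.52, 1.03, 1.96, 5.1, 9.9, 20.3)
  for (wt in c("none", "inverse_x2")) {
    fit <- fitCalibration(conc, y, weighting = wt)
    wts <- if (wt == "inverse_x2") 1 / conc^2 else rep(1, 6)
    # oracle: solve (X'WX) b = X'Wy directly
    X <- cbind(1, conc)
    b <- solve(t(X) %*% (wts * X), t(X) %*% (wts * y))
    expect_equal(fit@intercept, b[1], tolerance = 1e-10)
    expect_equal(fit@slope, b[2], tolerance = 1e-10)
    # sigma oracle: sqrt of [ (X'WX)^-1 s2 ]_11 with s2 = RSS/(n-2)
    res <- y - X %*% b
    s2 <- sum(wts * res^2) / 4
    seInt <- sqrt(solve(t(X) %*% (wts * X))[1, 1] * s2)
    expect_equal(fit@sigmaIntercept, seInt, tolerance = 1e-10)
    expect_equal(fit@lod, 3.3 * seInt / b[2], tolerance = 1e-10)
  }
  # a negative-slope curve is rejected
  down <- fitCalibration(conc, rev(0.02 * conc), weighting = "none")
  expect_false(down@accepted)
})

test_that("region quantitation inverts the curve with flags and clipping", {
  w <- tinyWorld()
  cv <- fitCalibration(c(25, 50, 100, 250, 500, 1000),
                       0.02 * c(25, 50, 100, 250, 500, 1000))
  nrm <- list(ratio = matrix(2, 20, 24), valid = matrix(TRUE, 20, 24))
  q <- quantifyRegion(nrm, w$atlas@regions[["MCx"]], cv)
  expect_equal(q$concentration, 100)
  expect_false(q$belowLloq)
  # intensity below the intercept clips to zero and is flagged
  cv2 <- fitCalibration(c(25, 50, 100), 0.5 + 0.02 * c(25, 50, 100))
  nrmLow <- list(ratio = matrix(0.1, 20, 24), valid = matrix(TRUE, 20, 24))
  q2 <- quantifyRegion(nrmLow, w$atlas@regions[["MCx"]], cv2)
  expect_equal(q2$concentration, 0)
  expect_true(q2$belowLloq)
  expect_true(q2$clipped)
  # empty mask is degenerate
  expect_error(quantifyRegion(nrm, matrix(FALSE, 20, 24), cv),
               "degenerate")
  # monotonicity: higher mean intensity, higher concentration
  lvls <- seq(0.5, 4, by = 0.5)
  concs <- vapply(lvls, function(v)
    quantifyRegion(list(ratio = matrix(v, 20, 24),
                        valid = matrix(TRUE, 20, 24)),
                   w$atlas@regions[["MCx"]], cv)$concentration, numeric(1))
  expect_true(all(diff(concs) > 0))
})

test_that("zero-noise quantitation is the exact inverse of the generator", {
  w <- tinyWorld()
  pr <- tinyProfile()
  lay <- new("CalibrationLayout", spots = data.frame(
    spotId = 1:3, row = c(5, 10, 15), col = c(18, 20, 5),
    areaMm2 = pi * 0.1^2, concentration = c(50, 200, 800),
    volumeNl = 40, group = "tinydrug"))
  cal <- generateCalibration(pr, lay, noiseFree(), seed = 3,
                             grid = w$grid, tissue = w$tissue)
  curve <- calibrateSection(cal, lay, "tinydrug")
  for (cond in c("in_vivo", "brain_slice")) {
    sec <- generateSection(pr, cond, w$atlas, noiseFree(), seed = 4,
                           grid = w$grid, tissue = w$tissue)
    q <- quantifySection(sec, w$atlas, curve, "tinydrug")
    truth <- regionTruthTable(pr, cond, w$atlas, w$tissue)
    for (lab in c(regionNames(w$atlas), "background", "whole_section")) {
      expect_equal(q$concentration[q$region == lab],
                   truth$concentration[truth$region == lab],
                   tolerance = 1e-6)
    }
  }
})

test_that("whole-section value conserves the pixel-weighted region means", {
  w <- tinyWorld()
  pr <- tinyProfile()
  sec <- generateSection(pr, "in_vivo", w$atlas, NoiseModel(), seed = 6,
                         grid = w$grid, tissue = w$tissue)
  lay <- new("CalibrationLayout", spots = data.frame(
    spotId = 1:3, row = c(5, 10, 15), col = c(18, 20, 5),
    areaMm2 = pi * 0.1^2, concentration = c(50, 200, 800),
    volumeNl = 40, group = "tinydrug"))
  cal <- generateCalibration(pr, lay, noiseFree(), seed = 3,
                             grid = w$grid, tissue = w$tissue)
  curve <- calibrateSection(cal, lay, "tinydrug")
  q <- quantifySection(sec, w$atlas, curve, "tinydrug")
  parts <- q[q$region %in% c(regionNames(w$atlas), "background"), ]
  weighted <- sum(parts$concentration * parts$nPixels) / sum(parts$nPixels)
  expect_equal(q$concentration[q$region == "whole_section"], weighted,
               tolerance = 1e-10)
})

test_that("QC evaluation computes bias and RSD with pass/fail flags", {
  r <- qcEvaluate(c(100, 100, 100), 100)
  expect_equal(r$biasPct, 0)
  expect_equal(r$rsdPct, 0)
  expect_true(r$pass)
  r2 <- qcEvaluate(c(80, 80, 80), 100)
  expect_equal(r2$biasPct, -20)
  expect_false(r2$accuracyPass)
  expect_false(r2$pass)
  r3 <- qcEvaluate(c(90, 100, 110), 100)
  expect_equal(r3$rsdPct, 10, tolerance = 1e-12)
  expect_error(qcEvaluate(c(90, 100), 0), "domain error")
  expect_error(qcEvaluate(100, 100), "insufficient")
})
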