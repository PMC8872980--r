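test_that("pixel tissue mass follows geometry and density", {
  g <- PixelGrid(10, 10, rasterStep = 100, sectionThickness = 12,
                 tissueDensity = 1.027)
  # (0.01 cm)^2 x 0.0012 cm x 1.027 g/cm3
  expect_equal(pixelTissueMass(g), 1.2324e-7, tolerance = 1e-12)
  # unit-cancellation case
  g2 <- PixelGrid(10, 10, 100, sectionThickness = 10, tissueDensity = 1)
  expect_equal(pixelTissueMass(g2), 1e-7, tolerance = 1e-12)
  # quadratic scaling in the raster step
  g20 <- PixelGrid(10, 10, 20)
  g100 <- PixelGrid(10, 10, 100)
  expect_equal(pixelTissueMass(g20) / pixelTissueMass(g100), (20 / 100)^2)
  # strictly increasing in every factor
  base <- pixelTissueMass(PixelGrid(5, 5, 50, 10, 1))
  expect_gt(pixelTissueMass(PixelGrid(5, 5, 60, 10, 1)), base)
  expect_gt(pixelTissueMass(PixelGrid(5, 5, 50, 12, 1)), base)
  expect_gt(pixelTissueMass(PixelGrid(5, 5, 50, 10, 1.1)), base)
})

test_that("grid and channel invariants are enforced", {
  expect_error(PixelGrid(0, 10, 100), "positive")
  expect_error(PixelGrid(10, 10, -5), "positive")
  w <- tinyWorld()
  bad <- matrix(-1, 20, 24)
  expect_error(ChannelImage("x", bad), "non-negative")
  # channel shape must match the grid
  ok <- ChannelImage("x", matrix(1, 19, 24))
  expect_error(SectionDataset(w$grid, list(ok), tissueMask = w$tissue),
               "shape")
  # one internal standard per group
  a <- ChannelImage("d", matrix(1, 20, 24), group = "d")
  i1 <- ChannelImage("d-IS", matrix(1, 20, 24), group = "d",
                     role = "internal_standard")
  i2 <- ChannelImage("d-IS2", matrix(1, 20, 24), group = "d",
                     role = "internal_standard")
  expect_error(SectionDataset(w$grid, list(a, i1, i2),
                              tissueMask = w$tissue),
               "internal_standard")
})

test_that("section save/load round trip is lossless", {
  w <- tinyWorld()
  pr <- tinyProfile()
  sec <- generateSection(pr, "in_vivo", w$atlas, NoiseModel(), seed = 7,
                         grid = w$grid, tissue = w$tissue,
                         subjectId = "a3", replicateId = "r2")
  dir <- withr::local_tempdir()
  saveSection(sec, dir)
  back <- loadSection(dir)
  expect_identical(back@grid, sec@grid)
  expect_identical(back@condition, sec@condition)
  expect_identical(back@subjectId, sec@subjectId)
  expect_identical(back@replicateId, sec@replicateId)
  expect_identical(back@tissueMask, sec@tissueMask)
  expect_identical(names(back@channels), names(sec@channels))
  for (nm in names(sec@channels)) {
    expect_identical(back@channels[[nm]]@intensities,
                     sec@channels[[nm]]@intensities)
    expect_identical(back@channels[[nm]]@role, sec@channels[[nm]]@role)
  }
})

test_that("load rejects shape mismatches and negative intensities", {
  w <- tinyWorld()
  sec <- generateSection(tinyProfile(), "control", w$atlas, noiseFree(),
                         seed = 1, grid = w$grid, tissue = w$tissue)
  dir <- withr::local_tempdir()
  saveSection(sec, dir)
  # tamper with the declared grid: 20x24 -> 20x23
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  man$grid$nCols <- 23L
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(loadSection(dir), "structural error")
  # restore shape, inject a negative intensity
  man$grid$nCols <- 24L
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  arr <- matrix(-1, 20, 24)
  con <- file(file.path(dir, "channel_01.bin"), "wb")
  writeBin(as.vector(arr), con, size = 8, endian = "little")
  close(con)
  expect_error(loadSection(dir), "validation error")
})

test_that("analysis mask excludes spots and detects degenerate masks", {
  w <- tinyWorld()
  sec <- generateSection(tinyProfile(), "control", w$atlas, noiseFree(),
                         seed = 1, grid = w$grid, tissue = w$tissue)
  # no spots: identical to tissue
  expect_identical(analysisMask(sec), sec@tissueMask)
  # one small spot: pixel count drops by the (dilated) disc size
  lay <- new("CalibrationLayout", spots = data.frame(
    spotId = 1, row = 10, col = 12, areaMm2 = pi * 0.05^2,
    concentration = 25, volumeNl = 40, group = "tinydrug"))
  m <- analysisMask(sec, lay, dilatePx = 0)
  expect_lt(sum(m), sum(sec@tissueMask))
  expect_true(all(m | !sec@tissueMask | spotMask(lay, 1, w$grid)))
  # spot tiling the whole tissue: degenerate
  big <- new("CalibrationLayout", spots = data.frame(
    spotId = 1, row = 10, col = 12, areaMm2 = 50,
    concentration = 25, volumeNl = 40, group = "tinydrug"))
  expect_error(analysisMask(sec, big), "degenerate")
})

test_that("atlas disjointness is enforced on construction and on load", {
  nr <- 10; nc <- 10
  a <- matrix(FALSE, nr, nc); a[1:4, 1:4] <- TRUE
  b <- matrix(FALSE, nr, nc); b[4:6, 4:6] <- TRUE  # overlaps at (4,4)
  expect_error(RegionAtlas(list(MCx = a, CPu = b)), "disjoint")
  expect_error(RegionAtlas(list(foo = a)), "vocabulary")
  b2 <- matrix(FALSE, nr, nc); b2[5:6, 5:6] <- TRUE
  atlas <- RegionAtlas(list(MCx = a, CPu = b2))
  dir <- withr::local_tempdir()
  saveAtlas(atlas, dir)
  back <- loadAtlas(dir)
  expect_identical(back@regions, atlas@regions)
  # corrupt one stored mask into an overlap; load must fail validity
  con <- file(file.path(dir, "region_02.bin"), "wb")
  writeBin(as.integer(a), con, size = 1)
  close(con)
  expect_error(loadAtlas(dir), "disjoint")
})

test_that("default atlas is disjoint, in-tissue, and fully covered by truth", {
  atlas <- defaultAtlas()
  tissue <- defaultTissueMask()
  overlap <- Reduce(`+`, atlas@regions)
  expect_lte(max(overlap), 1)
  expect_true(all(!(overlap > 0 & !tissue)))
  expect_setequal(regionNames(atlas), regionVocabulary())
  w <- regionAreaWeights(atlas)
  expect_equal(sum(w), 1)
  expect_true(w[["background"]] > 0.5)
})

test_that("imzML ingestion sums the per-channel m/z window", {
  # three pixels in a row; two channels 50 mDa apart
  mz <- c(411.2000, 411.2196, 411.2200, 411.2204, 411.2700, 411.2707)
  sp <- list(
    list(x = 1, y = 1, mz = mz, intensity = c(5, 1, 2, 3, 10, 20)),
    list(x = 2, y = 1, mz = mz, intensity = c(0, 4, 4, 4, 1, 2)),
    list(x = 3, y = 1, mz = mz, intensity = c(9, 0, 7, 0, 0, 5)))
  chans <- data.frame(
    analyteId = c("drug", "drug-IS"), group = "drug",
    role = c("analyte", "internal_standard"),
    mz = c(411.2200, 411.2705))
  path <- file.path(withr::local_tempdir(), "t.imzML")
  writeTestImzML(path, sp, continuous = TRUE)
  ds <- readImzML(path, chans, tissueMask = matrix(TRUE, 1, 3))
  # brute-force oracle: sum intensities with |mz - target| <= window/2
  oracle <- function(s, target, win) sum(s$intensity[abs(s$mz - target) <= win / 2])
  for (j in 1:3) {
    expect_equal(ds@channels[["drug"]]@intensities[1, j],
                 oracle(sp[[j]], 411.2200, 0.001))
    expect_equal(ds@channels[["drug-IS"]]@intensities[1, j],
                 oracle(sp[[j]], 411.2705, 0.0015))
  }
  # the analyte window (1 mDa full width) must exclude the 411.2000 peak
  expect_equal(ds@channels[["drug"]]@intensities[1, 1], 1 + 2 + 3)

  # processed mode with per-spectrum axes gives the same images here
  path2 <- file.path(withr::local_tempdir(), "p.imzML")
  writeTestImzML(path2, sp, continuous = FALSE)
  ds2 <- readImzML(path2, chans, tissueMask = matrix(TRUE, 1, 3))
  expect_identical(ds2@channels[["drug"]]@intensities,
                   ds@channels[["drug"]]@intensities)

  # missing ibd companion is a structural error
  file.remove(sub("imzML$", "ibd", path2))
  expect_error(readImzML(path2, chans), "structural error")
})

test_that("bulk sample tables are validated on read", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bulk.csv")
  write.csv(data.frame(matrix = "plasma_total", value = 100,
                       replicateId = "r1"), f, row.names = FALSE)
  expect_equal(readBulkSamples(f)$value, 100)
  write.csv(data.frame(matrix = "weird", value = 100, replicateId = "r1"),
            f, row.names = FALSE)
  expect_error(readBulkSamples(f), "matrix kind")
  write.csv(data.frame(matrix = "plasma_total", value = -5,
                       replicateId = "r1"), f, row.names = FALSE)
  expect_error(readBulkSamples(f), "negative")
})
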