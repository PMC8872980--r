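# ---- internal dataset format: flat binary arrays + a JSON manifest ----
# Little-endian float64 for intensities, uint8 for masks; the manifest
# declares the grid so shape errors are caught on load. Binary round-trips
# are bit-exact, which the save/load identity tests rely on.

.writeArray <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 8, endian = "little")
}

.readArray <- function(path, nRows, nCols) {
  expect <- nRows * nCols
  sz <- file.info(path)$size
  if (is.na(sz) || sz != expect * 8)
    stop("structural error: '", basename(path), "' holds ", sz %/% 8,
         " values but the manifest declares a ", nRows, " x ", nCols,
         " grid", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  matrix(readBin(con, "double", n = expect, size = 8, endian = "little"),
         nRows, nCols)
}

.writeMask <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(x)), con, size = 1)
}

.readMask <- function(path, nRows, nCols) {
  expect <- nRows * nCols
  sz <- file.info(path)$size
  if (is.na(sz) || sz != expect)
    stop("structural error: mask '", basename(path),
         "' does not match the declared grid", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  matrix(readBin(con, "integer", n = expect, size = 1) > 0, nRows, nCols)
}

#' Save a SectionDataset to a directory
#'
#' Writes a JSON manifest plus one flat little-endian binary array per
#' channel and the tissue mask. The round trip through
#' \code{\link{loadSection}} is lossless.
#'
#' @param section a \linkS4class{SectionDataset}.
#' @param dir target directory (created if needed).
#' @return invisibly, the directory.
#' @export
saveSection <- function(section, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- section@grid
  chans <- lapply(seq_along(section@channels), function(i) {
    ch <- section@channels[[i]]
    fn <- sprintf("channel_%02d.bin", i)
    .writeArray(ch@intensities, file.path(dir, fn))
    list(analyteId = ch@analyteId, group = ch@group, role = ch@role,
         file = fn)
  })
  .writeMask(section@tissueMask, file.path(dir, "tissue_mask.bin"))
  manifest <- list(
    format = "msiKpuu-section-v1",
    grid = list(nRows = g@nRows, nCols = g@nCols, rasterStep = g@rasterStep,
                sectionThickness = g@sectionThickness,
                tissueDensity = g@tissueDensity),
    condition = section@condition, subjectId = section@subjectId,
    replicateId = section@replicateId,
    channels = chans, tissueMask = "tissue_mask.bin")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a SectionDataset from a directory
#'
#' Validates the manifest against the stored arrays: a size inconsistent
#' with the declared grid is a structural error, negative intensities a
#' validation error. Channels the caller does not recognise are preserved.
#'
#' @param dir directory written by \code{\link{saveSection}}.
#' @return a \linkS4class{SectionDataset}.
#' @export
loadSection <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop("structural error: no manifest.json in '", dir, "'", call. = FALSE)
  man <- jsonlite::read_json(mf, simplifyVector = FALSE)
  g <- man$grid
  grid <- PixelGrid(g$nRows, g$nCols, g$rasterStep, g$sectionThickness,
                    g$tissueDensity)
  channels <- lapply(man$channels, function(ch) {
    arr <- .readArray(file.path(dir, ch$file), grid@nRows, grid@nCols)
    if (any(arr < 0))
      stop("validation error: negative intensities in channel '",
           ch$analyteId, "'", call. = FALSE)
    ChannelImage(ch$analyteId, arr, group = ch$group, role = ch$role)
  })
  mask <- .readMask(file.path(dir, man$tissueMask), grid@nRows, grid@nCols)
  SectionDataset(grid, channels, tissueMask = mask,
                 condition = man$condition, subjectId = man$subjectId,
                 replicateId = man$replicateId)
}

#' Save / load a RegionAtlas
#'
#' Same manifest-plus-binary layout as sections; disjointness is re-checked
#' on load through the class validity.
#'
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param dir directory.
#' @return \code{saveAtlas}: invisibly the directory; \code{loadAtlas}: the
#'   atlas.
#' @export
saveAtlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(atlas@regions[[1]])
  regs <- lapply(seq_along(atlas@regions), function(i) {
    fn <- sprintf("region_%02d.bin", i)
    .writeMask(atlas@regions[[i]], file.path(dir, fn))
    list(label = names(atlas@regions)[i], file = fn)
  })
  jsonlite::write_json(
    list(format = "msiKpuu-atlas-v1", nRows = d[1], nCols = d[2],
         vocabulary = atlas@vocabulary, regions = regs),
    file.path(dir, "atlas.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveAtlas
#' @export
loadAtlas <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "atlas.json"),
                             simplifyVector = FALSE)
  regions <- lapply(man$regions, function(r)
    .readMask(file.path(dir, r$file), man$nRows, man$nCols))
  names(regions) <- vapply(man$regions, `[[`, character(1), "label")
  RegionAtlas(regions, vocabulary = unlist(man$vocabulary))
}

#' Read bulk sample tables
#'
#' CSV with columns matrix (plasma_total, buffer_unbound or
#' brain_homogenate_total), value and replicateId.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
readBulkSamples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("matrix", "value", "replicateId")
  if (!all(need %in% names(df)))
    stop("bulk table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ok <- c("plasma_total", "buffer_unbound", "brain_homogenate_total")
  if (!all(df$matrix %in% ok))
    stop("validation error: unknown bulk matrix kind", call. = FALSE)
  if (any(df$value < 0))
    stop("validation error: negative bulk concentrations", call. = FALSE)
  df
}
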