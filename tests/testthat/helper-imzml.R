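# Programmatic writer of a minimal imzML/ibd pair for reader tests.
# Spectra are supplied as list(x=, y=, mz=, intensity=); in continuous mode
# all spectra share the first spectrum's m/z axis.

writeTestImzML <- function(path, spectra, continuous = TRUE) {
  ibdPath <- sub("\\.imzML$", ".ibd", path)
  con <- file(ibdPath, "wb")
  writeBin(as.raw(rep(0, 16)), con)  # UUID placeholder
  offset <- 16
  locs <- list()
  sharedMz <- NULL
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (continuous) {
      if (is.null(sharedMz)) {
        writeBin(as.numeric(sp$mz), con, size = 8, endian = "little")
        sharedMz <- list(offset = offset, n = length(sp$mz))
        offset <- offset + 8 * length(sp$mz)
      }
      mzLoc <- sharedMz
    } else {
      writeBin(as.numeric(sp$mz), con, size = 8, endian = "little")
      mzLoc <- list(offset = offset, n = length(sp$mz))
      offset <- offset + 8 * length(sp$mz)
    }
    writeBin(as.numeric(sp$intensity), con, size = 8, endian = "little")
    locs[[i]] <- list(mz = mzLoc,
                      int = list(offset = offset, n = length(sp$intensity)))
    offset <- offset + 8 * length(sp$intensity)
  }
  close(con)

  mode <- if (continuous) "IMS:1000030" else "IMS:1000031"
  spec <- vapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]; lc <- locs[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray><referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray><referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, sp$x, sp$y, lc$mz$offset, lc$mz$n, lc$int$offset, lc$int$n)
  }, character(1))

  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="%s" name="mode"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<run id="r1"><spectrumList count="%d">%s</spectrumList></run>',
    '</mzML>'),
    mode, length(spectra), paste(spec, collapse = ""))
  writeLines(xml, path)
  invisible(path)
}
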