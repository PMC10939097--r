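# imzML input/output.
#
# imzML stores metadata as mzML-dialect XML and the numeric arrays in a
# companion .ibd binary file whose first 16 bytes repeat the dataset UUID.
# Per-spectrum cvParams carry the external offset / array length / encoded
# length of each array. Both the "continuous" dialect (shared m/z axis) and
# the "processed" dialect (per-pixel arrays) are read; files are written in
# the processed dialect with 64-bit m/z and 32-bit intensities, the layout
# other imzML tooling emits by default.

ibdPath <- function(path) {
  p <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(p, path)) paste0(path, ".ibd") else p
}

#' Read an imzML/ibd dataset
#'
#' Loads every pixel of an imzML file (continuous or processed dialect)
#' into an [MSIDataset-class]. imzML 1-based scan positions are shifted to
#' the package's 0-based raster convention. Polarity, spectrum mode and
#' pixel size are taken from the file metadata when present.
#'
#' @param path path to the `.imzML` file; the companion `.ibd` must sit
#'   next to it.
#' @param pixelSizeUm fallback pixel spacing (micrometres) when the file
#'   does not declare one.
#' @return An [MSIDataset-class].
#' @seealso [writeImzML()]
#' @export
readImzML <- function(path, pixelSizeUm = 50) {
  if (!file.exists(path)) stop("imzML file not found: ", path)
  ibd <- ibdPath(path)
  if (!file.exists(ibd)) stop("missing companion ibd file: ", ibd)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed imzML XML: ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)

  acc <- function(node, accession) {
    xml2::xml_find_first(node,
      sprintf(".//cvParam[@accession='%s']", accession))
  }
  hasAcc <- function(node, accession) !inherits(acc(node, accession),
                                                "xml_missing")

  ## data type per referenceable param group
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  dtypes <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    size <- if (hasAcc(g, "MS:1000523")) 8L         # 64-bit float
            else if (hasAcc(g, "MS:1000521")) 4L    # 32-bit float
            else NA_integer_
    dtypes[[id]] <- size
  }

  fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  polarity <- if (hasAcc(doc, "MS:1000129")) "negative" else "positive"
  mode <- if (hasAcc(fc, "MS:1000128")) "profile" else "centroid"

  px <- acc(doc, "IMS:1000046")  # pixel size x
  if (!inherits(px, "xml_missing")) {
    v <- suppressWarnings(as.numeric(xml2::xml_attr(px, "value")))
    if (is.finite(v) && v > 0) pixelSizeUm <- v
  }

  specNodes <- xml2::xml_find_all(doc, ".//run/spectrumList/spectrum")
  if (!length(specNodes)) stop("imzML file contains no spectra")

  ibdSize <- file.info(ibd)$size
  con <- file(ibd, "rb")
  on.exit(close(con))

  readArray <- function(bda, i) {
    ref <- xml2::xml_attr(
      xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref")
    size <- dtypes[[ref]]
    if (is.na(size))
      stop("unsupported binary data type in array group '", ref, "'")
    val <- function(a) as.numeric(xml2::xml_attr(acc(bda, a), "value"))
    len <- val("IMS:1000103")
    off <- val("IMS:1000102")
    enc <- val("IMS:1000104")
    if (any(!is.finite(c(len, off, enc))))
      stop("pixel ", i, ": missing external offset/length cvParams")
    if (!is.na(enc) && enc != len * size)
      stop("pixel ", i, ": inconsistent encoded length")
    if (off + len * size > ibdSize)
      stop("pixel ", i, ": ibd truncated (need ", off + len * size,
           " bytes, file has ", ibdSize, ")")
    seek(con, where = off, origin = "start")
    readBin(con, what = "double", n = len, size = size, endian = "little")
  }

  n <- length(specNodes)
  spectraList <- vector("list", n)
  coords <- matrix(NA_integer_, n, 2L, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(n)) {
    sn <- specNodes[[i]]
    posx <- as.integer(xml2::xml_attr(acc(sn, "IMS:1000050"), "value"))
    posy <- as.integer(xml2::xml_attr(acc(sn, "IMS:1000051"), "value"))
    if (is.na(posx) || is.na(posy))
      stop("pixel ", i, ": missing scan position")
    bdas <- xml2::xml_find_all(sn, ".//binaryDataArray")
    mzNode <- intNode <- NULL
    for (b in bdas) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(b, "./referenceableParamGroupRef"), "ref")
      if (grepl("mz", ref, ignore.case = TRUE)) mzNode <- b else intNode <- b
    }
    if (is.null(mzNode) || is.null(intNode))
      stop("pixel ", i, ": could not identify m/z and intensity arrays")
    mz <- readArray(mzNode, i)
    int <- readArray(intNode, i)
    if (length(mz) != length(int))
      stop("pixel ", i, ": m/z and intensity array lengths differ (",
           length(mz), " vs ", length(int), ")")
    int[int < 0] <- 0  # guard against float32 round-off
    spectraList[[i]] <- Spectrum(mz, int, mode = mode)
    coords[i, ] <- c(posx - 1L, posy - 1L)  # imzML is 1-based
  }
  MSIDataset(spectraList, coords, pixelSizeUm = pixelSizeUm,
             polarity = polarity)
}

## Deterministic pseudo-UUID derived from the dataset content (no RNG draw,
## so writing a file never perturbs downstream seeded analyses).
contentUUID <- function(ds) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  sizes <- vapply(ds@spectra, function(s) length(s@mz), integer(1))
  tot <- vapply(ds@spectra, function(s) sum(s@intensity), numeric(1))
  writeBin(c(as.numeric(sizes), tot, as.numeric(ds@coords)), tmp)
  hex <- unname(tools::md5sum(tmp))
  as.raw(strtoi(substring(hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

formatUUID <- function(bytes) {
  h <- toupper(paste(format(bytes), collapse = ""))
  sprintf("{%s-%s-%s-%s-%s}", substr(h, 1, 8), substr(h, 9, 12),
          substr(h, 13, 16), substr(h, 17, 20), substr(h, 21, 32))
}

#' Write an MSIDataset to imzML/ibd
#'
#' Emits a processed-dialect imzML file (per-pixel m/z and intensity
#' arrays; m/z as 64-bit, intensities as 32-bit floats) plus the companion
#' `.ibd`. The result round-trips through [readImzML()] up to float32
#' intensity storage precision.
#'
#' @param ds a valid, non-empty [MSIDataset-class].
#' @param path output `.imzML` path.
#' @return `path`, invisibly.
#' @export
writeImzML <- function(ds, path) {
  validObject(ds)
  if (!length(ds@spectra)) stop("nothing to write: dataset has no spectra")
  ibd <- ibdPath(path)
  uuid <- contentUUID(ds)

  con <- file(ibd, "wb")
  writeBin(uuid, con)
  offset <- 16
  n <- length(ds@spectra)
  offs <- matrix(0, n, 4L)  # mz offset, mz len, int offset, int len
  for (i in seq_len(n)) {
    s <- ds@spectra[[i]]
    L <- length(s@mz)
    writeBin(as.numeric(s@mz), con, size = 8, endian = "little")
    offs[i, 1:2] <- c(offset, L)
    offset <- offset + 8 * L
    writeBin(as.numeric(s@intensity), con, size = 4, endian = "little")
    offs[i, 3:4] <- c(offset, L)
    offset <- offset + 4 * L
  }
  close(con)
  md5 <- toupper(unname(tools::md5sum(ibd)))

  mode <- ds@spectra[[1]]@mode
  modeParam <- if (mode == "profile")
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  polParam <- if (ds@polarity == "positive")
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'

  maxx <- max(ds@coords[, "x"]) + 1L
  maxy <- max(ds@coords[, "y"]) + 1L

  head <- sprintf(
'<?xml version="1.0" encoding="ISO-8859-1"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
  <cvList count="3">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" uri="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" uri="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>
    <cv id="IMS" fullName="Imaging MS Ontology" uri="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
      %s
      <cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>
      <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>
    </fileContent>
  </fileDescription>
  <referenceableParamGroupList count="3">
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="spectrum1">
      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
      %s
      %s
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <softwareList count="1">
    <software id="fiberMSI" version="0.1.0">
      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="fiberMSI exporter"/>
    </software>
  </softwareList>
  <scanSettingsList count="1">
    <scanSettings id="scanSettings1">
      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%g"/>
      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g"/>
    </scanSettings>
  </scanSettingsList>
  <instrumentConfigurationList count="1">
    <instrumentConfiguration id="IC1">
    </instrumentConfiguration>
  </instrumentConfigurationList>
  <dataProcessingList count="1">
    <dataProcessing id="export">
      <processingMethod order="0" softwareRef="fiberMSI">
        <cvParam cvRef="MS" accession="MS:1000530" name="file format conversion" value="Output to imzML"/>
      </processingMethod>
    </dataProcessing>
  </dataProcessingList>
  <run defaultInstrumentConfigurationRef="IC1" id="run1">
    <spectrumList count="%d" defaultDataProcessingRef="export">',
    modeParam, formatUUID(uuid), md5, modeParam, polParam,
    maxx, maxy, ds@pixelSizeUm, ds@pixelSizeUm, n)

  specChunks <- vapply(seq_len(n), function(i) {
    sprintf(
'      <spectrum defaultArrayLength="0" id="spectrum=%d" index="%d">
        <referenceableParamGroupRef ref="spectrum1"/>
        <scanList count="1">
          <cvParam cvRef="MS" accession="MS:1000795" name="no combination"/>
          <scan instrumentConfigurationRef="IC1">
            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>',
      i, i, ds@coords[i, "x"] + 1L, ds@coords[i, "y"] + 1L,
      offs[i, 2], offs[i, 2] * 8, offs[i, 1],
      offs[i, 4], offs[i, 4] * 4, offs[i, 3])
  }, character(1))

  tail <- '    </spectrumList>\n  </run>\n</mzML>\n'
  writeLines(c(head, specChunks, tail), path)
  invisible(path)
}
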