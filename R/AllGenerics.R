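#' Accessor generics
#'
#' Accessors for the package's S4 containers: `featureMz()` returns the
#' consensus feature m/z vector, `pixelCoords()` the 0-based pixel
#' coordinate matrix, `intensityMatrix()` the feature x pixel (or feature
#' x sample) intensity matrix, `normalization()` the normalization tag,
#' `spectra()` the list of per-pixel spectra, and `labelMatrix()` the
#' integer label grid.
#'
#' @param x an object of the documented class.
#' @return The slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureMz", function(x) standardGeneric("featureMz"))

#' @rdname accessors
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname accessors
#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))

#' @rdname accessors
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setMethod("featureMz", "PeakTable",
          function(x) SummarizedExperiment::rowData(x)$mz)

#' @rdname accessors
#' @export
setMethod("pixelCoords", "PeakTable", function(x) {
  cd <- SummarizedExperiment::colData(x)
  cbind(x = as.integer(cd$x), y = as.integer(cd$y))
})

#' @rdname accessors
#' @export
setMethod("pixelCoords", "MSIDataset", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("intensityMatrix", "PeakTable",
          function(x) SummarizedExperiment::assay(x, "intensity"))

#' @rdname accessors
#' @export
setMethod("intensityMatrix", "LCMSTable", function(x) x@intensities)

#' @rdname accessors
#' @export
setMethod("normalization", "PeakTable",
          function(x) S4Vectors::metadata(x)$normalization)

#' @rdname accessors
#' @export
setMethod("spectra", "MSIDataset", function(x) x@spectra)

#' @rdname accessors
#' @export
setMethod("labelMatrix", "ROILabelMap", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("labelMatrix", "SegmentationResult", function(x) x@labels@labels)
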