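#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Single mass spectrum
#'
#' One pixel's mass spectrum: a strictly increasing m/z axis with
#' non-negative intensities, in either profile (densely sampled peak
#' shapes) or centroid (stick) representation.
#'
#' @slot mz numeric, strictly increasing m/z values in Da.
#' @slot intensity numeric, non-negative abundances (arbitrary units).
#' @slot mode character, `"profile"` or `"centroid"`.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(mz = "numeric", intensity = "numeric", mode = "character"),
  prototype(mode = "profile"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have the same length")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz must be strictly increasing")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensity must be non-negative")
  if (length(object@mode) != 1L || !object@mode %in% c("profile", "centroid"))
    msg <- c(msg, "mode must be 'profile' or 'centroid'")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param mz strictly increasing m/z values (Da).
#' @param intensity non-negative intensities, same length as `mz`.
#' @param mode `"profile"` or `"centroid"`.
#' @return A [Spectrum-class] object.
#' @examples
#' Spectrum(c(100, 200, 300), c(1, 5, 2), mode = "centroid")
#' @export
Spectrum <- function(mz, intensity, mode = c("profile", "centroid")) {
  mode <- match.arg(mode)
  new("Spectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
      mode = mode)
}

#' MSI datacube: spectra on a 2-D pixel grid
#'
#' The raw dataset: one [Spectrum-class] per occupied pixel, with 0-based
#' `(x, y)` pixel indices (origin top-left, x = column), physical pixel
#' spacing and acquisition polarity. Missing pixels (sparse acquisitions)
#' are simply absent and render as `NA` in ion images.
#'
#' @slot spectra list of [Spectrum-class] objects.
#' @slot coords integer matrix with columns `x`, `y`; one row per spectrum.
#' @slot pixelSizeUm numeric, pixel spacing in micrometres.
#' @slot polarity `"positive"` or `"negative"`.
#' @slot metadata free-form list.
#' @exportClass MSIDataset
setClass("MSIDataset",
  representation(spectra = "list", coords = "matrix",
                 pixelSizeUm = "numeric", polarity = "character",
                 metadata = "list"),
  prototype(pixelSizeUm = 50, polarity = "positive", metadata = list()))

setValidity("MSIDataset", function(object) {
  msg <- character()
  if (length(object@spectra) != nrow(object@coords))
    msg <- c(msg, "one coordinate row per spectrum required")
  if (!all(c("x", "y") %in% colnames(object@coords)))
    msg <- c(msg, "coords must have columns x and y")
  else {
    if (anyDuplicated(object@coords))
      msg <- c(msg, "duplicate pixel coordinates")
    if (nrow(object@coords) && any(object@coords < 0))
      msg <- c(msg, "coords must be 0-based non-negative")
  }
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (!object@polarity %in% c("positive", "negative"))
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
    msg <- c(msg, "spectra must all be Spectrum objects")
  if (length(msg)) msg else TRUE
})

#' Construct an MSIDataset
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param coords matrix/data.frame of 0-based pixel indices (columns x, y).
#' @param pixelSizeUm pixel spacing in micrometres.
#' @param polarity acquisition polarity.
#' @param metadata free-form list.
#' @return An [MSIDataset-class].
#' @export
MSIDataset <- function(spectra, coords, pixelSizeUm = 50,
                       polarity = c("positive", "negative"),
                       metadata = list()) {
  polarity <- match.arg(polarity)
  new("MSIDataset", spectra = spectra, coords = asCoords(coords),
      pixelSizeUm = pixelSizeUm, polarity = polarity, metadata = metadata)
}

#' Consensus peak table (feature x pixel intensity matrix)
#'
#' The processed datacube all statistics operate on. Extends
#' \linkS4class{SummarizedExperiment}: rows are consensus m/z features
#' (`rowData(x)$mz`), columns are pixels (`colData(x)$x`, `colData(x)$y`,
#' 0-based). `metadata(x)$normalization` is `"none"` or `"rms"`; with
#' `"rms"` every pixel column has root-mean-square 1 over its picked
#' (nonzero) features.
#'
#' @exportClass PeakTable
setClass("PeakTable", contains = "SummarizedExperiment")

setValidity("PeakTable", function(object) {
  msg <- character()
  mz <- SummarizedExperiment::rowData(object)$mz
  if (is.null(mz))
    return("rowData must contain an 'mz' column")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    msg <- c(msg, "feature m/z must be strictly increasing")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("x", "y") %in% colnames(cd)))
    msg <- c(msg, "colData must contain pixel coordinates x and y")
  a <- SummarizedExperiment::assay(object)
  if (any(a < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative")
  norm <- S4Vectors::metadata(object)$normalization
  if (is.null(norm) || !norm %in% c("none", "rms"))
    msg <- c(msg, "metadata normalization must be 'none' or 'rms'")
  else if (norm == "rms" && ncol(a)) {
    rms <- apply(a, 2L, function(v) {
      nz <- v[v > 0]
      if (!length(nz)) return(1)
      sqrt(mean(nz^2))
    })
    if (any(abs(rms - 1) > 1e-6))
      msg <- c(msg, "rms-normalized columns must have RMS 1 over picked features")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakTable
#'
#' @param featureMz sorted consensus feature m/z centers (Da).
#' @param intensities feature x pixel matrix of non-negative intensities.
#' @param coords 0-based pixel coordinates (columns x, y), one row per
#'   matrix column.
#' @param normalization `"none"` or `"rms"`.
#' @return A [PeakTable-class].
#' @examples
#' pt <- PeakTable(c(150.05, 400.1), matrix(1:4, 2), cbind(x = 0:1, y = 0L))
#' featureMz(pt)
#' @export
PeakTable <- function(featureMz, intensities, coords,
                      normalization = c("none", "rms")) {
  normalization <- match.arg(normalization)
  intensities <- as.matrix(intensities)
  coords <- asCoords(coords)
  rownames(intensities) <- sprintf("mz_%.4f", featureMz)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = S4Vectors::DataFrame(mz = as.numeric(featureMz)),
    colData = S4Vectors::DataFrame(x = coords[, "x"], y = coords[, "y"]),
    metadata = list(normalization = normalization))
  new("PeakTable", se)
}

#' Ion image of a single feature
#'
#' 2-D intensity map over the bounding pixel grid; unoccupied pixels are
#' `NA`.
#'
#' @slot values numeric matrix (rows = y, cols = x).
#' @slot featureMz numeric, the imaged feature's m/z.
#' @slot tolPpm numeric, tolerance used to select the feature.
#' @exportClass IonImage
setClass("IonImage",
  representation(values = "matrix", featureMz = "numeric", tolPpm = "numeric"))

setValidity("IonImage", function(object) {
  v <- object@values
  if (any(v < 0, na.rm = TRUE)) "values must be non-negative or NA" else TRUE
})

#' Construct an IonImage
#' @param values numeric matrix (NA = missing pixel).
#' @param featureMz feature m/z.
#' @param tolPpm selection tolerance in ppm.
#' @return An [IonImage-class].
#' @export
IonImage <- function(values, featureMz = NA_real_, tolPpm = NA_real_) {
  new("IonImage", values = values, featureMz = featureMz, tolPpm = tolPpm)
}

#' Integer label map on the MSI grid
#'
#' Per-pixel integer class labels; 0 is background/unassigned. Used both
#' for segmentation output and for immunofluorescence-derived fiber-type
#' masks after co-registration.
#'
#' @slot labels integer matrix (rows = y, cols = x), values >= 0.
#' @slot labelNames named character; names are label integers as strings.
#' @exportClass ROILabelMap
setClass("ROILabelMap",
  representation(labels = "matrix", labelNames = "character"))

setValidity("ROILabelMap", function(object) {
  msg <- character()
  lab <- object@labels
  if (any(lab < 0, na.rm = TRUE))
    msg <- c(msg, "labels must be >= 0")
  used <- sort(unique(lab[lab > 0]))
  if (length(used) && !all(as.character(used) %in% names(object@labelNames)))
    msg <- c(msg, "every nonzero label needs an entry in labelNames")
  if (length(msg)) msg else TRUE
})

#' Construct an ROILabelMap
#' @param labels integer matrix of class labels (0 = background).
#' @param labelNames named character vector mapping label to name; defaults
#'   to `"class_<i>"` for every label present.
#' @return An [ROILabelMap-class].
#' @export
ROILabelMap <- function(labels, labelNames = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  used <- sort(unique(labels[labels > 0]))
  if (is.null(labelNames)) {
    labelNames <- stats::setNames(sprintf("class_%d", used), as.character(used))
  }
  new("ROILabelMap", labels = labels, labelNames = labelNames)
}

#' Spatial segmentation result
#'
#' @slot labels [ROILabelMap-class]; classes 1..k on occupied pixels.
#' @slot centroids k x feature matrix of cluster centers (on the
#'   standardized scale used for clustering).
#' @slot dendrogram `hclust` tree over the k centroids (Ward linkage), or
#'   NULL when k < 2 after merging.
#' @slot k integer number of classes.
#' @slot seed integer RNG seed used.
#' @slot inertia numeric, best total within-cluster sum of squares.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(labels = "ROILabelMap", centroids = "matrix",
                 dendrogram = "ANY", k = "integer", seed = "integer",
                 inertia = "numeric"))

setValidity("SegmentationResult", function(object) {
  msg <- character()
  lab <- object@labels@labels
  used <- unique(lab[lab > 0])
  if (length(used) && max(used) > object@k)
    msg <- c(msg, "labels must lie in 1..k")
  if (!all(is.finite(object@centroids)))
    msg <- c(msg, "centroids must be finite")
  if (!is.null(object@dendrogram) &&
      length(object@dendrogram$order) != object@k)
    msg <- c(msg, "dendrogram must have k leaves")
  if (length(msg)) msg else TRUE
})

#' Least-squares similarity transform between landmark sets
#'
#' Maps source (mask) coordinates onto destination (MSI) coordinates as
#' `dst = scale * R(rotation) %*% src + translation`.
#'
#' @slot scale positive scale factor.
#' @slot rotation rotation angle in radians.
#' @slot translation numeric length-2 (dx, dy) in destination pixels.
#' @slot rmse root-mean-square landmark residual.
#' @exportClass LandmarkTransform
setClass("LandmarkTransform",
  representation(scale = "numeric", rotation = "numeric",
                 translation = "numeric", rmse = "numeric"))

setValidity("LandmarkTransform", function(object) {
  msg <- character()
  if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
  if (object@rmse < 0) msg <- c(msg, "rmse must be >= 0")
  if (length(object@translation) != 2L)
    msg <- c(msg, "translation must have length 2")
  if (length(msg)) msg else TRUE
})

#' Fitted PLS-DA model
#'
#' NIPALS PLS2 on autoscaled X and dummy-coded group membership, with
#' per-feature Variable Importance in Projection (VIP). For any fitted
#' model `sum(vip^2)` equals the number of retained features.
#'
#' @slot nComponents integer.
#' @slot scores sample x component X-score matrix (orthogonal columns).
#' @slot xLoadings feature x component loading matrix.
#' @slot weights feature x component weight matrix (unit columns).
#' @slot yVariancePerComp fraction of Y sum-of-squares explained per
#'   component.
#' @slot vip per-feature VIP score.
#' @slot featureNames retained feature names (constant columns dropped).
#' @slot groups factor of the two class labels, in model order.
#' @exportClass PLSDAModel
setClass("PLSDAModel",
  representation(nComponents = "integer", scores = "matrix",
                 xLoadings = "matrix", weights = "matrix",
                 yVariancePerComp = "numeric", vip = "numeric",
                 featureNames = "character", groups = "factor"))

setValidity("PLSDAModel", function(object) {
  p <- length(object@vip)
  if (p && abs(sum(object@vip^2) - p) > 1e-6 * p)
    "sum(vip^2) must equal the number of features" else TRUE
})

#' LC-MS feature table
#'
#' @slot features data.frame with columns `id`, `mz` and optional `rt`.
#' @slot intensities feature x sample matrix (non-negative).
#' @slot groups named character, sample -> group label.
#' @exportClass LCMSTable
setClass("LCMSTable",
  representation(features = "data.frame", intensities = "matrix",
                 groups = "character"))

setValidity("LCMSTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@features$id))
    msg <- c(msg, sprintf("duplicate feature id: %s",
      paste(unique(object@features$id[duplicated(object@features$id)]),
            collapse = ", ")))
  if (nrow(object@features) != nrow(object@intensities))
    msg <- c(msg, "one feature row per matrix row required")
  if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be non-negative")
  samp <- colnames(object@intensities)
  if (!all(samp %in% names(object@groups)))
    msg <- c(msg, sprintf("missing group for sample(s): %s",
      paste(setdiff(samp, names(object@groups)), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated dataset
#'
#' @slot classMap [ROILabelMap-class] of planted classes (a rare subclass
#'   may be embedded inside one parent class).
#' @slot effectTable data.frame: `feature` (index), `mz`, `class` (label
#'   the marker is boosted in), `log2_effect`, `name`.
#' @slot varianceComponents named numeric: `target` (pixel-level variance
#'   shared across replicate acquisitions) and `error` (residual variance),
#'   both on the natural-log intensity scale.
#' @slot seed integer.
#' @exportClass SimTruth
setClass("SimTruth",
  representation(classMap = "ROILabelMap", effectTable = "data.frame",
                 varianceComponents = "numeric", seed = "integer"))

setValidity("SimTruth", function(object) {
  if (nrow(object@effectTable) &&
      !all(is.finite(object@effectTable$log2_effect)))
    "planted effects must be finite" else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum (%s): %d points, m/z %.4f..%.4f\n", object@mode,
              length(object@mz),
              if (length(object@mz)) min(object@mz) else NA,
              if (length(object@mz)) max(object@mz) else NA))
})

setMethod("show", "MSIDataset", function(object) {
  d <- if (nrow(object@coords)) gridDims(object@coords) else c(0L, 0L)
  cat(sprintf("MSIDataset: %d pixels on a %d x %d grid, %s mode, %g um spacing\n",
              length(object@spectra), d[1], d[2], object@polarity,
              object@pixelSizeUm))
})

setMethod("show", "ROILabelMap", function(object) {
  used <- sort(unique(object@labels[object@labels > 0]))
  cat(sprintf("ROILabelMap: %d x %d grid, %d classes (%s)\n",
              nrow(object@labels), ncol(object@labels), length(used),
              paste(object@labelNames[as.character(used)], collapse = ", ")))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: k = %d, seed = %d, inertia = %.4g\n",
              object@k, object@seed, object@inertia))
})

setMethod("show", "LandmarkTransform", function(object) {
  cat(sprintf(
    "LandmarkTransform: scale %.4f, rotation %.4f rad, translation (%.2f, %.2f), rmse %.3g\n",
    object@scale, object@rotation, object@translation[1],
    object@translation[2], object@rmse))
})

setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf("PLSDAModel: %d components, %d features, groups %s vs %s\n",
              object@nComponents, length(object@vip),
              levels(object@groups)[1], levels(object@groups)[2]))
})

setMethod("show", "LCMSTable", function(object) {
  cat(sprintf("LCMSTable: %d features x %d samples (%s)\n",
              nrow(object@intensities), ncol(object@intensities),
              paste(sprintf("%s=%d", names(table(object@groups)),
                            table(object@groups)), collapse = ", ")))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d planted marker features, seed %d\n",
              nrow(object@effectTable), object@seed))
})
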