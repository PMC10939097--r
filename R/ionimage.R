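# Ion images and label-map / tabular side-input I/O.

#' Extract an ion image from a peak table
#'
#' Selects the single consensus feature whose relative mass difference to
#' the query is minimal and within `tolPpm`, and renders its per-pixel
#' intensities on the bounding grid (unoccupied pixels are `NA`). The
#' result is deterministic and independent of feature order.
#'
#' @param pt a [PeakTable-class].
#' @param mz query m/z (Da).
#' @param tolPpm positive relative tolerance in ppm (default 10, the usual
#'   high-resolution matching window).
#' @return An [IonImage-class].
#' @examples
#' pt <- PeakTable(c(500.0), matrix(c(1, 2), 1), cbind(x = 0:1, y = 0L))
#' getIonImage(pt, 500.004, tolPpm = 10)  # 8 ppm away -> selected
#' @export
getIonImage <- function(pt, mz, tolPpm = 10) {
  stopifnot(tolPpm > 0)
  fmz <- featureMz(pt)
  if (!length(fmz)) stop("peak table has no features")
  dppm <- abs(ppmDiff(mz, fmz))
  best <- which.min(dppm)
  if (dppm[best] > tolPpm)
    stop(sprintf(
      "feature not found: no peak within %g ppm of m/z %.4f (nearest: %.4f at %.1f ppm)",
      tolPpm, mz, fmz[best], dppm[best]))
  vals <- intensityMatrix(pt)[best, ]
  IonImage(valuesToGrid(vals, pixelCoords(pt)), featureMz = fmz[best],
           tolPpm = tolPpm)
}

#' Read / write ROI label maps
#'
#' Label maps travel as plain-text CSV integer grids (no header; one row
#' per image row) or as indexed grayscale PNG where the gray level *is*
#' the integer label (supports up to 255 classes). 0 means background.
#'
#' @param path file ending in `.csv` or `.png`.
#' @param labelNames optional named character vector (label -> name).
#' @return `readLabelMap()` returns an [ROILabelMap-class];
#'   `writeLabelMap()` returns `path` invisibly.
#' @export
readLabelMap <- function(path, labelNames = NULL) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    lab <- round(img * 255)
  } else {
    lab <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(lab) <- NULL
  }
  ROILabelMap(lab, labelNames = labelNames)
}

#' @rdname readLabelMap
#' @param mask an [ROILabelMap-class] to write.
#' @export
writeLabelMap <- function(mask, path) {
  lab <- labelMatrix(mask)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(lab) > 255) stop("PNG label maps support at most 255 classes")
    png::writePNG(lab / 255, path)
  } else {
    utils::write.table(lab, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a metabolite reference table
#'
#' CSV with header `id,name,neutral_mass` and optional `adduct`,
#' `adduct_mz` (precomputed ion mass) and `class` columns. Rows with a
#' precomputed `adduct_mz` are matched directly; others are expanded over
#' the configured adduct list at annotation time.
#'
#' @param path CSV path.
#' @return A validated data.frame (the package's MetaboliteDB contract).
#' @export
readMetaboliteDB <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateMetaboliteDB(db)
}

validateMetaboliteDB <- function(db) {
  if (!all(c("id", "name") %in% names(db)))
    stop("metabolite DB needs 'id' and 'name' columns")
  if (anyDuplicated(db$id))
    stop("duplicate metabolite ids: ",
         paste(unique(db$id[duplicated(db$id)]), collapse = ", "))
  if (!is.null(db$neutral_mass) && any(db$neutral_mass <= 0, na.rm = TRUE))
    stop("neutral masses must be positive")
  if (!is.null(db$adduct_mz) && any(db$adduct_mz <= 0, na.rm = TRUE))
    stop("precomputed adduct m/z must be positive")
  db
}

#' Read / write a metabolite-set library (GMT)
#'
#' Tab-separated GMT: set name, description, then member metabolite ids.
#' Empty sets and duplicate set names are rejected.
#'
#' @param path GMT file path.
#' @return `readGMT()` returns a named list of character id vectors;
#'   `writeGMT()` returns `path` invisibly.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set names: ", paste(unique(nm[duplicated(nm)]),
                                        collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)][nzchar(p[-(1:2)])])
  names(sets) <- nm
  if (any(lengths(sets) == 0L))
    stop("empty metabolite set(s): ",
         paste(nm[lengths(sets) == 0L], collapse = ", "))
  sets
}

#' @rdname readGMT
#' @param sets named list of metabolite id vectors.
#' @param descriptions optional per-set description strings.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(sets) > 0, all(lengths(sets) > 0))
  lines <- mapply(function(nm, ds, ids)
    paste(c(nm, ds, ids), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
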