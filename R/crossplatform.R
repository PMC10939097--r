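# LC-MS feature-table ingestion, differential screening and identity-level
# Venn overlap against MSI findings.

#' Load an LC-MS feature table
#'
#' Reads a Progenesis-style CSV export: header row with `id`, `mz`,
#' optional `rt`, then one column per sample. Duplicate feature ids,
#' negative intensities and samples without a group assignment are
#' rejected.
#'
#' @param path CSV path.
#' @param groups named character vector, sample name -> group label.
#' @return An [LCMSTable-class].
#' @export
loadLCMS <- function(path, groups) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "mz") %in% names(df)))
    stop("LC-MS table needs 'id' and 'mz' columns")
  meta <- intersect(c("id", "mz", "rt"), names(df))
  sampleCols <- setdiff(names(df), meta)
  if (!length(sampleCols)) stop("no sample columns found")
  mat <- as.matrix(df[, sampleCols, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$id
  feats <- df[, meta, drop = FALSE]
  new("LCMSTable", features = feats, intensities = mat, groups = groups)
}

#' Write an LC-MS feature table to CSV
#' @param tbl an [LCMSTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLCMS <- function(tbl, path) {
  df <- cbind(tbl@features, as.data.frame(tbl@intensities))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Differential screening of an LC-MS table
#'
#' Runs the same per-feature Student's t machinery as the MSI arm
#' ([ttestFeatures()]) on (by default) log2-transformed intensities and
#' returns the ids passing the raw `p < pMax` criterion; the BH-adjusted
#' column rides along in the full stats table.
#'
#' @param tbl an [LCMSTable-class] with >= 2 samples per group.
#' @param pMax raw p-value cutoff (default 0.05).
#' @param log2Transform t-test log2 intensities (default TRUE; a pseudo
#'   count of 1 guards zeros).
#' @return list with `ids` (significant feature ids) and `stats` (full
#'   per-feature table).
#' @export
differentialLCMS <- function(tbl, pMax = 0.05, log2Transform = TRUE) {
  M <- t(tbl@intensities)  # samples x features
  if (log2Transform) M <- log2(M + 1)
  groups <- factor(tbl@groups[rownames(M)])
  st <- ttestFeatures(M, groups)
  list(ids = st$feature[st$p < pMax], stats = st)
}

#' Exact Venn partition of two id sets
#'
#' @param a,b character vectors of ids (e.g. annotated metabolite ids from
#'   LC-MS and MSI differential lists).
#' @return list with `only_a`, `only_b`, `both` and their `counts`; the
#'   three sets are disjoint and their sizes sum to `|union(a, b)|`.
#' @examples
#' vennOverlap(c("a", "b", "c"), c("b", "c", "d"))$counts
#' @export
vennOverlap <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  both <- intersect(a, b)
  onlyA <- setdiff(a, b); onlyB <- setdiff(b, a)
  list(only_a = onlyA, only_b = onlyB, both = both,
       counts = c(only_a = length(onlyA), only_b = length(onlyB),
                  both = length(both)))
}

#' Match two feature m/z lists at a ppm tolerance
#'
#' Fallback for cross-platform comparison when annotations are absent:
#' pairs each feature of `a` with the nearest feature of `b` within
#' `tolPpm`.
#'
#' @param a,b numeric m/z vectors.
#' @param tolPpm relative tolerance (default 10).
#' @return data.frame with `mz_a`, `mz_b`, `ppm_error` (matched pairs).
#' @export
matchByMz <- function(a, b, tolPpm = 10) {
  hits <- lapply(a, function(x) {
    err <- ppmDiff(x, b)
    j <- which.min(abs(err))
    if (abs(err[j]) <= tolPpm)
      data.frame(mz_a = x, mz_b = b[j], ppm_error = err[j])
    else NULL
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    data.frame(mz_a = numeric(), mz_b = numeric(), ppm_error = numeric())
  else out
}
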