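# Metabolite annotation by precise-mass matching with adducts at ppm
# tolerance.

## Ion mass shifts (Da) for common singly charged adducts, electron mass
## included.
ADDUCT_SHIFTS <- c(
  "M+H"  =  1.00727646,
  "M+Na" = 22.98922142,
  "M+K"  = 38.96315791,
  "M-H"  = -1.00727646
)

defaultAdducts <- function(polarity) {
  if (polarity == "positive") c("M+H", "M+Na", "M+K") else "M-H"
}

#' Annotate consensus features against a metabolite database
#'
#' For every feature m/z, reports all (metabolite, adduct) candidates
#' whose theoretical ion m/z lies within `tolPpm` (relative, the
#' high-resolution matching convention). Database rows carrying a
#' precomputed `adduct_mz` are matched directly; rows with a
#' `neutral_mass` are expanded over the adduct list for the polarity.
#' Candidates are ranked by absolute ppm error within each feature; all
#' ambiguous candidates are retained (resolving identities needs MS/MS,
#' which is outside this package's scope).
#'
#' @param features numeric vector of feature m/z values.
#' @param db metabolite table (see [readMetaboliteDB()]).
#' @param polarity `"positive"` or `"negative"`.
#' @param adducts adduct names (subset of `"M+H"`, `"M+Na"`, `"M+K"`,
#'   `"M-H"`); defaults depend on polarity.
#' @param tolPpm mass error tolerance in ppm (default 10).
#' @return data.frame with `feature_mz`, `metabolite_id`, `name`,
#'   `adduct`, `theoretical_mz`, `ppm_error`, sorted by feature then
#'   |ppm_error|.
#' @export
annotateFeatures <- function(features, db, polarity = c("positive", "negative"),
                             adducts = NULL, tolPpm = 10) {
  polarity <- match.arg(polarity)
  stopifnot(tolPpm > 0)
  db <- validateMetaboliteDB(db)
  if (!nrow(db)) stop("metabolite database is empty")
  if (is.null(adducts)) adducts <- defaultAdducts(polarity)
  unknown <- setdiff(adducts, names(ADDUCT_SHIFTS))
  if (length(unknown))
    stop("unknown adduct name(s): ", paste(unknown, collapse = ", "))

  ## candidate ion table: id, name, adduct, theoretical m/z
  cand <- list()
  if (!is.null(db$adduct_mz)) {
    pre <- db[!is.na(db$adduct_mz), , drop = FALSE]
    if (nrow(pre))
      cand[[length(cand) + 1L]] <- data.frame(
        metabolite_id = pre$id, name = pre$name,
        adduct = if (!is.null(pre$adduct)) pre$adduct else "precomputed",
        theoretical_mz = pre$adduct_mz, stringsAsFactors = FALSE)
  }
  if (!is.null(db$neutral_mass)) {
    neu <- db[!is.na(db$neutral_mass), , drop = FALSE]
    if (!is.null(db$adduct_mz))
      neu <- neu[is.na(neu$adduct_mz), , drop = FALSE]
    for (ad in adducts) {
      if (nrow(neu))
        cand[[length(cand) + 1L]] <- data.frame(
          metabolite_id = neu$id, name = neu$name, adduct = ad,
          theoretical_mz = neu$neutral_mass + ADDUCT_SHIFTS[[ad]],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) stop("database carries neither neutral_mass nor adduct_mz")
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$theoretical_mz, cand$metabolite_id,
                     cand$adduct), , drop = FALSE]

  hits <- lapply(features, function(fmz) {
    err <- ppmDiff(fmz, cand$theoretical_mz)
    sel <- which(abs(err) <= tolPpm)
    if (!length(sel)) return(NULL)
    out <- cand[sel, , drop = FALSE]
    out$feature_mz <- fmz
    out$ppm_error <- err[sel]
    out[order(abs(out$ppm_error)), , drop = FALSE]
  })
  res <- do.call(rbind, hits)
  if (is.null(res))
    return(data.frame(feature_mz = numeric(), metabolite_id = character(),
                      name = character(), adduct = character(),
                      theoretical_mz = numeric(), ppm_error = numeric()))
  rownames(res) <- NULL
  res[, c("feature_mz", "metabolite_id", "name", "adduct",
          "theoretical_mz", "ppm_error")]
}
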