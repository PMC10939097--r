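# Ground-truthed simulators: phantom muscle sections as MSI datacubes with
# planted fiber-type regions, fingerprint markers and replicate variance
# components, plus LC-MS feature tables with a matching metabolite DB and
# set library.

#' Generate a phantom fiber-type label map
#'
#' Layout presets:
#' \describe{
#'   \item{`"muscle"`}{elongated vertical bands cycling through slow,
#'     fast-2a and fast-2b classes (mimicking longitudinal fiber
#'     sections), plus scattered short bands of a rare oxidative 2b
#'     subclass embedded inside the fast-2b region (`rareFrac` of its
#'     parent's pixels, the planted-discovery scenario).}
#'   \item{`"two_region"`}{two half-plane regions (each half the pixels),
#'     the minimal two-class phantom.}
#' }
#' Deterministic at fixed seed.
#'
#' @param width,height grid size in pixels (>= 16 x 16).
#' @param layout preset name.
#' @param seed RNG seed.
#' @param rareFrac target fraction of the parent class's pixels occupied
#'   by the rare subclass (muscle preset; default 0.05).
#' @return A [SimTruth-class] with the planted class map (effect table is
#'   filled by [simulateMSI()]).
#' @export
makePhantom <- function(width, height, layout = c("muscle", "two_region"),
                        seed = 7, rareFrac = 0.05) {
  layout <- match.arg(layout)
  if (width < 16 || height < 16) stop("phantom must be at least 16 x 16")
  lab <- matrix(0L, nrow = height, ncol = width)
  if (layout == "two_region") {
    lab[, seq_len(width %/% 2)] <- 1L
    lab[, (width %/% 2 + 1L):width] <- 2L
    names_ <- c("1" = "region_1", "2" = "region_2")
  } else {
    withSeed(seed, {
      cls <- 0L
      j <- 1L
      while (j <= width) {
        cls <- cls %% 3L + 1L
        w <- sample(3:6, 1L)
        lab[, j:min(width, j + w - 1L)] <- cls
        j <- j + w
      }
      ## rare oxidative subclass: short bands inside class 3, two pixels
      ## wide (a fiber spans at least two pixels at fine spacing, so the
      ## 3x3 median denoiser does not erase them)
      parentCols <- which(apply(lab == 3L, 2L, any))
      ## anchor on column pairs fully inside the parent region so bands
      ## really are two pixels wide
      anchors <- parentCols[(parentCols + 1L) %in% parentCols]
      if (!length(anchors)) anchors <- parentCols
      target <- rareFrac * sum(lab == 3L)
      count <- 0L
      it <- 0L
      while (count < target && it < 10000L) {
        it <- it + 1L
        cc <- sample(anchors, 1L)
        cols <- cc:min(cc + 1L, width)
        ## cap the band so the planted fraction cannot overshoot far
        len <- min(sample(3:6, 1L),
                   max(2L, ceiling((target - count) / length(cols))))
        r0 <- sample(seq_len(height - len + 1L), 1L)
        rows <- r0:(r0 + len - 1L)
        sel <- which(lab[rows, cols, drop = FALSE] == 3L)
        blk <- lab[rows, cols, drop = FALSE]
        blk[sel] <- 4L
        lab[rows, cols] <- blk
        count <- count + length(sel)
      }
    })
    names_ <- c("1" = "slow", "2" = "fast_2a", "3" = "fast_2b",
                "4" = "fast_2b_oxidative")
  }
  new("SimTruth", classMap = ROILabelMap(lab, labelNames = names_),
      effectTable = data.frame(feature = integer(), mz = numeric(),
                               class = integer(), log2_effect = numeric(),
                               name = character()),
      varianceComponents = c(target = 0.0625, error = NA_real_),
      seed = as.integer(seed))
}

## fingerprint naming per phantom class, echoing the fiber-type biology
## (dipeptides in fast glycolytic fibers, acylcarnitines in oxidative ones)
markerBaseName <- function(className) {
  switch(className,
         slow = "PC_like", fast_2a = "TG_like", fast_2b = "anserine_like",
         fast_2b_oxidative = "acylcarnitine_like",
         region_1 = "marker_r1", region_2 = "marker_r2",
         paste0("marker_", className))
}

#' Simulate MSI datacubes over a phantom
#'
#' Builds per-pixel spectra from the planted class map: `nFeatures`
#' features at randomized m/z in 100-1000 Da, `nMarkersPerClass` of them
#' boosted `2^effectLog2`-fold in their class's pixels. Intensities follow
#' a multiplicative log-normal noise model (non-negative, heteroscedastic,
#' as MSI intensities are): on the natural-log scale, pixel-level
#' deviations with variance `sigma2Target` are shared across replicate
#' acquisitions, a small replicate shift is drawn per acquisition, and
#' residual noise has variance `sigma2Error` (default `(1/snr)^2`), so the
#' per-feature ICC(C,k) across replicates has the closed-form expectation
#' `k * s2T / (k * s2T + s2E)`. Profile mode adds sampled Gaussian peak
#' shapes (apex = feature intensity), a smooth additive exponential
#' baseline and a small additive noise floor, and is writable as imzML;
#' centroid mode returns stick spectra directly.
#'
#' @param truth a [SimTruth-class] from [makePhantom()].
#' @param nFeatures total features (>= classes x `nMarkersPerClass`).
#' @param nMarkersPerClass planted markers per class.
#' @param snr multiplicative signal-to-noise ratio; residual log-scale
#'   sd is `1/snr` (`Inf` = noiseless).
#' @param replicates number of replicate acquisitions.
#' @param seed RNG seed.
#' @param mode `"centroid"` (stick spectra) or `"profile"`.
#' @param effectLog2 planted marker effect in log2 units (default 2).
#' @param sigma2Target,sigma2Error override the variance components
#'   (natural-log scale); defaults: truth's target component and
#'   `(1/snr)^2`.
#' @param binWidth profile bin width in Da (default 0.2).
#' @param peakSigma Gaussian peak sd in Da (default 0.35).
#' @param replicateSd log-scale sd of the per-replicate global shift
#'   (default 0.1; removed by the consistency ICC).
#' @return list with `datasets` (list of [MSIDataset-class], one per
#'   replicate) and `truth` (the input [SimTruth-class] with the effect
#'   table and variance components filled in).
#' @export
simulateMSI <- function(truth, nFeatures = 60, nMarkersPerClass = 5,
                        snr = 4, replicates = 1, seed = 1,
                        mode = c("centroid", "profile"), effectLog2 = 2,
                        sigma2Target = NULL, sigma2Error = NULL,
                        binWidth = 0.2, peakSigma = 0.35,
                        replicateSd = 0.1) {
  mode <- match.arg(mode)
  lab <- labelMatrix(truth@classMap)
  classes <- sort(unique(lab[lab > 0]))
  if (nFeatures < length(classes) * nMarkersPerClass)
    stop("inconsistent sizes: nFeatures < n_classes * nMarkersPerClass")
  if (is.null(sigma2Target)) sigma2Target <- truth@varianceComponents[["target"]]
  if (is.null(sigma2Error)) sigma2Error <- (1 / snr)^2
  occ <- which(lab > 0, arr.ind = TRUE)
  coords <- cbind(x = occ[, "col"] - 1L, y = occ[, "row"] - 1L)
  pixCls <- lab[occ]
  npix <- nrow(coords)

  out <- withSeed(seed, {
    ## feature m/z: jittered regular grid (guaranteed spacing)
    spacing <- (990 - 110) / max(nFeatures - 1, 1)
    mz <- seq(110, 990, length.out = nFeatures) +
      stats::runif(nFeatures, -0.3, 0.3) * spacing
    if (mode == "profile")
      mz <- 100 + round((mz - 100) / binWidth) * binWidth
    baseAbund <- exp(stats::rnorm(nFeatures, log(100), 0.6))

    ## plant markers
    pool <- sample.int(nFeatures)
    markerClass <- rep(NA_integer_, nFeatures)
    eff <- data.frame(feature = integer(), mz = numeric(), class = integer(),
                      log2_effect = numeric(), name = character())
    if (nMarkersPerClass > 0) {
      for (i in seq_along(classes)) {
        idx <- pool[((i - 1) * nMarkersPerClass + 1):(i * nMarkersPerClass)]
        markerClass[idx] <- classes[i]
        cname <- truth@classMap@labelNames[as.character(classes[i])]
        eff <- rbind(eff, data.frame(
          feature = idx, mz = mz[idx], class = classes[i],
          log2_effect = effectLog2,
          name = sprintf("%s_%02d", markerBaseName(cname),
                         seq_len(nMarkersPerClass))))
      }
    }
    effectMat <- matrix(0, nFeatures, npix)
    if (nrow(eff))
      for (r in seq_len(nrow(eff)))
        effectMat[eff$feature[r], pixCls == eff$class[r]] <- eff$log2_effect[r]

    aFP <- matrix(stats::rnorm(nFeatures * npix, 0, sqrt(sigma2Target)),
                  nFeatures, npix)
    grid <- NULL; kernIdx <- NULL; kernVal <- NULL
    if (mode == "profile") {
      grid <- seq(100, 1000, by = binWidth)
      kernIdx <- lapply(mz, function(m)
        which(abs(grid - m) < 5 * peakSigma))
      kernVal <- lapply(seq_along(mz), function(f)
        exp(-(grid[kernIdx[[f]]] - mz[f])^2 / (2 * peakSigma^2)))
    }
    datasets <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      bR <- stats::rnorm(nFeatures, 0, replicateSd)
      epsSd <- if (is.finite(snr)) sqrt(sigma2Error) else 0
      eps <- matrix(stats::rnorm(nFeatures * npix, 0, epsSd),
                    nFeatures, npix)
      I <- baseAbund * 2^effectMat * exp(aFP + bR + eps)
      if (mode == "centroid") {
        sp <- lapply(seq_len(npix), function(p)
          Spectrum(mz, I[, p], mode = "centroid"))
      } else {
        medBase <- stats::median(baseAbund)
        sp <- lapply(seq_len(npix), function(p) {
          y <- 0.5 * medBase * exp(-(grid - 100) / 250) *
            exp(stats::rnorm(1, 0, 0.1))
          y <- y + abs(stats::rnorm(length(grid), 0, 0.01 * medBase))
          for (f in seq_len(nFeatures))
            y[kernIdx[[f]]] <- y[kernIdx[[f]]] + I[f, p] * kernVal[[f]]
          Spectrum(grid, y, mode = "profile")
        })
      }
      datasets[[r]] <- MSIDataset(sp, coords,
                                  metadata = list(replicate = r))
    }
    list(datasets = datasets, eff = eff)
  })
  truth@effectTable <- out$eff
  truth@varianceComponents <- c(target = sigma2Target, error = sigma2Error)
  truth@seed <- as.integer(seed)
  list(datasets = out$datasets, truth = truth)
}

#' Simulate an LC-MS feature table with planted group effects
#'
#' Log-normal intensities for two groups with planted log2 fold changes on
#' selected features; feature ids are shared with a generated metabolite
#' database (neutral masses back-computed assuming protonated ions) and a
#' set library (one planted "acyl carnitines" set holding the marker ids
#' plus random null sets), so annotation, enrichment and Venn overlap are
#' exercisable end to end.
#'
#' @param nFeatures number of features.
#' @param nPerGroup samples per group (>= 2... the study used 3).
#' @param planted either an integer count of marker features (boosted by
#'   `effectLog2` in group B), a vector of feature indices, or a
#'   data.frame with columns `feature`, `log2fc`. NULL = no effects.
#' @param effectLog2 default planted effect (log2 units).
#' @param seed RNG seed.
#' @param sdlog residual log-scale (natural) sd of intensities
#'   (default 0.3).
#' @param nNullSets,setSize random null sets added to the library.
#' @param ids,mzValues optional feature identities / m/z values to reuse
#'   (e.g. from an MSI run, so cross-platform overlap is exercisable);
#'   defaults are generated.
#' @return list with `table` ([LCMSTable-class]), `db` (metabolite
#'   data.frame), `sets` (named list), `truth` (data.frame `id`,
#'   `feature`, `log2fc`).
#' @export
simulateLCMS <- function(nFeatures = 200, nPerGroup = 3, planted = NULL,
                         effectLog2 = 2, seed = 1, sdlog = 0.3,
                         nNullSets = 10, setSize = 10, ids = NULL,
                         mzValues = NULL) {
  if (nPerGroup < 2) stop("nPerGroup must be >= 2")
  withSeed(seed, {
    if (is.null(ids)) ids <- sprintf("met_%04d", seq_len(nFeatures))
    stopifnot(length(ids) == nFeatures)
    spacing <- (900 - 150) / max(nFeatures - 1, 1)
    mz <- if (!is.null(mzValues)) as.numeric(mzValues)
      else sort(seq(150, 900, length.out = nFeatures) +
                  stats::runif(nFeatures, -0.3, 0.3) * spacing)
    if (is.null(planted)) {
      plantedDf <- data.frame(feature = integer(), log2fc = numeric())
    } else if (is.data.frame(planted)) {
      plantedDf <- planted
    } else if (length(planted) == 1L && planted[1] == floor(planted[1]) &&
               planted[1] <= nFeatures && length(planted) == 1L) {
      plantedDf <- data.frame(feature = sample.int(nFeatures, planted),
                              log2fc = effectLog2)
    } else {
      plantedDf <- data.frame(feature = as.integer(planted),
                              log2fc = effectLog2)
    }
    fc <- numeric(nFeatures)
    fc[plantedDf$feature] <- plantedDf$log2fc
    n <- 2L * nPerGroup
    samples <- c(sprintf("A_%d", seq_len(nPerGroup)),
                 sprintf("B_%d", seq_len(nPerGroup)))
    groups <- stats::setNames(rep(c("A", "B"), each = nPerGroup), samples)
    base <- exp(stats::rnorm(nFeatures, log(1000), 1))
    isB <- rep(c(0, 1), each = nPerGroup)
    I <- matrix(0, nFeatures, n, dimnames = list(ids, samples))
    for (s in seq_len(n))
      I[, s] <- base * 2^(fc * isB[s]) *
        exp(stats::rnorm(nFeatures, 0, sdlog))
    feats <- data.frame(id = ids, mz = mz,
                        rt = round(stats::runif(nFeatures, 30, 900), 1))
    tbl <- new("LCMSTable", features = feats, intensities = I,
               groups = groups)
    markerIds <- ids[plantedDf$feature]
    db <- data.frame(
      id = ids,
      name = ifelse(ids %in% markerIds,
                    sprintf("acylcarnitine_like_%s", ids),
                    sprintf("metabolite_%s", ids)),
      neutral_mass = mz - 1.00727646,
      class = ifelse(ids %in% markerIds, "acyl carnitine", "other"),
      stringsAsFactors = FALSE)
    sets <- list()
    if (length(markerIds)) sets[["acyl carnitines"]] <- markerIds
    nonMarkers <- setdiff(ids, markerIds)
    for (i in seq_len(nNullSets))
      sets[[sprintf("null_set_%02d", i)]] <-
        sample(nonMarkers, min(setSize, length(nonMarkers)))
    list(table = tbl, db = db, sets = sets,
         truth = data.frame(id = markerIds, feature = plantedDf$feature,
                            log2fc = plantedDf$log2fc))
  })
}
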