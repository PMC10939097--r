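# Spatially aware K-means segmentation of the peak table into metabolic
# classes, with a Ward dendrogram over class centroids and operator-guided
# class merging (the "semi-supervised" step: unsupervised clustering
# followed by curation against histology).

kmeansppInit <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      ## fewer distinct points than centers requested
      idx[j + 1L] <- sample.int(n, 1L)
    } else {
      idx[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    dj <- rowSums((X - matrix(X[idx[j + 1L], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  X[idx, , drop = FALSE]
}

#' Segment a peak table into metabolic classes
#'
#' Pixel feature vectors are (optionally) denoised per feature image with
#' a NaN-aware median filter, standardized per feature (z-score, so
#' high-abundance lipids do not dominate the distance), and clustered by
#' K-means with k-means++ initialization at a fixed seed; 10 restarts are
#' run and the solution with the lowest total within-cluster sum of
#' squares is kept. A Ward dendrogram over the class centroids summarises
#' between-class structure and guides [mergeClasses()].
#'
#' @param pt a [PeakTable-class].
#' @param k number of classes (>= 2; the muscle study used 9 regions).
#' @param seed RNG seed; identical seeds give identical segmentations.
#' @param denoise logical, median-filter each feature image before
#'   clustering (default TRUE).
#' @param nstart number of k-means++ restarts (default 10).
#' @param kernel median-filter kernel when `denoise = TRUE`.
#' @return A [SegmentationResult-class].
#' @export
segment <- function(pt, k, seed = 42, denoise = TRUE, nstart = 10,
                    kernel = 3) {
  if (k < 2) stop("k must be >= 2")
  coords <- pixelCoords(pt)
  npix <- nrow(coords)
  if (k > npix) stop("k exceeds the number of occupied pixels")
  X <- t(intensityMatrix(pt))  # pixels x features
  if (denoise) {
    for (j in seq_len(ncol(X))) {
      grid <- denoiseIonImage(valuesToGrid(X[, j], coords), kernel = kernel)
      X[, j] <- gridToValues(grid, coords)
    }
  }
  ## per-feature standardization; constant features carry no signal
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")

  if (nrow(unique(X)) == 1L) {
    warning("all pixels identical: single effective cluster")
    lab <- valuesToGrid(rep(1, npix), coords)
    lab[is.na(lab)] <- 0
    res <- new("SegmentationResult",
               labels = ROILabelMap(lab),
               centroids = matrix(colMeans(X), 1L,
                                  dimnames = list(NULL, colnames(X))),
               dendrogram = NULL, k = 1L, seed = as.integer(seed),
               inertia = 0)
    return(res)
  }

  fit <- withSeed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      centers <- kmeansppInit(X, k)
      km <- suppressWarnings(
        stats::kmeans(X, centers = centers, iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  lab <- valuesToGrid(fit$cluster, coords)
  lab[is.na(lab)] <- 0
  dnd <- stats::hclust(stats::dist(fit$centers), method = "ward.D2")
  new("SegmentationResult",
      labels = ROILabelMap(lab),
      centroids = fit$centers,
      dendrogram = dnd, k = as.integer(k), seed = as.integer(seed),
      inertia = fit$tot.withinss)
}

#' Merge segmentation classes
#'
#' Applies an operator-supplied label mapping (e.g. after comparing the
#' dendrogram and label map with histology), recomputes centroids as
#' pixel-count-weighted means, compacts labels to 1..k' and rebuilds the
#' Ward dendrogram. Mass is conserved: the weighted centroid sum equals
#' the sum over all pixel vectors before and after merging.
#'
#' @param seg a [SegmentationResult-class].
#' @param mapping named integer vector, old label (name) -> new label
#'   (value). Unmentioned labels map to themselves. Mapping to 0
#'   (background) is forbidden.
#' @return A [SegmentationResult-class].
#' @export
mergeClasses <- function(seg, mapping) {
  old <- as.integer(names(mapping))
  new_ <- as.integer(mapping)
  lab <- labelMatrix(seg)
  used <- sort(unique(lab[lab > 0]))
  if (!all(old %in% used))
    stop("mapping references absent label(s): ",
         paste(setdiff(old, used), collapse = ", "))
  if (any(new_ == 0L)) stop("merging into background label 0 is forbidden")
  full <- stats::setNames(used, as.character(used))
  full[as.character(old)] <- new_
  counts <- table(factor(lab[lab > 0], levels = used))
  ## compact merged labels to 1..k'
  uniqNew <- sort(unique(full))
  compact <- stats::setNames(seq_along(uniqNew), as.character(uniqNew))
  finalMap <- compact[as.character(full)]  # old label -> compact new label
  names(finalMap) <- names(full)
  labNew <- lab
  labNew[lab > 0] <- finalMap[as.character(lab[lab > 0])]
  kNew <- length(uniqNew)
  cent <- matrix(0, kNew, ncol(seg@centroids),
                 dimnames = list(NULL, colnames(seg@centroids)))
  for (j in seq_len(kNew)) {
    members <- used[finalMap == j]
    w <- as.numeric(counts[as.character(members)])
    cent[j, ] <- colSums(seg@centroids[match(members, used), , drop = FALSE] *
                           w) / sum(w)
  }
  dnd <- if (kNew >= 2L)
    stats::hclust(stats::dist(cent), method = "ward.D2") else NULL
  new("SegmentationResult", labels = ROILabelMap(labNew), centroids = cent,
      dendrogram = dnd, k = as.integer(kNew), seed = seg@seed,
      inertia = seg@inertia)
}

#' Class-wise mean spectra
#'
#' Extracts region-specific mean spectra: for every nonzero class in the
#' label map, the mean over its pixels of each consensus feature.
#'
#' @param pt a [PeakTable-class].
#' @param labels an [ROILabelMap-class] on the same grid.
#' @param classes optional integer vector of classes to extract (default:
#'   all nonzero classes present). A requested class with no pixels is an
#'   error.
#' @return class x feature numeric matrix (rownames = class labels).
#' @export
classMeanSpectra <- function(pt, labels, classes = NULL) {
  coords <- pixelCoords(pt)
  lab <- gridToValues(labelMatrix(labels), coords)
  if (is.null(classes)) classes <- sort(unique(lab[!is.na(lab) & lab > 0]))
  M <- intensityMatrix(pt)
  out <- matrix(NA_real_, length(classes), nrow(M),
                dimnames = list(as.character(classes), rownames(M)))
  for (i in seq_along(classes)) {
    sel <- which(!is.na(lab) & lab == classes[i])
    if (!length(sel)) stop("class ", classes[i], " covers no pixels")
    out[i, ] <- rowMeans(M[, sel, drop = FALSE])
  }
  out
}
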