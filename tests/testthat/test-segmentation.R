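# K-means segmentation, class merging, class mean spectra.

makeThreeClassTable <- function(seed = 7) {
  ph <- makePhantom(32, 20, "muscle", seed = seed, rareFrac = 0)
  sim <- simulateMSI(ph, nFeatures = 30, nMarkersPerClass = 4, snr = 4,
                     seed = seed)
  list(pt = processDataset(sim$datasets[[1]], minPixelFraction = 0.3),
       truth = sim$truth)
}

test_that("three planted classes are recovered with ARI >= 0.9", {
  skip_if_not_installed("mclust")
  x <- makeThreeClassTable(seed = 7)
  seg <- segment(x$pt, k = 3, seed = 7, denoise = TRUE)
  tl <- gridToValues(labelMatrix(x$truth@classMap), pixelCoords(x$pt))
  sl <- gridToValues(labelMatrix(seg), pixelCoords(x$pt))
  expect_gte(mclust::adjustedRandIndex(tl, sl), 0.9)
  ## reproducibility at fixed seed
  seg2 <- segment(x$pt, k = 3, seed = 7, denoise = TRUE)
  expect_identical(labelMatrix(seg), labelMatrix(seg2))
  expect_equal(seg@inertia, seg2@inertia)
})

test_that("k = 1 is rejected and exact duplicates separate perfectly", {
  pt <- PeakTable(c(100, 200), rbind(c(1, 1, 9, 9), c(2, 2, 8, 8)),
                  cbind(x = 0:3, y = 0L))
  expect_error(segment(pt, k = 1), "k must be >= 2")
  skip_if_not_installed("mclust")
  seg <- segment(pt, k = 2, seed = 1, denoise = FALSE)
  sl <- gridToValues(labelMatrix(seg), pixelCoords(pt))
  expect_equal(mclust::adjustedRandIndex(c(1, 1, 2, 2), sl), 1)
})

test_that("degenerate all-identical pixels collapse with a warning", {
  pt <- PeakTable(c(100, 200), matrix(3, 2, 5), cbind(x = 0:4, y = 0L))
  expect_warning(seg <- segment(pt, k = 2, seed = 1, denoise = FALSE),
                 "single effective cluster")
  expect_identical(seg@k, 1L)
})

test_that("merging classes conserves mass and recomputes centroids", {
  x <- makeThreeClassTable(seed = 9)
  seg <- segment(x$pt, k = 3, seed = 9, denoise = FALSE)
  lab <- labelMatrix(seg)
  counts <- table(factor(lab[lab > 0], levels = 1:3))
  total <- as.numeric(counts) %*% seg@centroids
  ## identity mapping changes nothing
  id <- mergeClasses(seg, c("1" = 1, "2" = 2, "3" = 3))
  expect_identical(labelMatrix(id), lab)
  expect_equal(id@centroids, seg@centroids, ignore_attr = TRUE)
  ## merge 2 -> 1: weighted mean centroid, labels compacted to 1..2
  mg <- mergeClasses(seg, c("2" = 1))
  expect_identical(mg@k, 2L)
  w <- as.numeric(counts[1:2])
  expect_equal(mg@centroids[1, ],
               (w[1] * seg@centroids[1, ] + w[2] * seg@centroids[2, ]) /
                 sum(w),
               ignore_attr = TRUE)
  ## conservation across the merge
  labM <- labelMatrix(mg)
  countsM <- table(factor(labM[labM > 0], levels = 1:2))
  expect_equal(as.numeric(as.numeric(countsM) %*% mg@centroids),
               as.numeric(total))
  ## dendrogram has the merged class count
  expect_length(mg@dendrogram$order, 2L)
  ## invalid mappings
  expect_error(mergeClasses(seg, c("9" = 1)), "absent")
  expect_error(mergeClasses(seg, c("2" = 0)), "background")
})

test_that("class mean spectra average pixels and recover planted effects", {
  ## two pixels with intensities 2 and 4 in one class -> mean 3
  pt <- PeakTable(500, matrix(c(2, 4), 1), cbind(x = 0:1, y = 0L))
  lab <- ROILabelMap(matrix(c(1L, 1L), 1))
  expect_equal(as.numeric(classMeanSpectra(pt, lab)), 3)
  ## single-class map equals the global mean spectrum
  pt2 <- PeakTable(c(100, 300), rbind(c(1, 2, 3), c(4, 5, 6)),
                   cbind(x = 0:2, y = 0L))
  cm <- classMeanSpectra(pt2, ROILabelMap(matrix(1L, 1, 3)))
  expect_equal(as.numeric(cm), unname(rowMeans(intensityMatrix(pt2))))
  ## empty requested class errors
  expect_error(classMeanSpectra(pt2, ROILabelMap(matrix(1L, 1, 3)),
                                classes = 5), "no pixels")
  ## planted marker fold change recovered within 10% (unnormalized table)
  ph <- makePhantom(24, 16, "muscle", seed = 3, rareFrac = 0)
  sim <- simulateMSI(ph, nFeatures = 30, nMarkersPerClass = 3, snr = 8,
                     seed = 3, sigma2Target = 0.01)
  ptU <- processDataset(sim$datasets[[1]], normalize = FALSE)
  cmU <- classMeanSpectra(ptU, ph@classMap)
  et <- sim$truth@effectTable
  fast2b <- et[et$class == 3, ][1, ]  # an "anserine-like" fast marker
  j <- which.min(abs(featureMz(ptU) - fast2b$mz))
  fc <- cmU["3", j] / cmU["1", j]
  expect_lt(abs(fc - 2^fast2b$log2_effect) / 2^fast2b$log2_effect, 0.1)
})
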