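# Phantom generators: geometry, determinism, planted-effect fidelity,
# noise calibration.

test_that("phantom presets honour their geometric contracts", {
  ## two_region: exactly two classes, each at least a quarter of pixels
  tr <- makePhantom(32, 32, "two_region", seed = 1)
  tab <- table(labelMatrix(tr@classMap))
  expect_identical(sort(as.integer(names(tab))), c(1L, 2L))
  expect_true(all(tab >= 0.25 * 32 * 32))
  ## muscle: rare subclass occupies ~rareFrac of its parent
  mu <- makePhantom(40, 28, "muscle", seed = 7, rareFrac = 0.05)
  tab2 <- table(factor(labelMatrix(mu@classMap), levels = 1:4))
  frac <- tab2["4"] / (tab2["3"] + tab2["4"])
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
  ## determinism
  mu2 <- makePhantom(40, 28, "muscle", seed = 7, rareFrac = 0.05)
  expect_identical(labelMatrix(mu@classMap), labelMatrix(mu2@classMap))
  expect_error(makePhantom(8, 8, "muscle"), "at least 16")
  expect_error(makePhantom(32, 32, "nope"), "arg")
})

test_that("noiseless simulation reproduces planted fold changes exactly", {
  ph <- makePhantom(24, 16, "muscle", seed = 2, rareFrac = 0)
  sim <- simulateMSI(ph, nFeatures = 24, nMarkersPerClass = 3, snr = Inf,
                     replicates = 1, seed = 2, sigma2Target = 0)
  pt <- processDataset(sim$datasets[[1]], normalize = FALSE)
  cm <- classMeanSpectra(pt, ph@classMap)
  et <- sim$truth@effectTable
  for (r in seq_len(nrow(et))) {
    j <- which.min(abs(featureMz(pt) - et$mz[r]))
    others <- setdiff(rownames(cm), as.character(et$class[r]))
    fc <- cm[as.character(et$class[r]), j] / cm[others[1], j]
    expect_equal(fc, 2^et$log2_effect[r], tolerance = 0.01)
  }
})

test_that("replicate acquisitions carry the planted variance components", {
  ph <- makePhantom(20, 16, "muscle", seed = 2)
  sim <- simulateMSI(ph, nFeatures = 120, nMarkersPerClass = 0, snr = 1,
                     replicates = 4, seed = 6, sigma2Target = 1,
                     sigma2Error = 1)
  expect_identical(unname(sim$truth@varianceComponents), c(1, 1))
  ptL <- lapply(sim$datasets, processDataset, normalize = FALSE)
  icc <- replicateICC(ptL, nTargets = 40, seed = 1)
  ## ICC(C,4) expectation 4/(4+1) = 0.8
  expect_equal(mean(icc$icc), 0.8, tolerance = 0.03)
})

test_that("null phantoms do not trigger the AUC discrimination gate", {
  ph <- makePhantom(24, 20, "two_region", seed = 3)
  sim <- simulateMSI(ph, nFeatures = 100, nMarkersPerClass = 0, snr = 4,
                     seed = 3)
  pt <- processDataset(sim$datasets[[1]], normalize = FALSE)
  lab <- gridToValues(labelMatrix(ph@classMap), pixelCoords(pt))
  au <- aucFeatures(t(intensityMatrix(pt)), factor(lab))
  ## both groups have >= 50 pixels; expect <= 5% + MC slack flagged
  expect_lte(mean(au$discriminative), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("simulated datacubes are deterministic and round-trip imzML", {
  ph <- makePhantom(16, 16, "two_region", seed = 4)
  s1 <- simulateMSI(ph, nFeatures = 10, nMarkersPerClass = 2, snr = 4,
                    seed = 9)
  s2 <- simulateMSI(ph, nFeatures = 10, nMarkersPerClass = 2, snr = 4,
                    seed = 9)
  expect_equal(spectra(s1$datasets[[1]])[[5]]@intensity,
               spectra(s2$datasets[[1]])[[5]]@intensity)
  expect_identical(s1$truth@effectTable, s2$truth@effectTable)
  path <- file.path(tempdir(), "sim.imzML")
  writeImzML(s1$datasets[[1]], path)
  back <- readImzML(path)
  expect_identical(pixelCoords(back), pixelCoords(s1$datasets[[1]]))
  expect_equal(spectra(back)[[1]]@intensity,
               spectra(s1$datasets[[1]])[[1]]@intensity, tolerance = 1e-6)
})

test_that("simulated LC-MS tables are deterministic with planted truth", {
  a <- simulateLCMS(nFeatures = 50, nPerGroup = 3, planted = 5, seed = 8)
  b <- simulateLCMS(nFeatures = 50, nPerGroup = 3, planted = 5, seed = 8)
  expect_identical(intensityMatrix(a$table), intensityMatrix(b$table))
  expect_identical(a$truth, b$truth)
  ## planted ids live in the generated DB and the planted set
  expect_true(all(a$truth$id %in% a$db$id))
  expect_setequal(a$sets[["acyl carnitines"]], a$truth$id)
  ## null sets avoid the markers
  expect_length(intersect(unlist(a$sets[-1]), a$truth$id), 0L)
})

test_that("null LC-MS simulations show no group separation", {
  skip_if_not_installed("cluster")
  sim <- simulateLCMS(nFeatures = 150, nPerGroup = 6, planted = NULL,
                      seed = 10)
  M <- t(log2(intensityMatrix(sim$table) + 1))
  p <- pcaFeatures(M, 2)
  grp <- as.integer(factor(sim$table@groups[rownames(M)]))
  sil <- cluster::silhouette(grp, dist(p$scores))
  expect_lt(abs(mean(sil[, "sil_width"])), 0.1)
})
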