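# Baseline removal, RMS normalization, peak picking, alignment, median
# denoising.

test_that("morphological baseline removal behaves on constructed spectra", {
  mz <- seq(100, 120, by = 0.1)
  ## flat spectrum: baseline equals signal -> all zero
  flat <- Spectrum(mz, rep(7, length(mz)))
  expect_true(all(removeBaseline(flat, 11)@intensity == 0))
  ## isolated narrow peak on zero baseline survives within 1% of apex
  peak <- 50 * exp(-(mz - 110)^2 / (2 * 0.2^2))
  s <- Spectrum(mz, peak)
  out <- removeBaseline(s, 31)
  expect_lt(abs(max(out@intensity) - 50) / 50, 0.01)
  ## linear ramp + peak: apex reduced by the local ramp value
  ramp <- 0.5 * (mz - 100)
  s2 <- Spectrum(mz, ramp + peak)
  out2 <- removeBaseline(s2, 31)
  apex <- which.max(peak)
  expect_equal(out2@intensity[apex], 50, tolerance = 0.02)
  ## centroid input is refused with guidance
  expect_error(removeBaseline(Spectrum(1:3, 1:3, mode = "centroid"), 11),
               "skip")
})

test_that("RMS normalization gives unit-RMS output and the exact factor", {
  r <- rmsNormalize(Spectrum(c(100, 200), c(3, 4)))
  expect_equal(r$factor, sqrt(12.5))
  expect_equal(r$spectrum@intensity, c(3, 4) / sqrt(12.5))
  ## constant spectrum -> all ones
  rc <- rmsNormalize(Spectrum(1:5, rep(2.5, 5)))
  expect_equal(rc$spectrum@intensity, rep(1, 5))
  expect_equal(rc$factor, 2.5)
  expect_error(rmsNormalize(Spectrum(1:3, rep(0, 3))), "all-zero")
  ## property: RMS of output is 1 to 1e-9 on random spectra
  withr::with_seed(4, {
    for (i in 1:20) {
      s <- Spectrum(sort(runif(50, 100, 1000)), rexp(50))
      out <- rmsNormalize(s)$spectrum
      expect_equal(sqrt(mean(out@intensity^2)), 1, tolerance = 1e-9)
    }
  })
})

test_that("peak picking finds planted peaks and ignores pure noise", {
  ## flat nonzero spectrum: zero-MAD fallback warns, still no peaks
  expect_warning(pl0 <- pickPeaks(Spectrum(1:100, rep(1, 100))),
                 "smallest positive")
  expect_identical(nrow(pl0), 0L)
  ## flat zero spectrum: silently empty
  expect_identical(nrow(pickPeaks(Spectrum(1:100, rep(0, 100)))), 0L)
  ## strong Gaussian at 400.00 in seeded noise: exactly one peak near apex
  withr::with_seed(11, {
    s <- gaussSpectrum(400.00, amp = 50, noiseSd = 1)
    pl <- pickPeaks(s, snrMin = 5)
    strong <- pl[pl$snr > 20, ]
    expect_identical(nrow(strong), 1L)
    expect_lt(abs(strong$mz - 400.00), 0.05)  # within one profile bin
  })
  ## seeded pure noise rarely yields peaks at snrMin = 5
  withr::with_seed(12, {
    hits <- vapply(1:100, function(i) {
      y <- abs(rnorm(200, 0, 1))
      nrow(pickPeaks(Spectrum(seq(100, 120, length.out = 200), y),
                     snrMin = 5))
    }, integer(1))
    expect_gte(mean(hits == 0), 0.95)
  })
})

test_that("ppm alignment merges at 8 ppm and splits at 20 ppm", {
  plA <- data.frame(mz = 500.000, intensity = 10, snr = 10)
  plB <- data.frame(mz = 500.004, intensity = 20, snr = 10)  # 8 ppm away
  coords <- cbind(x = 0:1, y = 0L)
  pt <- alignPeaks(list(plA, plB), coords, tolPpm = 10,
                   minPixelFraction = 0)
  expect_length(featureMz(pt), 1L)
  ## intensity-weighted consensus lies within the member span
  expect_gte(featureMz(pt), 500.000)
  expect_lte(featureMz(pt), 500.004)
  plC <- data.frame(mz = 500.010, intensity = 20, snr = 10)  # 20 ppm away
  pt2 <- alignPeaks(list(plA, plC), coords, tolPpm = 10,
                    minPixelFraction = 0)
  expect_length(featureMz(pt2), 2L)
  expect_error(alignPeaks(list(plA, plB), coords, tolPpm = 0), "positive")
})

test_that("alignment of identical peak lists reproduces the shared m/z", {
  pl <- data.frame(mz = c(150.1, 400.2, 900.3), intensity = c(1, 2, 3),
                   snr = 10)
  coords <- cbind(x = 0:3, y = 0L)
  pt <- alignPeaks(rep(list(pl), 4), coords, tolPpm = 10)
  expect_equal(featureMz(pt), pl$mz)
  expect_true(all(intensityMatrix(pt) == matrix(pl$intensity, 3, 4)))
})

test_that("alignment is invariant to pixel order", {
  withr::with_seed(3, {
    pls <- lapply(1:6, function(i)
      data.frame(mz = sort(runif(5, 100, 1000)), intensity = rexp(5),
                 snr = 10))
  })
  coords <- cbind(x = 0:5, y = 0L)
  pt1 <- alignPeaks(pls, coords, tolPpm = 10, minPixelFraction = 0)
  perm <- c(4, 2, 6, 1, 3, 5)
  pt2 <- alignPeaks(pls[perm], coords[perm, ], tolPpm = 10,
                    minPixelFraction = 0)
  expect_equal(featureMz(pt1), featureMz(pt2))
  ord <- order(perm)
  expect_equal(intensityMatrix(pt1),
               intensityMatrix(pt2)[, ord],
               ignore_attr = TRUE)
})

test_that("median denoising removes impulses but preserves edges", {
  ## constant image unchanged
  cimg <- matrix(5, 8, 8)
  expect_equal(denoiseIonImage(cimg, 3), cimg)
  ## single impulse replaced by background
  imp <- cimg; imp[4, 4] <- 100
  expect_equal(denoiseIonImage(imp, 3), cimg)
  ## vertical step edge preserved exactly
  step <- cbind(matrix(1, 8, 4), matrix(9, 8, 4))
  expect_equal(denoiseIonImage(step, 3), step)
  ## idempotent on its own output for piecewise-constant images
  once <- denoiseIonImage(step, 3)
  expect_equal(denoiseIonImage(once, 3), once)
  ## NaN pixels stay missing and are excluded from windows
  withNA <- cimg; withNA[1, 1] <- NA; withNA[2, 2] <- 100
  out <- denoiseIonImage(withNA, 3)
  expect_true(is.na(out[1, 1]))
  expect_equal(out[2, 2], 5)
  expect_error(denoiseIonImage(cimg, 4), "odd")
})

test_that("processDataset yields unit-RMS pixel columns when normalizing", {
  withr::with_seed(21, {
    sp <- lapply(1:6, function(i)
      Spectrum(c(200, 500, 800), rexp(3) + 0.1, mode = "centroid"))
  })
  ds <- MSIDataset(sp, cbind(x = 0:5, y = 0L))
  pt <- processDataset(ds, normalize = TRUE)
  expect_identical(normalization(pt), "rms")
  M <- intensityMatrix(pt)
  rms <- apply(M, 2, function(v) sqrt(mean(v[v > 0]^2)))
  expect_true(all(abs(rms - 1) < 1e-9))
})
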