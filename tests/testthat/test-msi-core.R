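# Domain types and imzML I/O.

test_that("Spectrum and MSIDataset enforce their invariants", {
  expect_error(Spectrum(c(2, 1), c(1, 1)), "increasing")
  expect_error(Spectrum(c(1, 2), c(1, -1)), "non-negative")
  expect_error(Spectrum(c(1, 2), c(1, 2, 3)), "same length")
  sp <- list(Spectrum(1:3, 1:3), Spectrum(1:3, 1:3))
  expect_error(MSIDataset(sp, cbind(x = c(0, 0), y = c(0, 0))),
               "duplicate")
  expect_error(MSIDataset(sp, cbind(x = c(0, -1), y = c(0, 0))),
               "0-based")
})

test_that("imzML round-trips coords, m/z and intensities", {
  ds <- stripDataset(list(c(1.25, 2.5, 3.75), c(4.1, 0, 5.9)))
  path <- file.path(tempdir(), "rt.imzML")
  writeImzML(ds, path)
  ds2 <- readImzML(path)
  expect_identical(pixelCoords(ds2), pixelCoords(ds))
  expect_equal(ds2@polarity, "positive")
  for (i in 1:2) {
    expect_identical(spectra(ds2)[[i]]@mz, spectra(ds)[[i]]@mz)  # 64-bit
    expect_equal(spectra(ds2)[[i]]@intensity, spectra(ds)[[i]]@intensity,
                 tolerance = 1e-6)  # float32 storage
  }
})

test_that("single-pixel file with three points loads as written", {
  ds <- MSIDataset(list(Spectrum(c(100, 200, 300), c(1, 2, 3),
                                 mode = "centroid")),
                   cbind(x = 0L, y = 0L))
  path <- file.path(tempdir(), "one.imzML")
  writeImzML(ds, path)
  ds2 <- readImzML(path)
  expect_length(spectra(ds2), 1L)
  expect_length(spectra(ds2)[[1]]@mz, 3L)
})

test_that("truncated ibd gives a parse error naming the pixel", {
  ds <- stripDataset(list(c(1, 2, 3), c(4, 5, 6)))
  path <- file.path(tempdir(), "trunc.imzML")
  writeImzML(ds, path)
  ibd <- sub("imzML$", "ibd", path)
  sz <- file.info(ibd)$size
  con <- file(ibd, "r+b")
  truncate <- function(con, n) {
    raw <- readBin(con, "raw", n)
    close(con)
    writeBin(raw, ibd)
  }
  truncate(con, sz - 10)
  expect_error(readImzML(path), "pixel .*truncated")
})

test_that("empty dataset refuses to write", {
  ds <- new("MSIDataset", spectra = list(),
            coords = matrix(integer(), 0, 2,
                            dimnames = list(NULL, c("x", "y"))),
            pixelSizeUm = 50, polarity = "positive", metadata = list())
  expect_error(writeImzML(ds, tempfile(fileext = ".imzML")),
               "nothing to write")
})

test_that("our imzML interoperates with an independent parser", {
  py <- Sys.which("python")
  skip_if(py == "", "python unavailable")
  ds <- stripDataset(list(c(1, 2, 3), c(4, 5, 6)))
  path <- file.path(tempdir(), "interop.imzML")
  writeImzML(ds, path)
  out <- suppressWarnings(system2(py, c("-c", shQuote(sprintf(
    "from pyimzml.ImzMLParser import ImzMLParser; p = ImzMLParser('%s'); mz, i = p.getspectrum(1); print(','.join(str(v) for v in mz)); print(','.join(str(c) for c in p.coordinates[1][:2]))",
    path))), stdout = TRUE, stderr = FALSE))
  skip_if(length(out) < 2, "pyimzml unavailable")
  expect_equal(as.numeric(strsplit(out[1], ",")[[1]]), c(200, 500, 800))
  expect_equal(as.integer(strsplit(out[2], ",")[[1]]), c(2L, 1L))  # 1-based
})

test_that("ion image extraction honours the ppm window", {
  pt <- PeakTable(c(300, 500), rbind(c(1, 2, 3), c(4, 5, 6)),
                  cbind(x = c(0L, 1L, 0L), y = c(0L, 0L, 1L)))
  ## 500.004 is 8 ppm from 500 -> selected
  img <- getIonImage(pt, 500.004, tolPpm = 10)
  expect_equal(img@featureMz, 500)
  expect_equal(img@values[1, ], c(4, 5))
  expect_true(is.na(img@values[2, 2]))  # unoccupied pixel
  ## 500.010 is 20 ppm away -> refused, nearest candidate named
  expect_error(getIonImage(pt, 500.010, tolPpm = 10),
               "feature not found.*500")
  ## exact query
  expect_equal(getIonImage(pt, 500, tolPpm = 10)@featureMz, 500)
  ## independence of feature order
  pt2 <- PeakTable(c(300, 500), rbind(c(1, 2, 3), c(4, 5, 6)),
                   cbind(x = c(0L, 1L, 0L), y = c(0L, 0L, 1L)))
  expect_equal(getIonImage(pt2, 500.004, 10)@values,
               img@values)
})

test_that("label maps and GMT libraries round-trip through disk", {
  lab <- matrix(c(0L, 1L, 2L, 2L), 2)
  m <- ROILabelMap(lab, c("1" = "slow", "2" = "fast"))
  csv <- tempfile(fileext = ".csv")
  writeLabelMap(m, csv)
  m2 <- readLabelMap(csv, labelNames = c("1" = "slow", "2" = "fast"))
  expect_identical(labelMatrix(m2), lab)
  pngf <- tempfile(fileext = ".png")
  writeLabelMap(m, pngf)
  expect_identical(labelMatrix(readLabelMap(pngf)), lab)

  sets <- list(tca = c("cit", "mal"), fao = c("c2", "c16", "c18"))
  gmt <- tempfile(fileext = ".gmt")
  writeGMT(sets, gmt)
  expect_identical(readGMT(gmt), sets)
  writeLines("empty\tdesc\t", gmt)
  expect_error(readGMT(gmt), "empty")
})
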