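# Spectrum-level preprocessing: baseline removal, RMS normalization, peak
# picking, cross-pixel peak alignment, and NaN-aware median denoising of
# ion images.

#' Morphological baseline removal
#'
#' Estimates the baseline of a profile spectrum by a morphological opening
#' (rolling minimum followed by rolling maximum, `window` bins wide) and
#' subtracts it, clipping at zero. Peaks narrower than the window survive
#' essentially untouched; smooth chemical background and matrix drift are
#' removed. The m/z axis is unchanged.
#'
#' @param s a profile-mode [Spectrum-class].
#' @param window structuring-element width in m/z bins (>= 3; even widths
#'   are promoted to the next odd integer).
#' @return A baseline-corrected [Spectrum-class].
#' @export
removeBaseline <- function(s, window = 51) {
  if (s@mode != "profile")
    stop("baseline removal expects a profile spectrum; ",
         "skip this step for centroided data")
  stopifnot(window >= 3)
  baseline <- runExtreme(runExtreme(s@intensity, window, "min"),
                         window, "max")
  Spectrum(s@mz, pmax(s@intensity - baseline, 0), mode = "profile")
}

#' Root-mean-square normalization
#'
#' Divides a spectrum by the root mean square of its intensities so the
#' normalized spectrum has RMS exactly 1; the factor is returned for
#' record keeping.
#'
#' @param s a [Spectrum-class] with at least one nonzero intensity.
#' @return A list with elements `spectrum` (normalized [Spectrum-class])
#'   and `factor` (`sqrt(mean(intensity^2))`).
#' @examples
#' rmsNormalize(Spectrum(c(100, 200), c(3, 4)))$factor  # sqrt(12.5)
#' @export
rmsNormalize <- function(s) {
  if (!any(s@intensity > 0))
    stop("all-zero spectrum: RMS normalization undefined")
  factor <- sqrt(mean(s@intensity^2))
  list(spectrum = Spectrum(s@mz, s@intensity / factor, mode = s@mode),
       factor = factor)
}

#' Peak picking by local maxima over a MAD noise floor
#'
#' Noise is estimated as `1.4826 * median(|I - median(I)|)` (the robust
#' MAD scale, insensitive to sparse peaks). Local maxima whose amplitude
#' above the noise floor -- `(I - median(I)) / noise` -- reaches `snrMin`
#' are reported; measuring the excursion above the floor rather than the
#' raw intensity keeps baseline-corrected noise (which is non-negative,
#' hence offset from zero) from clearing the gate. The apex m/z is
#' refined by parabolic interpolation of the log-intensities of the three
#' bins around the maximum (exact for a sampled Gaussian), so apex
#' positions are reproducible across pixels to well below one bin.
#'
#' @param s a baseline-corrected profile [Spectrum-class].
#' @param snrMin minimum signal-to-noise ratio (default 3).
#' @return A data.frame (`mz`, `intensity`, `snr`), the package's
#'   PeakList contract; zero rows when nothing clears the threshold.
#' @export
pickPeaks <- function(s, snrMin = 3) {
  y <- s@intensity
  n <- length(y)
  if (n < 3L) return(data.frame(mz = numeric(), intensity = numeric(),
                                snr = numeric()))
  med <- stats::median(y)
  noise <- 1.4826 * stats::median(abs(y - med))
  if (noise == 0) {
    pos <- y[y > 0]
    if (!length(pos))
      return(data.frame(mz = numeric(), intensity = numeric(),
                        snr = numeric()))
    noise <- min(pos)
    warning("zero MAD noise estimate; falling back to smallest positive intensity")
  }
  i <- 2:(n - 1L)
  snr <- (y - med) / noise
  isMax <- y[i] > y[i - 1L] & y[i] >= y[i + 1L] & snr[i] >= snrMin
  idx <- i[isMax]
  if (!length(idx))
    return(data.frame(mz = numeric(), intensity = numeric(),
                      snr = numeric()))
  ## parabolic apex refinement on log intensities
  apex <- vapply(idx, function(j) {
    y0 <- y[j - 1L]; y1 <- y[j]; y2 <- y[j + 1L]
    if (y0 <= 0 || y2 <= 0) return(s@mz[j])
    l0 <- log(y0); l1 <- log(y1); l2 <- log(y2)
    denom <- l0 - 2 * l1 + l2
    if (denom >= 0) return(s@mz[j])
    delta <- 0.5 * (l0 - l2) / denom
    delta <- max(min(delta, 0.5), -0.5)
    s@mz[j] + delta * (s@mz[min(j + 1L, n)] - s@mz[max(j - 1L, 1L)]) / 2
  }, numeric(1))
  ord <- order(apex)
  data.frame(mz = apex[ord], intensity = y[idx][ord],
             snr = snr[idx][ord])
}

#' Align per-pixel peak lists into a consensus peak table
#'
#' Pools all picked peaks, sorts them along m/z and cuts the pool wherever
#' the relative gap between consecutive peaks exceeds `tolPpm`
#' (single-linkage clustering at a ppm cut, the natural 1-D formulation).
#' Each cluster becomes one consensus feature whose m/z is the
#' intensity-weighted mean of its members; per pixel the apex intensity is
#' stored (max if a pixel contributed several member peaks, 0 if absent).
#' Features observed in fewer than `minPixelFraction` of pixels are
#' dropped.
#'
#' @param peakLists list of PeakList data.frames (one per pixel, as
#'   returned by [pickPeaks()]).
#' @param coords 0-based pixel coordinates, one row per peak list.
#' @param tolPpm positive clustering tolerance in ppm (default 10).
#' @param minPixelFraction minimum fraction of pixels a feature must
#'   appear in (default 0.01).
#' @param normalization tag recorded in the result (`"none"` or `"rms"`).
#' @return A [PeakTable-class].
#' @export
alignPeaks <- function(peakLists, coords, tolPpm = 10,
                       minPixelFraction = 0.01,
                       normalization = c("none", "rms")) {
  normalization <- match.arg(normalization)
  if (tolPpm <= 0) stop("tolPpm must be positive")
  coords <- asCoords(coords)
  stopifnot(length(peakLists) == nrow(coords))
  npix <- length(peakLists)
  sizes <- vapply(peakLists, nrow, integer(1))
  if (!any(sizes > 0)) stop("no peaks to align")
  mz <- unlist(lapply(peakLists, `[[`, "mz"), use.names = FALSE)
  int <- unlist(lapply(peakLists, `[[`, "intensity"), use.names = FALSE)
  pix <- rep.int(seq_len(npix), sizes)
  ord <- order(mz)
  mz <- mz[ord]; int <- int[ord]; pix <- pix[ord]
  ## single-linkage cut: new cluster where the consecutive relative gap
  ## exceeds tolPpm
  gapPpm <- diff(mz) / mz[-length(mz)] * 1e6
  cluster <- cumsum(c(1L, as.integer(gapPpm > tolPpm)))
  nclust <- cluster[length(cluster)]
  consMz <- vapply(split(seq_along(mz), cluster), function(ii) {
    w <- int[ii]
    if (sum(w) == 0) mean(mz[ii]) else sum(mz[ii] * w) / sum(w)
  }, numeric(1))
  mat <- matrix(0, nrow = nclust, ncol = npix)
  ## max apex intensity per (cluster, pixel)
  key <- (cluster - 1L) * npix + pix
  agg <- tapply(int, key, max)
  kk <- as.integer(names(agg)) - 1L
  mat[cbind(kk %/% npix + 1L, kk %% npix + 1L)] <- as.numeric(agg)
  present <- rowSums(mat > 0) / npix
  keep <- present >= minPixelFraction
  if (!any(keep)) stop("all features fall below minPixelFraction")
  ord2 <- order(consMz[keep])
  PeakTable(consMz[keep][ord2], mat[keep, , drop = FALSE][ord2, , drop = FALSE],
            coords, normalization = normalization)
}

#' NaN-aware median filtering of an ion image
#'
#' Replaces every occupied pixel by the median of its `kernel x kernel`
#' neighborhood, excluding `NA` (missing) pixels from the window; missing
#' pixels stay missing. The median filter preserves step edges between
#' homogeneous regions while removing single-pixel impulses, which is why
#' it is the standard denoiser for ion images feeding segmentation.
#'
#' @param img an [IonImage-class] (or bare numeric matrix).
#' @param kernel odd window edge length >= 3.
#' @return Same type as `img`, filtered.
#' @export
denoiseIonImage <- function(img, kernel = 3) {
  isS4img <- is(img, "IonImage")
  v <- if (isS4img) img@values else img
  if (kernel %% 2 != 1 || kernel < 3) stop("kernel must be an odd integer >= 3")
  h <- kernel %/% 2
  nr <- nrow(v); nc <- ncol(v)
  out <- v
  for (i in seq_len(nr)) {
    ri <- max(1L, i - h):min(nr, i + h)
    for (j in seq_len(nc)) {
      if (is.na(v[i, j])) next
      win <- v[ri, max(1L, j - h):min(nc, j + h)]
      out[i, j] <- stats::median(win, na.rm = TRUE)
    }
  }
  if (isS4img) IonImage(out, featureMz = img@featureMz, tolPpm = img@tolPpm)
  else out
}

#' Full spectrum-to-peak-table preprocessing chain
#'
#' Applies, per pixel: baseline removal (profile data), peak picking, ppm
#' alignment into a consensus table, then RMS normalization of each pixel
#' column over its picked (nonzero) features, so every normalized column
#' has RMS exactly 1. Centroided input skips baseline removal and picking.
#'
#' @param ds an [MSIDataset-class].
#' @param baselineWindow bins for [removeBaseline()].
#' @param snrMin for [pickPeaks()].
#' @param tolPpm,minPixelFraction for [alignPeaks()].
#' @param normalize logical; apply per-pixel RMS normalization (default
#'   TRUE).
#' @return A [PeakTable-class].
#' @export
processDataset <- function(ds, baselineWindow = 51, snrMin = 3,
                           tolPpm = 10, minPixelFraction = 0.01,
                           normalize = TRUE) {
  peakLists <- lapply(ds@spectra, function(s) {
    if (s@mode == "profile") {
      pickPeaks(removeBaseline(s, baselineWindow), snrMin = snrMin)
    } else {
      data.frame(mz = s@mz, intensity = s@intensity, snr = Inf)
    }
  })
  pt <- alignPeaks(peakLists, pixelCoords(ds), tolPpm = tolPpm,
                   minPixelFraction = minPixelFraction,
                   normalization = "none")
  if (normalize) rmsNormalizePixels(pt) else pt
}

#' Per-pixel RMS normalization of a peak table
#'
#' Divides every pixel column by the root mean square of its picked
#' (nonzero) feature intensities, so each normalized column has RMS 1
#' over the features observed in that pixel. Columns with no picked
#' features are left untouched.
#'
#' @param pt a [PeakTable-class].
#' @return The normalized [PeakTable-class] (tag `"rms"`).
#' @export
rmsNormalizePixels <- function(pt) {
  M <- intensityMatrix(pt)
  fac <- apply(M, 2L, function(v) {
    nz <- v[v > 0]
    if (!length(nz)) 1 else sqrt(mean(nz^2))
  })
  PeakTable(featureMz(pt), sweep(M, 2L, fac, "/"), pixelCoords(pt),
            normalization = "rms")
}
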