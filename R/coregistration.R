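# Co-registration of immunofluorescence-derived fiber-type masks onto the
# MSI pixel grid, and MSI-class vs fiber-type composition scoring.

#' Fit a similarity transform from landmark pairs
#'
#' Least-squares similarity transform (uniform scale + rotation +
#' translation, no reflection) minimizing the summed squared distance
#' between transformed source and destination landmarks. Adjacent thin
#' sections justify a rigid-plus-scale model; the closed-form solution
#' treats 2-D points as complex numbers (`dst ~ a * src + b` with
#' `a = scale * exp(i * rotation)`).
#'
#' @param src,dst matrices or data.frames of (x, y) landmark coordinates,
#'   >= 2 non-coincident pairs, `src` in mask pixels, `dst` in MSI pixels.
#' @return A [LandmarkTransform-class] with the achieved RMSE.
#' @examples
#' fitLandmarks(cbind(c(0, 1), c(0, 0)), cbind(c(5, 6), c(0, 0)))
#' @export
fitLandmarks <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 2L || nrow(dst) != nrow(src))
    stop("need at least 2 landmark pairs (equal counts)")
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- complex(real = dst[, 1], imaginary = dst[, 2])
  zc <- z - mean(z); wc <- w - mean(w)
  denom <- sum(Mod(zc)^2)
  if (denom == 0) stop("source landmarks are coincident")
  a <- sum(Conj(zc) * wc) / denom
  if (Mod(a) == 0) stop("degenerate landmark configuration")
  b <- mean(w) - a * mean(z)
  resid <- Mod(a * z + b - w)
  new("LandmarkTransform", scale = Mod(a), rotation = Arg(a),
      translation = c(Re(b), Im(b)),
      rmse = sqrt(mean(resid^2)))
}

applyTransform <- function(T, xy) {
  a <- complex(modulus = T@scale, argument = T@rotation)
  z <- complex(real = xy[, 1], imaginary = xy[, 2])
  w <- a * z + complex(real = T@translation[1], imaginary = T@translation[2])
  cbind(Re(w), Im(w))
}

invertTransform <- function(T, xy) {
  a <- complex(modulus = T@scale, argument = T@rotation)
  w <- complex(real = xy[, 1], imaginary = xy[, 2])
  z <- (w - complex(real = T@translation[1],
                    imaginary = T@translation[2])) / a
  cbind(Re(z), Im(z))
}

#' Resample a label mask onto the MSI grid
#'
#' Looks up, for every MSI pixel center, the nearest-neighbor label of the
#' source mask through the inverse transform. Labels are categorical, so
#' no interpolation is performed; out-of-bounds pixels become background
#' (0).
#'
#' @param mask an [ROILabelMap-class] in source (e.g. microscopy) pixels.
#' @param transform a fitted [LandmarkTransform-class] mapping mask
#'   coordinates to MSI coordinates.
#' @param gridRows,gridCols MSI grid extent (rows = y, cols = x).
#' @return An [ROILabelMap-class] on the MSI grid.
#' @export
resampleMask <- function(mask, transform, gridRows, gridCols) {
  src <- labelMatrix(mask)
  out <- matrix(0L, gridRows, gridCols)
  xy <- cbind(rep(seq_len(gridCols) - 1L, each = gridRows),
              rep(seq_len(gridRows), gridCols) - 1L)
  sxy <- invertTransform(transform, xy)
  sx <- round(sxy[, 1]); sy <- round(sxy[, 2])
  ok <- sx >= 0 & sx < ncol(src) & sy >= 0 & sy < nrow(src)
  out[cbind(xy[ok, 2] + 1L, xy[ok, 1] + 1L)] <-
    src[cbind(sy[ok] + 1L, sx[ok] + 1L)]
  ROILabelMap(out, labelNames = mask@labelNames)
}

#' MSI-class vs fiber-type composition
#'
#' Cross-tabulates pixels occupied in both label maps (MSI metabolic class
#' x fiber type), normalizes each class row to fractions, and converts
#' fractions to an ordinal 0-3 "+" score: the score is the number of band
#' thresholds less than or equal to the fraction. With the default bands
#' (0.05, 0.25, 0.50) a fraction of 0.04 scores 0 ("absent") and 0.5
#' scores 3 ("dominant").
#'
#' @param segLabels [ROILabelMap-class] of MSI classes.
#' @param fiberLabels [ROILabelMap-class] of fiber types, same grid.
#' @param bands strictly increasing thresholds in (0, 1).
#' @return A list with matrices `counts`, `row_fractions`, `scores`, and
#'   `glyphs` (the "+" rendering).
#' @export
composition <- function(segLabels, fiberLabels, bands = c(0.05, 0.25, 0.5)) {
  stopifnot(all(diff(bands) > 0), all(bands > 0 & bands < 1))
  a <- labelMatrix(segLabels); b <- labelMatrix(fiberLabels)
  if (!all(dim(a) == dim(b))) stop("label maps are on different grids")
  both <- a > 0 & b > 0
  if (!any(both)) stop("no pixels occupied in both label maps")
  counts <- as.matrix(table(factor(a[both]), factor(b[both])))
  names(dimnames(counts)) <- NULL
  fr <- counts / rowSums(counts)
  scores <- matrix(vapply(as.vector(fr), function(f) sum(bands <= f),
                          integer(1)),
                   nrow(fr), dimnames = dimnames(fr))
  glyphs <- matrix(strrep("+", scores), nrow(scores),
                   dimnames = dimnames(scores))
  list(counts = counts, row_fractions = fr, scores = scores,
       glyphs = glyphs)
}
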