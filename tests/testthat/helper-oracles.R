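# Independent oracles and small fixture builders used across test files.

## brute-force AUC: pairwise enumeration with 1/2 for ties
aucBrute <- function(x, pos) {
  xp <- x[pos]; xn <- x[!pos]
  wins <- 0
  for (a in xp) for (b in xn) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(xp) * length(xn))
}

## ICC(C,k) through R's own two-way ANOVA decomposition
iccAov <- function(m) {
  d <- data.frame(value = as.vector(m),
                  target = factor(rep(seq_len(nrow(m)), ncol(m))),
                  rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  fit <- stats::aov(value ~ target + rater, data = d)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / ms[1]
}

## minimal centroid dataset on a 1 x n strip
stripDataset <- function(intensityList, mz = c(200, 500, 800)) {
  sp <- lapply(intensityList, function(v) Spectrum(mz, v, mode = "centroid"))
  MSIDataset(sp, cbind(x = seq_along(intensityList) - 1L, y = 0L))
}

## Gaussian profile spectrum on a regular grid
gaussSpectrum <- function(center, amp, sigma = 0.35, from = 395, to = 405,
                          by = 0.05, noiseSd = 0, baseline = 0) {
  mz <- seq(from, to, by = by)
  y <- amp * exp(-(mz - center)^2 / (2 * sigma^2)) + baseline
  if (noiseSd > 0) y <- y + abs(rnorm(length(mz), 0, noiseSd))
  Spectrum(mz, y, mode = "profile")
}

gridToValues <- fiberMSI:::gridToValues
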