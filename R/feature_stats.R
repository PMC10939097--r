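# Per-feature univariate screening (pooled t, fold change, ROC AUC,
# two-way mixed ICC) and multivariate models (PCA, NIPALS PLS-DA with
# VIP-based biomarker selection).

#' Per-feature two-sample Student's t tests
#'
#' Pooled-variance (Student's) two-sample t per feature, vectorized across
#' the matrix, with two-sided p, log2 fold change of the group means and
#' Benjamini-Hochberg adjusted p. Welch's correction is available behind
#' `welch = TRUE`. A feature that is constant and equal in both groups
#' gets t = 0, p = 1.
#'
#' @param M sample x feature numeric matrix.
#' @param groups factor (or coercible) of length `nrow(M)` with exactly
#'   two levels; the first level is group A.
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @return data.frame with columns `feature`, `mean_a`, `mean_b`,
#'   `log2fc`, `t`, `p`, `p_adj` (the package's FeatureStats contract).
#' @export
ttestFeatures <- function(M, groups, welch = FALSE) {
  M <- as.matrix(M)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  ia <- groups == levels(groups)[1]
  na <- sum(ia); nb <- sum(!ia)
  if (na < 2L || nb < 2L) stop("need >= 2 samples per group")
  A <- M[ia, , drop = FALSE]; B <- M[!ia, , drop = FALSE]
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2L, stats::var); vb <- apply(B, 2L, stats::var)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, ncol(M))
  }
  t <- (ma - mb) / sqrt(se2)
  t[se2 == 0 & ma == mb] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0 & ma == mb] <- 1
  log2fc <- rep(NA_real_, ncol(M))
  ok <- ma > 0 & mb > 0
  log2fc[ok] <- log2(ma[ok] / mb[ok])
  feat <- colnames(M)
  if (is.null(feat)) feat <- as.character(seq_len(ncol(M)))
  data.frame(feature = feat, mean_a = ma, mean_b = mb, log2fc = log2fc,
             t = t, p = p, p_adj = stats::p.adjust(p, "BH"),
             row.names = NULL)
}

#' Per-feature ROC AUC screen
#'
#' Rank-based (Mann-Whitney) AUC per feature with midranks for ties:
#' the probability that a random sample from the positive group exceeds a
#' random sample from the other group (ties count 1/2). A feature is
#' flagged discriminative when AUC >= `aucMin` or AUC <= 1 - `aucMin`
#' (the symmetric reading of the one-sided screen, since direction depends
#' on group orientation).
#'
#' @param M sample x feature matrix.
#' @param groups two-level factor of length `nrow(M)`.
#' @param positive which group level counts as positive (default: second
#'   level).
#' @param aucMin discrimination threshold (default 0.7).
#' @return data.frame with `feature`, `auc`, `discriminative`.
#' @export
aucFeatures <- function(M, groups, positive = NULL, aucMin = 0.7) {
  M <- as.matrix(M)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (is.null(positive)) positive <- levels(groups)[2]
  pos <- groups == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both groups must be nonempty")
  auc <- apply(M, 2L, function(x) {
    r <- rank(x)  # midranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  feat <- colnames(M)
  if (is.null(feat)) feat <- as.character(seq_len(ncol(M)))
  data.frame(feature = feat, auc = auc,
             discriminative = auc >= aucMin | auc <= 1 - aucMin,
             row.names = NULL)
}

## ICC(C,k): two-way mixed model, consistency, average measures, from
## two-way ANOVA mean squares. x is a complete targets x raters matrix.
iccConsistency <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 targets and >= 2 raters")
  if (anyNA(x)) stop("complete target x rater matrix required")
  g <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - g)^2)           # between targets
  ssc <- n * sum((cm - g)^2)            # between raters
  sst <- sum((x - g)^2)
  sse <- sst - ssr - ssc
  ## guard float cancellation so perfect agreement returns exactly 1
  if (sse < 1e-12 * sst) sse <- 0
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0) {
    warning("zero between-target variance: ICC undefined")
    return(NaN)
  }
  (msr - mse) / msr
}

iccBand <- function(icc) {
  ifelse(is.na(icc), NA_character_,
    ifelse(icc >= 0.75, "excellent",
      ifelse(icc >= 0.60, "good",
        ifelse(icc >= 0.40, "fair", "poor"))))
}

#' Per-feature reproducibility ICC
#'
#' Intraclass correlation ICC(C,k) -- two-way mixed model, consistency,
#' average measures -- for each feature's complete target x rater matrix
#' (targets are e.g. sampled pixels or sections; raters are replicate
#' acquisitions). Computed from the two-way ANOVA mean squares as
#' `(MS_target - MS_error) / MS_target`. Reproducibility bands: >= 0.75
#' excellent, 0.60-0.75 good, 0.40-0.60 fair, < 0.40 poor.
#'
#' @param matrices a single targets x raters matrix or a (possibly named)
#'   list of them, one per feature.
#' @return data.frame with `feature`, `icc`, `icc_band`.
#' @export
iccFeatures <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  icc <- vapply(matrices, iccConsistency, numeric(1))
  feat <- names(matrices)
  if (is.null(feat)) feat <- as.character(seq_along(matrices))
  data.frame(feature = feat, icc = icc, icc_band = iccBand(icc),
             row.names = NULL)
}

#' Principal component analysis of a feature matrix
#'
#' Column-centered SVD PCA (via `prcomp`) with a deterministic sign
#' convention: per component, the largest-magnitude loading is made
#' positive. Explained-variance ratios are relative to total variance,
#' so the returned ratios sum to at most 1.
#'
#' @param M sample x feature matrix.
#' @param nComponents number of components (<= min(n samples - 1,
#'   n features)).
#' @param scale. logical, autoscale features (default FALSE).
#' @return list with `scores`, `loadings`, `explained_variance_ratio`.
#' @export
pcaFeatures <- function(M, nComponents = 2, scale. = FALSE) {
  M <- as.matrix(M)
  maxc <- min(nrow(M) - 1L, ncol(M))
  if (nComponents > maxc)
    stop("nComponents exceeds min(n_samples - 1, n_features) = ", maxc)
  pc <- stats::prcomp(M, center = TRUE, scale. = scale.)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  idx <- seq_len(nComponents)
  L <- pc$rotation[, idx, drop = FALSE]
  S <- pc$x[, idx, drop = FALSE]
  for (j in idx) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]; S[, j] <- -S[, j]
    }
  }
  list(scores = S, loadings = L, explained_variance_ratio = evr[idx])
}

#' PLS discriminant analysis with VIP scores
#'
#' NIPALS PLS2 on column-autoscaled X against dummy-coded (centered)
#' two-class membership. Per-feature Variable Importance in Projection:
#' `VIP_j = sqrt(p * sum_a(SSY_a * w_ja^2) / sum_a(SSY_a))` with unit
#' weight vectors, so `sum(VIP^2) = p` (the number of retained features)
#' for every fitted model. Constant feature columns are dropped with a
#' warning.
#'
#' @param M sample x feature matrix.
#' @param groups two-level factor of length `nrow(M)`.
#' @param nComponents number of latent components (default 2, capped at
#'   the data rank).
#' @return A [PLSDAModel-class].
#' @export
plsda <- function(M, groups, nComponents = 2) {
  M <- as.matrix(M)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  feat <- colnames(M)
  if (is.null(feat)) feat <- as.character(seq_len(ncol(M)))
  sdv <- apply(M, 2L, stats::sd)
  if (any(sdv == 0)) {
    warning("dropping constant feature column(s): ",
            paste(feat[sdv == 0], collapse = ", "))
    M <- M[, sdv > 0, drop = FALSE]
    feat <- feat[sdv > 0]
    sdv <- sdv[sdv > 0]
  }
  p <- ncol(M)
  if (p == 0L) stop("no non-constant features")
  X <- scale(M, center = TRUE, scale = TRUE)
  Y <- scale(stats::model.matrix(~ groups - 1), center = TRUE, scale = FALSE)
  n <- nrow(X)
  amax <- min(nComponents, n - 1L, p)
  ssyTot <- sum(Y^2)
  W <- P <- matrix(0, p, amax)
  Tm <- matrix(0, n, amax)
  ssy <- numeric(amax)
  Xa <- X; Ya <- Y
  a <- 0L
  for (comp in seq_len(amax)) {
    u <- Ya[, which.max(colSums(Ya^2))]
    if (sum(u^2) < 1e-12 * ssyTot) break
    w <- numeric(p)
    for (it in 1:500) {
      wNew <- crossprod(Xa, u)[, 1]
      nw <- sqrt(sum(wNew^2))
      if (nw == 0) break
      wNew <- wNew / nw
      tt <- Xa %*% wNew
      q <- crossprod(Ya, tt)[, 1] / sum(tt^2)
      uNew <- (Ya %*% q) / sum(q^2)
      if (sqrt(sum((wNew - w)^2)) < 1e-12) { w <- wNew; u <- uNew; break }
      w <- wNew; u <- uNew
    }
    if (sum(w^2) == 0) break
    tt <- Xa %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pl <- crossprod(Xa, tt)[, 1] / tt2
    q <- crossprod(Ya, tt)[, 1] / tt2
    a <- a + 1L
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- tt
    ssy[a] <- tt2 * sum(q^2)   # Y sum-of-squares explained by component a
    Xa <- Xa - tt %*% t(pl)
    Ya <- Ya - tt %*% t(q)
  }
  if (a == 0L) stop("PLS-DA failed: no informative component")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  ssy <- ssy[seq_len(a)]
  vip <- sqrt(p * as.numeric(W^2 %*% ssy) / sum(ssy))
  rownames(W) <- rownames(P) <- feat
  names(vip) <- feat
  new("PLSDAModel", nComponents = a, scores = Tm, xLoadings = P,
      weights = W, yVariancePerComp = ssy / ssyTot, vip = vip,
      featureNames = feat, groups = groups)
}

#' Select PLS-DA biomarkers by VIP and loading thresholds
#'
#' Keeps features with `VIP >= vipMin` and `|component-1 loading| >=
#' loadingMin` (defaults 1.0 and 0.05, the usual screening gates).
#'
#' @param model a fitted [PLSDAModel-class].
#' @param vipMin VIP threshold (default 1.0).
#' @param loadingMin absolute first-component loading threshold (default
#'   0.05).
#' @return character vector of selected feature names.
#' @export
selectBiomarkers <- function(model, vipMin = 1.0, loadingMin = 0.05) {
  keep <- model@vip >= vipMin & abs(model@xLoadings[, 1]) >= loadingMin
  model@featureNames[keep]
}
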