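# Univariate screening (t, AUC, ICC) and multivariate models (PCA,
# PLS-DA, VIP gates).

test_that("pooled t per feature matches t.test and the textbook example", {
  M <- cbind(f1 = c(1, 2, 3, 4, 5, 6), f2 = c(2, 2, 2, 5, 6, 7))
  g <- factor(rep(c("a", "b"), each = 3))
  st <- ttestFeatures(M, g)
  ## A = (1,2,3) vs B = (4,5,6): t = -3.674, p ~ 0.0214 on 4 df
  expect_equal(st$t[1], -3.674, tolerance = 1e-3)
  expect_equal(st$p[1], 0.0214, tolerance = 1e-2)
  expect_equal(st$p[1], 2 * pt(-abs(st$t[1]), 4), tolerance = 1e-12)
  ## agreement with stats::t.test across random matrices
  withr::with_seed(8, {
    X <- matrix(rnorm(10 * 6), 6)
    gg <- factor(rep(c("a", "b"), each = 3))
    stX <- ttestFeatures(X, gg)
    for (j in 1:10) {
      tt <- t.test(X[1:3, j], X[4:6, j], var.equal = TRUE)
      expect_equal(stX$t[j], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(stX$p[j], tt$p.value, tolerance = 1e-12)
    }
    wt <- ttestFeatures(X, gg, welch = TRUE)
    tw <- t.test(X[1:3, 1], X[4:6, 1])
    expect_equal(wt$t[1], unname(tw$statistic), tolerance = 1e-12)
    expect_equal(wt$p[1], tw$p.value, tolerance = 1e-12)
  })
  ## identical groups: t = 0, p = 1, log2fc = 0
  Mi <- cbind(c(1, 2, 3, 1, 2, 3))
  sti <- ttestFeatures(Mi, g)
  expect_equal(sti$t, 0)
  expect_equal(sti$p, 1)
  expect_equal(sti$log2fc, 0)
  ## equal means with nonzero variance: log2fc = 0
  Me <- cbind(c(1, 3, 2, 2, 1, 3))
  expect_equal(ttestFeatures(Me, g)$log2fc, 0)
})

test_that("rank AUC equals brute-force enumeration including ties", {
  g <- factor(c("a", "a", "b", "b"))
  ## A = (1,3), B = (2,4): 3 wins of 4 pairs -> 0.75
  expect_equal(aucFeatures(cbind(c(1, 3, 2, 4)), g)$auc, 0.75)
  ## all ties -> 0.5
  expect_equal(aucFeatures(cbind(rep(2, 4)), g)$auc, 0.5)
  ## complete separation -> 1
  g6 <- factor(rep(c("a", "b"), each = 3))
  r <- aucFeatures(cbind(c(1, 2, 3, 4, 5, 6)), g6)
  expect_equal(r$auc, 1)
  expect_true(r$discriminative)
  ## symmetric flag at the low side
  expect_true(aucFeatures(cbind(c(4, 5, 6, 1, 2, 3)), g6)$auc <= 0.3)
  ## oracle equivalence on random tied instances
  withr::with_seed(13, {
    for (i in 1:50) {
      n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
      x <- sample(1:6, n1 + n0, replace = TRUE)  # heavy ties
      pos <- c(rep(TRUE, n1), rep(FALSE, n0))
      g2 <- factor(ifelse(pos, "p", "n"), levels = c("n", "p"))
      expect_equal(aucFeatures(cbind(x), g2, positive = "p")$auc,
                   aucBrute(x, pos), tolerance = 1e-12)
    }
  })
})

test_that("ICC(C,k) matches the two-way ANOVA oracle and its bands", {
  ## raters identical, targets differ -> ICC exactly 1
  m1 <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(iccFeatures(m1)$icc, 1)
  ## worked 3 x 2 example against aov()
  m2 <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(iccFeatures(m2)$icc, iccAov(m2), tolerance = 1e-9)
  ## random matrices against the oracle
  withr::with_seed(14, {
    for (i in 1:20) {
      m <- matrix(rnorm(5 * 4), 5)
      icc <- iccFeatures(m)$icc
      expect_equal(icc, iccAov(m), tolerance = 1e-9)
      expect_lte(icc, 1)
    }
  })
  ## bands follow the 0.75 / 0.60 / 0.40 convention
  expect_identical(fiberMSI:::iccBand(c(0.8, 0.7, 0.5, 0.2)),
                   c("excellent", "good", "fair", "poor"))
  ## degenerate zero target variance
  expect_warning(r <- iccFeatures(matrix(1, 3, 2)), "undefined")
  expect_true(is.nan(r$icc))
})

test_that("Monte-Carlo ICC matches the variance-component closed form", {
  ## sigma2_T = sigma2_E = 1, k = 4 -> ICC(C,k) = 4 / (4 + 1) = 0.8
  withr::with_seed(15, {
    iccs <- vapply(1:400, function(i) {
      t <- rnorm(200)
      m <- t + matrix(rnorm(200 * 4), 200)
      fiberMSI:::iccConsistency(m)
    }, numeric(1))
  })
  expect_gte(mean(iccs), 0.78); expect_lte(mean(iccs), 0.82)
})

test_that("PCA fixes signs, bounds variance ratios and dedupes scores", {
  ## collinear data: PC1 explains everything
  M <- cbind(1:6, 2 * (1:6) + 3)
  p <- pcaFeatures(M, 2)
  expect_equal(p$explained_variance_ratio[1], 1)
  ## sign convention: largest-|loading| entry positive
  expect_true(all(apply(p$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
  ## isotropic 2-feature Gaussian: ratios near (0.5, 0.5)
  withr::with_seed(16, {
    G <- matrix(rnorm(2000), ncol = 2)
    pg <- pcaFeatures(G, 2)
    expect_lt(max(abs(pg$explained_variance_ratio - 0.5)), 0.05)
  })
  ## duplicated samples get identical scores
  D <- rbind(M, M[1, ])
  pd <- pcaFeatures(D, 2)
  expect_equal(pd$scores[1, ], pd$scores[7, ])
  expect_error(pcaFeatures(M, 5), "nComponents")
})

test_that("PLS-DA satisfies the VIP identity and ranks planted markers", {
  ## single feature, perfect separation: VIP exactly 1
  g <- factor(rep(c("a", "b"), each = 4))
  m1 <- plsda(cbind(f = c(1, 2, 1.5, 1.2, 9, 8, 9.5, 8.7)), g, 1)
  expect_equal(unname(m1@vip), 1)
  ## identity sum(VIP^2) = p on random fits
  withr::with_seed(17, {
    for (i in 1:10) {
      X <- matrix(rnorm(12 * 15), 12)
      gg <- factor(rep(c("a", "b"), each = 6))
      md <- plsda(X, gg, 2)
      expect_equal(sum(md@vip^2), length(md@vip),
                   tolerance = 1e-6 * length(md@vip))
      ## orthogonal score columns
      if (md@nComponents > 1)
        expect_lt(abs(crossprod(md@scores)[1, 2]) /
                    sqrt(prod(diag(crossprod(md@scores)))), 1e-8)
    }
  })
  ## 5 planted discriminative features out of 100 take the top VIP ranks
  withr::with_seed(18, {
    n <- 20
    X <- matrix(rnorm(n * 100), n)
    planted <- c(3, 20, 41, 77, 98)
    grp <- rep(c(0, 1), each = n / 2)
    X[, planted] <- X[, planted] + 3 * grp
    md <- plsda(X, factor(grp), 2)
    expect_setequal(order(-md@vip)[1:5], planted)
  })
  ## constant features are dropped with a warning
  expect_warning(
    plsda(cbind(a = c(1, 2, 1, 8, 9, 8), b = rep(1, 6)),
          factor(rep(c("x", "y"), each = 3)), 1),
    "constant")
})

test_that("our PLS-DA VIPs agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(19, {
    X <- matrix(rnorm(16 * 12), 16)
    colnames(X) <- paste0("f", 1:12)
    g <- factor(rep(c("a", "b"), each = 8))
    X[, 1:3] <- X[, 1:3] + 2 * (as.integer(g) - 1)
  })
  ours <- plsda(X, g, 2)
  ref <- mixOmics::plsda(X, g, ncomp = 2, scale = TRUE)
  vref <- mixOmics::vip(ref)[, 2]
  ## same ranking of feature importance and close values
  expect_gt(cor(ours@vip, vref, method = "spearman"), 0.95)
  expect_setequal(order(-ours@vip)[1:3], order(-vref)[1:3])
})

test_that("biomarker gate applies VIP >= 1 and |loading| >= 0.05", {
  ## pad with sub-threshold fillers so sum(VIP^2) = p holds exactly with
  ## the probe values untouched
  mkModel <- function(vip, load, fillers = 3) {
    fv <- sqrt((length(vip) + fillers - sum(vip^2)) / fillers)
    stopifnot(fv < 1)
    vip <- c(vip, rep(fv, fillers))
    load <- c(load, rep(0.5, fillers))
    p <- length(vip)
    new("PLSDAModel", nComponents = 1L,
        scores = matrix(0, 2, 1),
        xLoadings = matrix(load, p, 1),
        weights = matrix(1 / sqrt(p), p, 1),
        yVariancePerComp = 1, vip = vip,
        featureNames = paste0("f", seq_len(p)),
        groups = factor(c("a", "b")))
  }
  ## VIP 1.2 & loading 0.06 kept; VIP 0.9 dropped; loading 0.04 dropped
  m <- mkModel(c(1.2, 0.9, 1.5), c(0.06, 0.50, 0.04))
  sel <- selectBiomarkers(m, vipMin = 1.0, loadingMin = 0.05)
  expect_identical(sel, "f1")
  ## thresholds are inclusive (1.0 and |0.05| pass)
  m2 <- mkModel(c(1, 1.4), c(0.05, -0.05))
  expect_identical(selectBiomarkers(m2), c("f1", "f2"))
})

test_that("per-feature tests are calibrated under a permuted-label null", {
  withr::with_seed(20, {
    X <- matrix(rnorm(20 * 500), 20)
    g <- factor(rep(c("a", "b"), each = 10))
    st <- ttestFeatures(X, g)
  })
  expect_gte(mean(st$p < 0.05), 0.03)
  expect_lte(mean(st$p < 0.05), 0.07)
})
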