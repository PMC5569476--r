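test_that("kinship matches the per-element VanRaden formula", {
  sim <- simulatePopulationGenotypes(nMarkers = 30, nSamples = 6, seed = 14)
  K <- kinshipMatrix(sim$genotypes)
  d <- dosageMatrix(sim$genotypes)
  p <- rowMeans(d) / 2
  poly <- p > 0 & p < 1
  M <- d[poly, ] - 2 * p[poly]
  denom <- sum(2 * p[poly] * (1 - p[poly]))
  for (i in 1:6) for (j in 1:6)
    expect_equal(K[i, j], sum(M[, i] * M[, j]) / denom)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  # duplicated samples give identical rows and the largest off-diagonal
  cl <- calls(sim$genotypes)
  cl2 <- cbind(cl, dup = cl[, 1])
  K2 <- kinshipMatrix(cl2)
  expect_equal(unname(K2["dup", -c(1, 7)]), unname(K2[1, -c(1, 7)]))
  off <- K2[upper.tri(K2)]
  expect_equal(max(off), K2[1, "dup"])
  expect_error(kinshipMatrix(matrix("AA", 5, 4)), "polymorphic")
})

test_that("structure covariates span k - 1 dimensions plus an intercept", {
  sim <- simulatePopulationGenotypes(nMarkers = 500, nSamples = 60,
                                     nSubpops = 3, fst = 0.3, seed = 15)
  Q <- structureCovariates(sim$genotypes, 3)
  expect_identical(colnames(Q), c("intercept", "PC1", "PC2"))
  Q1 <- structureCovariates(sim$genotypes, 1)
  expect_identical(colnames(Q1), "intercept")
  # covariates separate the three groups (strong between-group signal)
  fit <- summary(stats::aov(Q[, "PC1"] ~ factor(sim$truth$subpop)))
  expect_lt(fit[[1]][["Pr(>F)"]][1], 1e-10)
})

test_that("MLM reduces to ordinary least squares when K is the identity", {
  sim <- simulatePopulationGenotypes(nMarkers = 60, nSamples = 50, seed = 16)
  gt <- sim$genotypes
  d <- dosageMatrix(gt)
  ph <- simulatePhenotype(gt, causal = 5, h2Snp = 0.2, h2Poly = 0, seed = 17)
  res <- mlmAssociation(ph$phenotype, gt, K = diag(ncol(d)), mafMin = 0)
  for (j in seq_len(nrow(res))) {
    x <- d[res$marker[j], ]
    if (var(x) == 0) next
    pOLS <- coef(summary(lm(ph$phenotype ~ x)))[2, 4]
    expect_lt(abs(res$p[j] - pOLS), 1e-8)
  }
})

test_that("P3D p-values match a fine grid-search REML oracle", {
  sim <- simulatePopulationGenotypes(nMarkers = 80, nSamples = 40,
                                     nSubpops = 2, fst = 0.2, seed = 18)
  gt <- sim$genotypes
  ph <- simulatePhenotype(gt, causal = 3, h2Snp = 0.2, h2Poly = 0.3,
                          seed = 19)
  K <- kinshipMatrix(gt)
  d <- dosageMatrix(gt)
  res <- mlmAssociation(ph$phenotype, gt, K = K, exact = TRUE)
  W <- matrix(1, ncol(d), 1)
  for (mk in res$marker[c(1, 5, 10)]) {
    o <- oracleMlmP(unname(ph$phenotype), W, d[mk, ], K)
    expect_lt(abs(res$p[match(mk, res$marker)] - o$p), 1e-6)
  }
})

test_that("singular fixed-effect designs are rejected with the column named", {
  sim <- simulatePopulationGenotypes(nMarkers = 50, nSamples = 30, seed = 20)
  Q <- cbind(intercept = 1, bad = 2,
             ok = rnorm(30))
  expect_error(mlmAssociation(rnorm(30), sim$genotypes, Q = Q), "bad")
})

test_that("significance thresholds reproduce the Bonferroni convention", {
  th <- significanceThresholds(54588)
  expect_equal(th$bonferroni, 1.8e-5)
  expect_equal(th$reporting, 1e-5)
  expect_equal(significanceThresholds(1)$bonferroni, 1)
  expect_equal(significanceThresholds(100)$bonferroni, 0.01)
  expect_error(significanceThresholds(0))
})

test_that("peak regions merge overlapping windows and attach genes", {
  res <- data.frame(marker = c("t1", "t2", "t3", "t4", "t5"),
                    chrom = c("D09", "D09", "D09", "D09", "D05"),
                    pos = c(3595148, 3793378, 3801945, 3812331, 8908622),
                    p = c(rep(1e-7, 4), 1e-6))
  ann <- data.frame(chrom = c("D09", "D09", "D05"),
                    start = c(3500000, 4500000, 9000000),
                    end = c(3510000, 4510000, 9010000),
                    type = "gene", id = c("g1", "g2", "g3"))
  rg <- peakRegionsAndGenes(res, annotation = ann)
  expect_equal(nrow(rg), 2)
  d09 <- rg[rg$chrom == "D09", ]
  expect_equal(c(d09$startMb, d09$endMb), c(3.10, 4.31))
  expect_equal(d09$nSNP, 4L)
  expect_identical(d09$genes, "g1")  # g2 lies outside the merged region
  d05 <- rg[rg$chrom == "D05", ]
  expect_equal(c(d05$startMb, d05$endMb), c(8.41, 9.41))
  expect_identical(d05$genes, "g3")
  # no significant SNPs
  expect_equal(nrow(peakRegionsAndGenes(transform(res, p = 1))), 0)
  # merging is idempotent and order-independent
  rg2 <- peakRegionsAndGenes(res[sample(nrow(res)), ], annotation = ann)
  expect_equal(rg2[order(rg2$chrom), c("chrom", "start", "end")],
               rg[order(rg$chrom), c("chrom", "start", "end")],
               ignore_attr = TRUE)
  expect_warning(
    peakRegionsAndGenes(res, annotation = ann[ann$chrom == "D09", ]),
    "D05")
})

test_that("Q+K controls structure-driven inflation better than naive OLS", {
  lambdaGC <- function(p) {
    chi <- qchisq(1 - p, df = 1)
    median(chi, na.rm = TRUE) / qchisq(0.5, df = 1)
  }
  devNaive <- devMLM <- numeric(3)
  for (r in 1:3) {
    sim <- simulatePopulationGenotypes(nMarkers = 800, nSamples = 120,
                                       nSubpops = 3, fst = 0.2,
                                       seed = 300 + r)
    gt <- sim$genotypes
    ph <- simulatePhenotype(gt, causal = 1, h2Snp = 0, h2Poly = 0.5,
                            seed = 400 + r)
    d <- dosageMatrix(gt)
    maf <- minorAlleleFreq(gt)
    sel <- which(maf > 0.05)
    pNaive <- vapply(sel, function(i)
      coef(summary(lm(ph$phenotype ~ d[i, ])))[2, 4], numeric(1))
    res <- mlmAssociation(ph$phenotype, gt,
                          Q = structureCovariates(gt, 3))
    devNaive[r] <- abs(lambdaGC(pNaive) - 1)
    devMLM[r] <- abs(lambdaGC(res$p) - 1)
  }
  expect_true(all(devMLM < devNaive))
})
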