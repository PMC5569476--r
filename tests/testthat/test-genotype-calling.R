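test_that("theta clustering recovers generated cluster counts", {
  set.seed(7)
  # well separated three-cluster locus
  th <- rep(c(0.05, 0.50, 0.95), each = 20)
  f <- fitThetaClusters(th, rep(1, 60))
  expect_equal(f$k, 3L)
  expect_equal(f$mean, c(0.05, 0.50, 0.95), tolerance = 1e-3)
  # all samples identical: single cluster
  f1 <- fitThetaClusters(rep(0.4, 30), rep(1, 30))
  expect_equal(f1$k, 1L)
  # five separated clusters
  th5 <- rep(c(0.03, 0.27, 0.50, 0.73, 0.97), each = 30) +
    rnorm(150, 0, 0.02)
  th5 <- pmin(pmax(th5, 0), 1)
  f5 <- fitThetaClusters(th5, rep(1, 150))
  expect_equal(f5$k, 5L)
  expect_equal(f5$mean, c(0.03, 0.27, 0.50, 0.73, 0.97), tolerance = 0.02)
})

test_that("markers with under two usable samples are failed", {
  f <- fitThetaClusters(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.5))
  expect_true(f$failed)
  expect_equal(callGenotypes(f, c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.5)),
               rep("--", 3))
})

test_that("cluster fit agrees with an independent mixture fitter", {
  library(mclust)
  set.seed(17)
  th <- c(rnorm(40, 0.05, 0.02), rnorm(30, 0.5, 0.02), rnorm(50, 0.95, 0.02))
  th <- pmin(pmax(th, 0), 1)
  f <- fitThetaClusters(th, rep(1, length(th)))
  mc <- mclust::Mclust(th, G = 1:5, modelNames = "V", verbose = FALSE)
  expect_equal(f$k, mc$G)
  expect_equal(f$mean, sort(unname(mc$parameters$mean)), tolerance = 0.01)
})

test_that("cluster adjustment merges close groups and relabels by rank", {
  cfg <- callingConfig()
  model <- list(k = 3L, mean = c(0.05, 0.15, 0.50), sd = rep(0.02, 3),
                weight = c(0.4, 0.2, 0.4), loglik = 0, bic = 0,
                nUsed = 100, failed = FALSE, merged = FALSE)
  adj <- adjustClusters(model, cfg)
  expect_equal(adj$k, 2L)
  expect_equal(adj$mean[1], (0.4 * 0.05 + 0.2 * 0.15) / 0.6)
  expect_identical(adj$diploid, c("AA", "AB"))
  expect_true(adj$merged)
  # single cluster untouched
  m1 <- list(k = 1L, mean = 0.04, sd = 0.02, weight = 1, loglik = 0,
             bic = 0, nUsed = 50, failed = FALSE, merged = FALSE)
  a1 <- adjustClusters(m1, cfg)
  expect_equal(a1$k, 1L)
  expect_identical(a1$diploid, "AA")
  # high-theta pair collapses into a single homozygous class
  m2 <- list(k = 2L, mean = c(0.88, 0.97), sd = rep(0.02, 2),
             weight = c(0.3, 0.7), loglik = 0, bic = 0, nUsed = 80,
             failed = FALSE, merged = FALSE)
  a2 <- adjustClusters(m2, cfg)
  expect_equal(a2$k, 1L)
  expect_identical(a2$diploid, "BB")
  # two homozygous clusters near 0 and 1 stay AA/BB
  m3 <- list(k = 2L, mean = c(0.05, 0.95), sd = rep(0.02, 2),
             weight = c(0.5, 0.5), loglik = 0, bic = 0, nUsed = 80,
             failed = FALSE, merged = FALSE)
  expect_identical(adjustClusters(m3, cfg)$diploid, c("AA", "BB"))
})

test_that("cluster adjustment is idempotent on fitted models", {
  set.seed(27)
  cfg <- callingConfig()
  for (i in 1:20) {
    k <- sample(1:5, 1)
    mu <- sort(runif(k))
    model <- list(k = as.integer(k), mean = mu,
                  sd = runif(k, 0.01, 0.05),
                  weight = as.vector(prop.table(runif(k) + 0.2)),
                  loglik = 0, bic = 0, nUsed = 100, failed = FALSE,
                  merged = FALSE)
    once <- adjustClusters(model, cfg)
    twice <- adjustClusters(once, cfg)
    expect_equal(twice[c("k", "mean", "sd", "weight", "diploid")],
                 once[c("k", "mean", "sd", "weight", "diploid")])
  }
})

test_that("per-sample calls follow the NG / off-cluster / nearest rules", {
  cfg <- callingConfig()
  model <- adjustClusters(list(k = 2L, mean = c(0.05, 0.95),
                               sd = rep(0.02, 2), weight = c(0.5, 0.5),
                               loglik = 0, bic = 0, nUsed = 100,
                               failed = FALSE, merged = FALSE), cfg)
  calls <- callGenotypes(model, c(0.04, 0.50, 0.96, 0.05),
                         c(1.2, 1.0, 1.0, 0.0), cfg)
  expect_identical(calls, c("AA", "--", "BB", "NG"))
})

test_that("locus patterns classify the canonical cluster-graph types", {
  cfg <- callingConfig()
  mk <- function(k, merged = FALSE, complex = FALSE, failed = FALSE)
    list(k = as.integer(k), merged = merged, complex = complex,
         failed = failed)
  expect_identical(classifyLocusPattern(mk(1), rep("AA", 5)), "monomorphic")
  expect_identical(classifyLocusPattern(mk(3), c("AA", "AB", "BB")),
                   "three_cluster")
  expect_identical(classifyLocusPattern(mk(2), c("AA", "BB")), "two_cluster")
  expect_identical(classifyLocusPattern(mk(3), c("AA", "NG", "BB")),
                   "partial_ng")
  expect_identical(classifyLocusPattern(mk(2, merged = TRUE),
                                        c("AA", "AB")), "polyploid_adjusted")
  expect_identical(classifyLocusPattern(mk(2), rep("--", 4)), "failed")
})

test_that("calling is deterministic and permutation-equivariant", {
  sim <- simulatePopulationGenotypes(nMarkers = 30, nSamples = 40, seed = 3)
  si <- simulateIntensities(sim$genotypes, sd = 0.03, ngRate = 0.05,
                            seed = 4)
  g1 <- calls(callGenotypeMatrix(si$intensities))
  g2 <- calls(callGenotypeMatrix(si$intensities))
  expect_identical(g1, g2)
  perm <- sample(ncol(g1))
  ieP <- IntensityExperiment(thetaMatrix(si$intensities)[, perm],
                             normRMatrix(si$intensities)[, perm])
  gP <- calls(callGenotypeMatrix(ieP))
  expect_identical(gP, g1[, perm])
})

test_that("tetraploid sub-cluster loci are merged and flagged", {
  sim <- simulatePopulationGenotypes(nMarkers = 20, nSamples = 120,
                                     mafBounds = c(0.3, 0.5), seed = 5)
  # AAAA/AAAB and ABBB/BBBB sub-clusters close enough to merge
  si <- simulateIntensities(sim$genotypes,
                            tetraMeans = c(0.05, 0.15, 0.5, 0.85, 0.95),
                            sd = 0.015, tetraFraction = 1, seed = 6)
  gt <- callGenotypeMatrix(si$intensities)
  rd <- SummarizedExperiment::rowData(gt)
  expect_gt(mean(rd$pattern == "polyploid_adjusted"), 0.5)
  # merged models still call the diploidized truth
  merged <- which(rd$merged)
  expect_gt(length(merged), 0)
  cl <- calls(gt)[merged, , drop = FALSE]
  tr <- si$truth$genotype[merged, , drop = FALSE]
  def <- cl %in% c("AA", "AB", "BB")
  expect_gt(mean(cl[def] == tr[def]), 0.99)
})
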