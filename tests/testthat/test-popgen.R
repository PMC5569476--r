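test_that("IBS distances follow allele sharing and match brute force", {
  cl <- cbind(a = c("AA", "AB"), b = c("AA", "AA"))
  d <- ibsDistanceMatrix(cl)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_equal(d["a", "b"], mean(c(0, 0.5)))
  # single-locus AA vs AB pair: distance one half
  d1 <- ibsDistanceMatrix(cbind(a = "AA", b = "AB"))
  expect_equal(d1["a", "b"], 0.5)
  set.seed(51)
  cl2 <- matrix(sample(c("AA", "AB", "BB", "--", "NG"), 100, TRUE,
                       prob = c(0.3, 0.2, 0.3, 0.1, 0.1)), 20, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
  expect_equal(ibsDistanceMatrix(cl2), oracleIBS(cl2))
  expect_error(ibsDistanceMatrix(cbind(a = "--", b = "AA")), "pair")
})

test_that("neighbor joining reconstructs a four-taxon additive matrix", {
  D <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 2,
                6, 6, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoiningTree(D)
  expect_equal(unname(as.matrix(stats::cophenetic(tr))[LETTERS[1:4],
                                                       LETTERS[1:4]]),
               unname(D), tolerance = 1e-10)
  # n = 3: closed-form branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr3 <- neighborJoiningTree(D3)
  cp <- as.matrix(stats::cophenetic(tr3))[letters[1:3], letters[1:3]]
  expect_equal(unname(cp), unname(D3), tolerance = 1e-10)
  # n = 2: single split with half the distance per edge
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- neighborJoiningTree(D2)
  expect_equal(sum(tr2$edge.length), 0.4)
})

test_that("neighbor joining is exact on random additive trees", {
  set.seed(61)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    ref <- ape::rtree(n, rooted = FALSE,
                      br = function(k) runif(k, 0.05, 1))
    D <- as.matrix(stats::cophenetic(ref))
    tr <- neighborJoiningTree(D)
    expect_equal(ape::dist.topo(ape::unroot(ref), tr), 0,
                 ignore_attr = TRUE)
    cp <- as.matrix(stats::cophenetic(tr))[rownames(D), colnames(D)]
    expect_equal(unname(cp), unname(D), tolerance = 1e-8)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("subpopulations form coherent clades in the NJ tree", {
  sim <- simulatePopulationGenotypes(nMarkers = 800, nSamples = 30,
                                     nSubpops = 3, fst = 0.2, seed = 12)
  D <- ibsDistanceMatrix(sim$genotypes)
  tr <- neighborJoiningTree(D)
  pops <- split(colnames(sim$genotypes), sim$truth$subpop)
  rooted <- ape::root(tr, outgroup = pops[[1]][1], resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, pops[[2]]))
  expect_true(ape::is.monophyletic(rooted, pops[[3]]))
})

test_that("PCA coordinates separate structured groups and respect identities", {
  sim <- simulatePopulationGenotypes(nMarkers = 1000, nSamples = 100,
                                     nSubpops = 2, fst = 0.3, seed = 13)
  pc <- pcaCoordinates(sim$genotypes, 3)
  expect_true(all(diff(pc$varExplained) <= 1e-12))
  g1 <- pc$coords[sim$truth$subpop == "pop1", 1]
  g2 <- pc$coords[sim$truth$subpop == "pop2", 1]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))
  # duplicated sample lands on identical coordinates
  cl <- calls(sim$genotypes)
  cl2 <- cbind(cl, dup = cl[, 1])
  pc2 <- pcaCoordinates(cl2, 2)
  expect_equal(pc2$coords["dup", ], pc2$coords[1, ])
  expect_error(pcaCoordinates(matrix("AA", 3, 4)), "monomorphic")
})

test_that("r2 and D-prime agree with closed forms and brute force", {
  # perfect correlation
  d1 <- c(0, 0, 1, 1, 2, 2)
  cl <- rbind(c("AA", "AA", "AB", "AB", "BB", "BB"),
              c("AA", "AA", "AB", "AB", "BB", "BB"))
  dimnames(cl) <- list(c("m1", "m2"), paste0("s", 1:6))
  ld <- ldStatistics(cl, chrom = c("c1", "c1"), pos = c(100, 200))
  expect_equal(ld$pairs$r2, 1)
  # coupling haplotypes only: AB x 10, ab x 10 -> r2 = D' = 1
  cl2 <- rbind(c(rep("BB", 5), rep("AA", 5)),
               c(rep("BB", 5), rep("AA", 5)))
  dimnames(cl2) <- list(c("m1", "m2"), paste0("s", 1:10))
  ld2 <- ldStatistics(cl2, chrom = rep("c1", 2), pos = c(1, 50))
  expect_equal(ld2$pairs$r2, 1)
  expect_equal(ld2$pairs$dPrime, 1)
  # r2 equals squared Pearson correlation computed by hand
  set.seed(71)
  x <- sample(0:2, 40, TRUE); y <- sample(0:2, 40, TRUE)
  clxy <- rbind(c("AA", "AB", "BB")[x + 1], c("AA", "AB", "BB")[y + 1])
  dimnames(clxy) <- list(c("m1", "m2"), paste0("s", 1:40))
  ldxy <- ldStatistics(clxy, chrom = c("c1", "c1"), pos = c(1, 10))
  expect_equal(ldxy$pairs$r2, cor(x, y)^2)
})

test_that("independent loci show near-zero mean r2 at large n", {
  set.seed(81)
  n <- 10000
  cl <- rbind(c("AA", "AB", "BB")[rbinom(n, 2, 0.4) + 1],
              c("AA", "AB", "BB")[rbinom(n, 2, 0.4) + 1])
  dimnames(cl) <- list(c("m1", "m2"), paste0("s", seq_len(n)))
  ld <- ldStatistics(cl, chrom = c("c1", "c1"), pos = c(1, 100))
  expect_lt(ld$pairs$r2, 0.01)
})

test_that("LD decay distance shrinks as recombination increases", {
  layout <- data.frame(chrom = "A01", length_bp = 3e6, subgenome = "At")
  dd <- vapply(c(2e-6, 1e-5, 5e-5), function(r) {
    sim <- simulatePopulationGenotypes(nMarkers = 150, nSamples = 80,
                                       nSubpops = 1, fst = 0,
                                       layout = layout, recombRate = r,
                                       seed = 91)
    ld <- ldStatistics(sim$genotypes, maxDist = 1e6, binWidth = 5e4)
    ld$decayDistance
  }, numeric(1))
  expect_false(any(is.na(dd)))
  expect_true(all(diff(dd) <= 0))
})
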