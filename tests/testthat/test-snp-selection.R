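test_that("hard filters remove each planted violation and report attrition", {
  cfg <- filterConfig()
  cand <- data.frame(
    id = paste0("s", 1:5),
    chrom = "A01",
    pos = c(1000, 5000, 9000, 13000, 17000),
    maf = c(0.30, 0.30, 0.30, 0.30, 0.08),       # s5 below MAF threshold
    het_rate = c(0.05, 0.05, 0.05, 0.20, 0.05),  # s4 too heterozygous
    accuracy = 1, multi_mapped = FALSE)
  mask <- data.frame(chrom = "A01", start = 4900, end = 5100)  # covers s2
  nbr <- data.frame(chrom = "A01", pos = 9040)                 # 40 bp from s3
  out <- applyHardFilters(cand, cfg, repeatMask = mask,
                          neighborVariants = nbr)
  expect_identical(out$candidates$id, "s1")
  rep <- out$report
  expect_identical(rep$stage,
                   c("maf", "accuracy", "repeat_region", "flanking_variant",
                     "heterozygosity", "uniqueness"))
  # totals conserve stage by stage and chain together
  expect_equal(rep$input, rep$removed + rep$surviving)
  expect_equal(rep$surviving[-nrow(rep)], rep$input[-1])
  expect_equal(rep$removed, c(1, 0, 1, 1, 1, 0))
})

test_that("empty candidate list yields empty survivors and all-zero report", {
  cand <- data.frame(id = character(), chrom = character(), pos = numeric(),
                     maf = numeric(), het_rate = numeric(),
                     accuracy = numeric(), multi_mapped = logical())
  out <- applyHardFilters(cand, filterConfig())
  expect_equal(nrow(out$candidates), 0)
  expect_true(all(out$report$input == 0 & out$report$removed == 0 &
                    out$report$surviving == 0))
})

test_that("interval and chromosome validation errors are raised", {
  cand <- data.frame(id = "s1", chrom = "A01", pos = 100, maf = 0.3,
                     het_rate = 0, accuracy = 1, multi_mapped = FALSE)
  expect_error(applyHardFilters(cand, filterConfig(),
                                repeatMask = data.frame(chrom = "A01",
                                                        start = 10, end = 5)),
               "end < start")
  expect_error(applyHardFilters(cand, filterConfig(),
                                repeatMask = data.frame(chrom = "Z99",
                                                        start = 1, end = 5)),
               "Z99")
  expect_error(applyHardFilters(cand, filterConfig(),
                                neighborVariants = data.frame(chrom = "Z98",
                                                              pos = 1)),
               "Z98")
})

test_that("design-score rule distinguishes genic and intergenic thresholds", {
  cfg <- filterConfig()
  cand <- data.frame(id = paste0("s", 1:4),
                     chrom = "A01", pos = 1:4,
                     region_class = c("genic", "genic", "intergenic",
                                      "intergenic"),
                     design_score = c(0.71, 0.69, 0.89, 0.91))
  kept <- applyDesignScoreRule(cand, cfg)
  expect_identical(kept$id, c("s1", "s4"))
  cand$design_score <- 1
  expect_identical(applyDesignScoreRule(cand, cfg)$id, cand$id)
  cand$design_score[2] <- NA
  expect_error(applyDesignScoreRule(cand, cfg), "s2")
})

test_that("spacing selection keeps the documented sets", {
  cand <- data.frame(id = paste0("s", 1:4), chrom = "A01",
                     pos = c(100, 1500, 2700, 5000))
  expect_equal(panelTable(selectSpacedMarkers(cand, 2100))$pos,
               c(100, 2700, 5000))
  one <- cand[1, ]
  expect_equal(length(selectSpacedMarkers(one, 2100)), 1)
  # all four inside one window: score_priority keeps exactly the top scorer
  cand$pos <- c(100, 500, 900, 1300)
  cand$design_score <- c(0.8, 0.95, 0.7, 0.9)
  sel <- selectSpacedMarkers(cand, 2100, mode = "score_priority")
  expect_identical(panelTable(sel)$id, "s2")
  dup <- rbind(cand, cand[1, ])
  expect_error(selectSpacedMarkers(dup, 2100), "duplicate")
})

test_that("max_count spacing equals the DP optimum on random instances", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(1:20, 1)
    pos <- sample.int(2e4, n)
    cand <- data.frame(id = sprintf("c%02d", seq_len(n)), chrom = "A01",
                       pos = pos)
    got <- length(selectSpacedMarkers(cand, 2100))
    expect_identical(got, oracleSpacingDP(pos, 2100))
  }
})

test_that("genic context annotation follows UTR > exon > intron precedence", {
  ann <- data.frame(chrom = "A01",
                    start = c(1000, 1000, 1500),
                    end = c(3000, 1200, 2000),
                    type = c("gene", "UTR", "exon"))
  cand <- data.frame(id = paste0("s", 1:4), chrom = "A01",
                     pos = c(1100, 1700, 2500, 5000))
  out <- annotateSnpContext(cand, ann)
  expect_equal(out$region_class, c("genic", "genic", "genic", "intergenic"))
  expect_equal(out$feature, c("UTR", "exon", "intron", "none"))
  # feature outside its gene span is ignored with a warning
  annBad <- rbind(ann, data.frame(chrom = "A01", start = 4900, end = 5100,
                                  type = "exon"))
  expect_warning(out2 <- annotateSnpContext(cand, annBad), "outside")
  expect_equal(out2$feature[4], "none")
})

test_that("panel summary reproduces the spacing definition and shares", {
  layout <- data.frame(chrom = c("A01", "A02"),
                       length_bp = c(99884700, 50e6),
                       subgenome = "At")
  # single marker on a chromosome of length L: average distance = L
  panel <- data.frame(chrom = "A02", pos = 1e6)
  s <- summarizePanel(panel, layout)
  ct <- s$chromTable
  expect_equal(ct$avgSpacingKb[ct$chrom == "A02"], 50e3)
  expect_true(is.na(ct$avgSpacingKb[ct$chrom == "A01"]))  # zero markers
  expect_equal(averageSpacingKb(3500, 99884.70), 28.5)
  # gap histogram shares sum to 100 within rounding
  panel2 <- data.frame(chrom = "A01",
                       pos = cumsum(c(1e3, rep(c(5e3, 15e3, 60e3), 10))))
  s2 <- summarizePanel(panel2, layout)
  expect_lt(abs(sum(s2$gapHist$sharePct) - 100), 0.02)
  expect_equal(sum(s2$gapHist$count), nrow(panel2) - 1)
  expect_error(summarizePanel(data.frame(chrom = "Z01", pos = 1), layout),
               "Z01")
})

test_that("cascade is idempotent and batching-invariant", {
  set.seed(21)
  cfg <- filterConfig()
  inst <- randomCandidateInstance(20, cfg)
  out1 <- applyHardFilters(inst$cand, cfg, inst$mask, inst$neighbors)
  again <- applyHardFilters(out1$candidates, cfg, inst$mask, inst$neighbors)
  expect_identical(again$candidates, out1$candidates)
  expect_true(all(again$report$removed == 0))
  # run in two chunks: union of survivors identical
  half <- nrow(inst$cand) %/% 2
  a <- applyHardFilters(inst$cand[seq_len(half), ], cfg, inst$mask,
                        inst$neighbors)$candidates
  b <- applyHardFilters(inst$cand[(half + 1):nrow(inst$cand), ], cfg,
                        inst$mask, inst$neighbors)$candidates
  expect_identical(sort(c(a$id, b$id)), sort(out1$candidates$id))
})

test_that("designPanel chains filters, score rule and spacing", {
  set.seed(31)
  sim <- simulateCandidateSet(nMarkers = 300,
                              fractions = list(repeat_region = 0.1,
                                               heterozygosity = 0.1),
                              seed = 5)
  out <- designPanel(sim$candidates, filterConfig(),
                     repeatMask = sim$repeatMask,
                     neighborVariants = sim$neighborVariants)
  expect_s4_class(out$panel, "MarkerPanel")
  expect_identical(tail(out$report$stage, 2), c("design_score", "spacing"))
  tb <- panelTable(out$panel)
  gaps <- unlist(tapply(tb$pos, tb$chrom, diff))
  expect_true(all(gaps > 2100))
})
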