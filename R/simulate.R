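## Seeded synthetic-data generators. Every generator returns the objects a
## downstream module consumes together with a `truth` component sufficient
## to score that module's output exactly.

#' Small example genome layout
#'
#' A toy allotetraploid layout: `nPerSubgenome` chromosomes in each of two
#' subgenomes (At, Dt), all of length `lengthBp`.
#'
#' @param nPerSubgenome Chromosomes per subgenome. Default 2.
#' @param lengthBp Chromosome length in bp. Default 5e6.
#' @return `data.frame(chrom, length_bp, subgenome)`.
#' @export
exampleGenomeLayout <- function(nPerSubgenome = 2, lengthBp = 5e6) {
  data.frame(
    chrom = c(sprintf("A%02d", seq_len(nPerSubgenome)),
              sprintf("D%02d", seq_len(nPerSubgenome))),
    length_bp = lengthBp,
    subgenome = rep(c("At", "Dt"), each = nPerSubgenome))
}

.placeMarkers <- function(nMarkers, layout) {
  prob <- layout$length_bp / sum(layout$length_bp)
  nPer <- drop(stats::rmultinom(1, nMarkers, prob))
  chrom <- rep(layout$chrom, nPer)
  pos <- unlist(lapply(seq_len(nrow(layout)), function(i) {
    if (nPer[i] == 0) return(numeric(0))
    if (nPer[i] > layout$length_bp[i])
      stop("more markers than placeable positions on ", layout$chrom[i])
    sort(sample.int(layout$length_bp[i], nPer[i]))
  }), use.names = FALSE)
  data.frame(chrom = chrom, pos = pos)
}

#' Simulate a candidate SNP universe for panel design
#'
#' Places candidates uniformly along the genome and plants controlled
#' fractions of violations of each design filter: repeat-region overlap,
#' a neighboring variant within the flank window, high heterozygosity, low
#' MAF, low accuracy, low design score and multi-mapped flanks. Violation
#' categories are disjoint and recorded per candidate in the truth table,
#' so each cascade stage can be checked against the planted set.
#'
#' @param nMarkers Number of candidates.
#' @param layout Genome layout (default [exampleGenomeLayout()]).
#' @param fractions Named list of violation fractions, any of
#'   `repeat_region`, `flanking_variant`, `heterozygosity`, `maf`,
#'   `accuracy`, `uniqueness`, `design_score`. Default all 0.
#' @param config [filterConfig()] supplying the thresholds the violations
#'   are planted against.
#' @param seed RNG seed.
#' @return List with `candidates` (manifest data.frame), `repeatMask`,
#'   `neighborVariants`, `annotation` (gene/exon/UTR intervals), `truth`
#'   (`violation` label per candidate, `"none"` for clean ones).
#' @export
simulateCandidateSet <- function(nMarkers = 500,
                                 layout = exampleGenomeLayout(),
                                 fractions = list(),
                                 config = filterConfig(),
                                 seed = 1) {
  set.seed(seed)
  pm <- .placeMarkers(nMarkers, layout)
  n <- nrow(pm)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  cand <- data.frame(
    id = sprintf("TM%05d", seq_len(n)),
    chrom = pm$chrom, pos = pm$pos, ref = ref, alt = alt,
    maf = stats::runif(n, config$mafMin, 0.5),
    het_rate = stats::runif(n, 0, 0.9 * config$hetMax),
    accuracy = stats::runif(n, (1 + config$accuracyMin) / 2, 1),
    design_score = NA_real_,
    multi_mapped = FALSE)

  ## gene structure: non-overlapping gene spans, one exon + one UTR each
  genes <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    ng <- max(1, round(layout$length_bp[i] / 2e5))
    width <- 5e3
    starts <- unique(sort(sample.int(layout$length_bp[i] - width, ng)))
    starts <- starts[c(TRUE, diff(starts) > width)]
    data.frame(chrom = layout$chrom[i], start = starts,
               end = starts + width - 1, type = "gene")
  }))
  feats <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    w <- g$end - g$start + 1
    rbind(data.frame(chrom = g$chrom, start = g$start,
                     end = g$start + round(0.1 * w), type = "UTR"),
          data.frame(chrom = g$chrom, start = g$start + round(0.2 * w),
                     end = g$start + round(0.6 * w), type = "exon"))
  }))
  annotation <- rbind(genes, feats)
  annotation$id <- c(sprintf("gene%04d", seq_len(nrow(genes))),
                     rep(NA, nrow(feats)))

  cand <- annotateSnpContext(cand, annotation)
  cand$design_score <- ifelse(
    cand$region_class == "genic",
    stats::runif(n, (1 + config$scoreGenicMin) / 2, 1),
    stats::runif(n, (1 + config$scoreIntergenicMin) / 2, 1))

  defaults <- list(repeat_region = 0, flanking_variant = 0,
                   heterozygosity = 0, maf = 0, accuracy = 0,
                   uniqueness = 0, design_score = 0)
  fr <- utils::modifyList(defaults, as.list(fractions))
  counts <- vapply(fr, function(f) round(f * n), numeric(1))
  if (sum(counts) > n) stop("violation fractions exceed 1")
  pool <- sample.int(n)
  violation <- rep("none", n)
  take <- function(k) {
    ix <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    ix
  }
  repeatMask <- data.frame(chrom = character(), start = numeric(),
                           end = numeric())
  neighborVariants <- data.frame(chrom = character(), pos = numeric())
  if (counts[["repeat_region"]] > 0) {
    ix <- take(counts[["repeat_region"]])
    violation[ix] <- "repeat_region"
    repeatMask <- data.frame(chrom = cand$chrom[ix],
                             start = pmax(cand$pos[ix] - 25, 1),
                             end = cand$pos[ix] + 25)
  }
  if (counts[["flanking_variant"]] > 0) {
    ix <- take(counts[["flanking_variant"]])
    violation[ix] <- "flanking_variant"
    neighborVariants <- data.frame(
      chrom = cand$chrom[ix],
      pos = cand$pos[ix] + sample(c(-1, 1), length(ix), TRUE) *
        sample.int(config$flankBp, length(ix), TRUE))
  }
  if (counts[["heterozygosity"]] > 0) {
    ix <- take(counts[["heterozygosity"]])
    violation[ix] <- "heterozygosity"
    cand$het_rate[ix] <- stats::runif(length(ix), config$hetMax, 1)
  }
  if (counts[["maf"]] > 0) {
    ix <- take(counts[["maf"]])
    violation[ix] <- "maf"
    cand$maf[ix] <- stats::runif(length(ix), 0, 0.95 * config$mafMin)
  }
  if (counts[["accuracy"]] > 0) {
    ix <- take(counts[["accuracy"]])
    violation[ix] <- "accuracy"
    cand$accuracy[ix] <- stats::runif(length(ix), 0, config$accuracyMin)
  }
  if (counts[["uniqueness"]] > 0) {
    ix <- take(counts[["uniqueness"]])
    violation[ix] <- "uniqueness"
    cand$multi_mapped[ix] <- TRUE
  }
  if (counts[["design_score"]] > 0) {
    ix <- take(counts[["design_score"]])
    violation[ix] <- "design_score"
    cand$design_score[ix] <- ifelse(
      cand$region_class[ix] == "genic",
      stats::runif(length(ix), 0, config$scoreGenicMin),
      stats::runif(length(ix), 0, config$scoreIntergenicMin))
  }
  list(candidates = cand, repeatMask = repeatMask,
       neighborVariants = neighborVariants, annotation = annotation,
       truth = data.frame(id = cand$id, violation = violation))
}

#' Simulate structured-population genotypes (Balding–Nichols)
#'
#' Ancestral allele frequencies are drawn uniformly from `mafBounds`; each
#' subpopulation draws its frequency from
#' `Beta(p (1 - Fst) / Fst, (1 - p)(1 - Fst) / Fst)` and genotypes follow
#' Hardy–Weinberg within subpopulations. `Fst = 0` collapses to the
#' ancestral frequencies, `Fst = 1` to fixation of one allele per
#' subpopulation. Optional linkage disequilibrium is produced by a latent
#' AR(1) (Markov) process along each haplotype with correlation
#' `exp(-recombRate * distance)` between adjacent markers.
#'
#' @param nMarkers,nSamples Problem size. Samples are split evenly across
#'   subpopulations.
#' @param nSubpops Number of subpopulations. Default 3.
#' @param fst Balding–Nichols differentiation. Default 0.2.
#' @param mafBounds Ancestral-frequency bounds. Default `c(0.1, 0.5)`.
#' @param layout Genome layout for marker placement.
#' @param missingRate Fraction of calls replaced by `--`. Default 0.
#' @param recombRate Per-bp decay rate of the latent haplotype correlation;
#'   `NULL` (default) for linkage equilibrium.
#' @param duplicateFirst Append a copy of the first sample (technical
#'   replicate) as an extra column? Default `FALSE`.
#' @param seed RNG seed.
#' @return List with `genotypes` (a [GenotypeExperiment-class] with
#'   `chrom`/`pos` rowData and `subpop` colData) and `truth`
#'   (`subpop`, `ancestralFreq`, `subpopFreq`, `dosage`).
#' @export
simulatePopulationGenotypes <- function(nMarkers = 1000, nSamples = 150,
                                        nSubpops = 3, fst = 0.2,
                                        mafBounds = c(0.1, 0.5),
                                        layout = exampleGenomeLayout(),
                                        missingRate = 0,
                                        recombRate = NULL,
                                        duplicateFirst = FALSE,
                                        seed = 1) {
  set.seed(seed)
  pm <- .placeMarkers(nMarkers, layout)
  m <- nrow(pm)
  p <- stats::runif(m, mafBounds[1], mafBounds[2])
  subFreq <- matrix(NA_real_, m, nSubpops)
  for (s in seq_len(nSubpops)) {
    subFreq[, s] <- if (fst <= 0) p
      else if (fst >= 1) as.numeric(stats::rbinom(m, 1, p))
      else stats::rbeta(m, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  }
  subpop <- rep(seq_len(nSubpops), length.out = nSamples)
  subpop <- sort(subpop)
  dos <- matrix(NA_real_, m, nSamples)
  if (is.null(recombRate)) {
    for (i in seq_len(nSamples))
      dos[, i] <- stats::rbinom(m, 2, subFreq[, subpop[i]])
  } else {
    ## latent AR(1) per haplotype within chromosome
    chromIdx <- split(seq_len(m), pm$chrom)
    for (i in seq_len(nSamples)) {
      f <- subFreq[, subpop[i]]
      hap <- matrix(0L, m, 2)
      for (h in 1:2) {
        for (ix in chromIdx) {
          k <- length(ix)
          if (k == 0) next
          z <- numeric(k)
          z[1] <- stats::rnorm(1)
          if (k > 1) {
            rho <- exp(-recombRate * diff(pm$pos[ix]))
            for (j in 2:k)
              z[j] <- rho[j - 1] * z[j - 1] +
                sqrt(1 - rho[j - 1]^2) * stats::rnorm(1)
          }
          hap[ix, h] <- as.integer(z < stats::qnorm(f[ix]))
        }
      }
      dos[, i] <- hap[, 1] + hap[, 2]
    }
  }
  cl <- matrix(c("AA", "AB", "BB")[dos + 1], m, nSamples)
  if (missingRate > 0)
    cl[stats::runif(length(cl)) < missingRate] <- "--"
  sn <- sprintf("S%03d", seq_len(nSamples))
  if (duplicateFirst) {
    cl <- cbind(cl, cl[, 1])
    dos <- cbind(dos, dos[, 1])
    subpop <- c(subpop, subpop[1])
    sn <- c(sn, paste0(sn[1], "_rep"))
  }
  dimnames(cl) <- list(sprintf("M%05d", seq_len(m)), sn)
  dimnames(dos) <- dimnames(cl)
  gt <- GenotypeExperiment(cl, chrom = pm$chrom, pos = pm$pos,
                           colData = DataFrame(
                             subpop = paste0("pop", subpop),
                             row.names = sn))
  list(genotypes = gt,
       truth = list(subpop = paste0("pop", subpop), ancestralFreq = p,
                    subpopFreq = subFreq, dosage = dos))
}

#' Simulate two-channel intensities from genotypes
#'
#' Theta values are drawn from Gaussians at the class means (truncated to
#' \[0, 1\]); normalized R is log-normal for samples with signal, and drawn
#' below the no-signal threshold for planted NG entries. In five-cluster
#' mode a fraction of markers behave as tetraploid loci: their homozygous
#' samples split between the outer and inner cluster of their side, and
#' heterozygotes sit at the middle cluster.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix (diploid
#'   truth classes).
#' @param clusterMeans Theta means for `AA`, `AB`, `BB`. Default
#'   `c(0.05, 0.5, 0.95)`.
#' @param tetraMeans Five theta means used for tetraploid-mode markers.
#'   Default `c(0.05, 0.275, 0.5, 0.725, 0.95)`; must be increasing.
#' @param sd Within-cluster theta standard deviation. Default 0.02.
#' @param ngRate Fraction of (marker, sample) entries planted as NG
#'   (no signal). Default 0.
#' @param tetraFraction Fraction of markers in five-cluster mode.
#'   Default 0.
#' @param ngRMin No-signal threshold the planted NG entries are drawn
#'   below. Default 0.2.
#' @param seed RNG seed.
#' @return List with `intensities` (an [IntensityExperiment-class]) and
#'   `truth` (`genotype` matrix, `ngMask`, `tetraMarkers`,
#'   `tetraClass` matrix of AAAA..BBBB labels for tetraploid markers).
#' @export
simulateIntensities <- function(genotypes,
                                clusterMeans = c(0.05, 0.5, 0.95),
                                tetraMeans = c(0.05, 0.275, 0.5, 0.725, 0.95),
                                sd = 0.02, ngRate = 0, tetraFraction = 0,
                                ngRMin = 0.2, seed = 1) {
  if (is.unsorted(clusterMeans, strictly = TRUE) ||
      is.unsorted(tetraMeans, strictly = TRUE))
    stop("cluster means must be strictly increasing")
  set.seed(seed)
  cl <- .asCallMatrix(genotypes)
  m <- nrow(cl); n <- ncol(cl)
  tetra <- stats::runif(m) < tetraFraction
  classIdx <- matrix(NA_integer_, m, n)   # index into the 5 tetra means
  classIdx[cl == "AA"] <- 1L
  classIdx[cl == "AB"] <- 3L
  classIdx[cl == "BB"] <- 5L
  if (any(tetra)) {
    ## homozygous samples of tetraploid markers split AAAA/AAAB (BBBB/ABBB)
    for (i in which(tetra)) {
      aa <- which(cl[i, ] == "AA")
      bb <- which(cl[i, ] == "BB")
      classIdx[i, aa] <- ifelse(stats::runif(length(aa)) < 0.5, 1L, 2L)
      classIdx[i, bb] <- ifelse(stats::runif(length(bb)) < 0.5, 5L, 4L)
    }
  }
  meanMat <- matrix(NA_real_, m, n)
  dip3 <- tetraMeans[c(1, 3, 5)]
  if (!all(abs(dip3 - clusterMeans) < .Machine$double.eps^0.5)) {
    ## honour clusterMeans for diploid-mode markers
    meanMat[!tetra, ] <- clusterMeans[(classIdx[!tetra, , drop = FALSE] + 1) %/% 2]
  } else {
    meanMat[!tetra, ] <- tetraMeans[classIdx[!tetra, , drop = FALSE]]
  }
  meanMat[tetra, ] <- tetraMeans[classIdx[tetra, , drop = FALSE]]
  theta <- matrix(pmin(pmax(stats::rnorm(m * n, meanMat, sd), 0), 1), m, n)
  theta[is.na(meanMat)] <- NA
  normR <- matrix(stats::rlnorm(m * n, meanlog = 0, sdlog = 0.3), m, n)
  ngMask <- matrix(stats::runif(m * n) < ngRate, m, n)
  normR[ngMask] <- stats::runif(sum(ngMask), 0, 0.9 * ngRMin)
  dimnames(theta) <- dimnames(normR) <- dimnames(ngMask) <- dimnames(cl)
  tetClass <- matrix(c("AAAA", "AAAB", "AABB", "ABBB", "BBBB")[classIdx],
                     m, n, dimnames = dimnames(cl))
  ie <- IntensityExperiment(theta, normR)
  list(intensities = ie,
       truth = list(genotype = cl, ngMask = ngMask,
                    tetraMarkers = which(tetra), tetraClass = tetClass))
}

#' Simulate an F1 from two parents
#'
#' Each F1 locus receives one allele drawn from each parent's genotype;
#' loci where the parents are opposite homozygotes are deterministically
#' heterozygous. Uncalled parent loci yield `--`.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix containing
#'   both parents.
#' @param parent1,parent2 Column names or indices.
#' @param f1Name Name of the new sample column. Default `"F1"`.
#' @param seed RNG seed.
#' @return A [GenotypeExperiment-class] (or matrix, matching the input)
#'   with the F1 appended.
#' @export
simulateTrio <- function(genotypes, parent1, parent2, f1Name = "F1",
                         seed = 1) {
  set.seed(seed)
  cl <- .asCallMatrix(genotypes)
  d <- dosageMatrix(cl)
  p1 <- d[, parent1]
  p2 <- d[, parent2]
  miss <- is.na(p1) | is.na(p2)
  a1 <- stats::rbinom(nrow(cl), 1, ifelse(miss, 0, p1 / 2))
  a2 <- stats::rbinom(nrow(cl), 1, ifelse(miss, 0, p2 / 2))
  f1 <- c("AA", "AB", "BB")[a1 + a2 + 1]
  f1[miss] <- "--"
  out <- cbind(cl, f1)
  colnames(out)[ncol(out)] <- f1Name
  if (is(genotypes, "GenotypeExperiment")) {
    cd <- colData(genotypes)
    cd <- rbind(cd, cd[parent1, , drop = FALSE])
    rownames(cd)[nrow(cd)] <- f1Name
    GenotypeExperiment(out, rowData = rowData(genotypes), colData = cd)
  } else out
}

#' Simulate a phenotype with a planted causal SNP
#'
#' `y = mu + beta * dosage(causal) + polygenic + noise`. The polygenic term
#' is drawn with covariance proportional to the VanRaden kinship of the
#' genotypes. Unless `beta` is given, the polygenic and noise draws are
#' made orthogonal (in sample) to the causal dosage and to each other and
#' every component is rescaled, so the realized variance fractions equal
#' `h2Snp` and `h2Poly` exactly (total variance 1). This pins the planted
#' effect size and makes the ground truth exact rather than
#' approximately-targeted; real phenotypes of course carry sampling
#' covariance between components.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix.
#' @param causal Marker name or index of the causal SNP (must be
#'   polymorphic).
#' @param h2Snp Variance fraction of the causal SNP. Default 0.1.
#' @param h2Poly Polygenic variance fraction. Default 0.3.
#' @param beta Optional fixed allele effect; overrides `h2Snp` scaling.
#' @param noiseSd Optional fixed residual standard deviation (with `beta`);
#'   `0` gives a noise-free phenotype.
#' @param mu Intercept. Default 0.
#' @param seed RNG seed.
#' @return List with `phenotype` (named numeric vector) and `truth`
#'   (`causal`, `beta`, realized variance components).
#' @export
simulatePhenotype <- function(genotypes, causal, h2Snp = 0.1, h2Poly = 0.3,
                              beta = NULL, noiseSd = NULL, mu = 0,
                              seed = 1) {
  set.seed(seed)
  d <- dosageMatrix(genotypes)
  x <- d[causal, ]
  if (any(is.na(x))) stop("causal SNP has missing calls")
  if (stats::var(x) == 0) stop("causal SNP is monomorphic")
  n <- ncol(d)
  sn <- colnames(d)
  g <- e <- numeric(n)
  if (h2Poly > 0) {
    K <- kinshipMatrix(genotypes)
    ch <- chol(K + diag(1e-8, n))
    g <- drop(crossprod(ch, stats::rnorm(n)))
  }
  eRaw <- stats::rnorm(n)
  if (is.null(beta)) {
    stopifnot(h2Snp + h2Poly <= 1)
    beta <- sqrt(h2Snp) / stats::sd(x)
    orth <- function(v, basis) {
      resid <- stats::lm.fit(cbind(1, basis), v)$residuals
      resid
    }
    if (h2Poly > 0) {
      g <- orth(g, x)
      g <- g / stats::sd(g) * sqrt(h2Poly)
    }
    h2Err <- 1 - h2Snp - h2Poly
    if (h2Err > 0) {
      e <- orth(eRaw, cbind(x, g))
      e <- e / stats::sd(e) * sqrt(h2Err)
    } else e <- 0 * eRaw
  } else {
    e <- if (is.null(noiseSd) || noiseSd == 0) 0 * eRaw else noiseSd * eRaw
    if (h2Poly == 0) g <- 0 * g
  }
  y <- mu + beta * x + g + e
  names(y) <- sn
  list(phenotype = y,
       truth = list(causal = causal, beta = beta,
                    varSnp = stats::var(beta * x), varPoly = stats::var(g),
                    varNoise = stats::var(e)))
}
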