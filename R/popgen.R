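## Population-genetic analyses on called genotypes: 1-IBS distances,
## neighbor-joining trees, PCA and linkage disequilibrium.

#' Alternate-allele dosage matrix
#'
#' Maps calls to 0 (`AA`), 1 (`AB`), 2 (`BB`); `NG` and `--` become `NA`.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix.
#' @return Numeric matrix, markers x samples.
#' @export
dosageMatrix <- function(genotypes) {
  cl <- .asCallMatrix(genotypes)
  d <- matrix(NA_real_, nrow(cl), ncol(cl), dimnames = dimnames(cl))
  d[cl == "AA"] <- 0
  d[cl == "AB"] <- 1
  d[cl == "BB"] <- 2
  d
}

#' 1-IBS distance matrix
#'
#' Identity-by-state for a called pair of genotypes at one locus is the
#' proportion of shared alleles: 1 for identical calls, 0.5 for
#' homozygote/heterozygote, 0 for opposite homozygotes. The pairwise
#' distance is one minus the mean IBS over co-called loci.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix
#'   (>= 2 samples).
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\]. A sample pair with no co-called loci is an error naming the
#'   pair.
#' @export
ibsDistanceMatrix <- function(genotypes) {
  d <- dosageMatrix(genotypes)
  n <- ncol(d)
  stopifnot(n >= 2)
  sn <- colnames(d)
  if (is.null(sn)) sn <- as.character(seq_len(n))
  out <- matrix(0, n, n, dimnames = list(sn, sn))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      if (!any(ok))
        stop("no co-called loci for pair ", sn[i], " / ", sn[j])
      dist <- mean(abs(d[ok, i] - d[ok, j])) / 2
      out[i, j] <- out[j, i] <- dist
    }
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining (via \code{\link[ape]{nj}}) on a 1-IBS
#' distance matrix. Negative branch lengths — an artifact of non-additive
#' distances — are clamped to zero, with the deficit transferred to the
#' branches incident at the same node so that path lengths through the node
#' are preserved where possible. On additive matrices the reconstruction is
#' exact and no clamping occurs.
#'
#' @param distances Symmetric distance matrix with sample dimnames
#'   (n >= 2).
#' @return An unrooted `phylo` tree. With exactly two samples, a single
#'   internal node joins the pair, each edge carrying half the distance.
#' @export
neighborJoiningTree <- function(distances) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  stopifnot(n >= 2, isSymmetric(unname(distances)))
  labs <- rownames(distances)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (n == 2) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(distances[1, 2] / 2, 2),
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(distances))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    child <- tr$edge[e, 2]
    adj <- which(tr$edge[, 1] == child)
    if (length(adj))
      tr$edge.length[adj] <- tr$edge.length[adj] + deficit
  }
  tr
}

#' Principal components of a genotype matrix
#'
#' Eigen-decomposition of the sample covariance of mean-centered allele
#' dosages. Missing dosages are imputed with the marker mean; monomorphic
#' markers are dropped. The sign of each component is fixed by making its
#' largest-magnitude marker loading positive.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix.
#' @param nComponents Number of components to return.
#' @param scale Scale markers to unit variance? Default `FALSE`.
#' @return A list of class `PcaResult`: `coords` (samples x components),
#'   `eigenvalues`, `varExplained`.
#' @export
pcaCoordinates <- function(genotypes, nComponents = 2, scale = FALSE) {
  d <- dosageMatrix(genotypes)
  stopifnot(ncol(d) >= 2)
  mns <- rowMeans(d, na.rm = TRUE)
  for (i in which(rowSums(is.na(d)) > 0)) d[i, is.na(d[i, ])] <- mns[i]
  v <- apply(d, 1, stats::var)
  d <- d[v > 0, , drop = FALSE]
  if (nrow(d) == 0) stop("all markers are monomorphic")
  nComponents <- min(nComponents, ncol(d) - 1, nrow(d))
  pc <- stats::prcomp(t(d), center = TRUE, scale. = scale)
  flip <- vapply(seq_len(nComponents), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(nComponents), drop = FALSE], 2, flip, "*")
  ev <- pc$sdev^2
  structure(list(coords = coords,
                 eigenvalues = ev[seq_len(nComponents)],
                 varExplained = (ev / sum(ev))[seq_len(nComponents)]),
            class = "PcaResult")
}

## Two-locus haplotype-frequency EM from unphased dosages. Only the
## double-heterozygote class is phase-ambiguous.
.haplotypeEM <- function(d1, d2, maxit = 100, tol = 1e-10) {
  ok <- !is.na(d1) & !is.na(d2)
  d1 <- d1[ok]; d2 <- d2[ok]
  n <- length(d1)
  if (n == 0) return(NULL)
  pA <- 1 - mean(d1) / 2   # frequency of allele 'a' (dosage-0 allele), locus 1
  pB <- 1 - mean(d2) / 2
  ## haplotypes: 11 = (a,b), 12 = (a,B), 21 = (A,b), 22 = (A,B)
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  h <- pmax(h, 1e-12); h <- h / sum(h)
  dh <- d1 == 1 & d2 == 1
  nDH <- sum(dh)
  ## Haplotype counts from unambiguous genotype classes. A sample with
  ## dosages (x, y) carries x alt / 2-x ref alleles at locus 1 (same at
  ## locus 2); the allele pairing is determined unless x == y == 1.
  k11 <- sum((d1 == 0) * (2 - d2) + (d1 == 1 & !dh) * (d2 == 0))
  k12 <- sum((d1 == 0) * d2 + (d1 == 1 & !dh) * (d2 == 2))
  k21 <- sum((d1 == 2) * (2 - d2) + (d1 == 1 & !dh) * (d2 == 0))
  k22 <- sum((d1 == 2) * d2 + (d1 == 1 & !dh) * (d2 == 2))
  if (nDH > 0) {
    for (it in seq_len(maxit)) {
      pCis <- h[1] * h[4] / max(h[1] * h[4] + h[2] * h[3], 1e-300)
      newh <- c(k11 + nDH * pCis, k12 + nDH * (1 - pCis),
                k21 + nDH * (1 - pCis), k22 + nDH * pCis) / (2 * n)
      if (max(abs(newh - h)) < tol) { h <- newh; break }
      h <- newh
    }
  } else {
    h <- c(k11, k12, k21, k22) / (2 * n)
  }
  list(h = h, pA = h[1] + h[2], pB = h[1] + h[3], n = n)
}

#' D-prime for one locus pair
#'
#' Lewontin's normalized disequilibrium coefficient from EM-estimated
#' haplotype frequencies of unphased genotypes.
#'
#' @param d1,d2 Dosage vectors (0/1/2, `NA` allowed) for the two loci.
#' @return `D'` in \[0, 1\], or `NA` when either locus is monomorphic.
#' @export
dPrime <- function(d1, d2) {
  em <- .haplotypeEM(d1, d2)
  if (is.null(em)) return(NA_real_)
  pA <- em$pA; pB <- em$pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  D <- em$h[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(NA_real_)
  min(abs(D) / dmax, 1)
}

#' Pairwise linkage disequilibrium and decay curve
#'
#' For every same-chromosome marker pair within `maxDist`, computes the
#' composite r-squared (squared Pearson correlation of allele dosages over
#' co-called samples — phase-free, appropriate for array genotypes) and
#' Lewontin's D' from EM haplotype frequencies. Mean r-squared per physical
#' distance bin gives the decay curve; the decay distance is the smallest
#' bin midpoint at which the smoothed curve (3-bin running mean) drops to
#' half its maximum.
#'
#' @param genotypes A [GenotypeExperiment-class] with `chrom`/`pos` in
#'   `rowData`, or a call matrix plus explicit `chrom`/`pos`.
#' @param chrom,pos Marker coordinates (only needed for plain matrices).
#' @param maxDist Maximum pair distance in bp. Default 1e6.
#' @param binWidth Decay-curve bin width in bp. Default 1e4.
#' @return A list of class `LdResult`: `pairs` (data.frame with `chrom`,
#'   `dist`, `r2`, `dPrime`), `decay` (bin midpoints and mean r2),
#'   `decayDistance` (bp, `NA` if the curve never falls to half maximum).
#'   Monomorphic members of a pair are skipped.
#' @export
ldStatistics <- function(genotypes, chrom = NULL, pos = NULL,
                         maxDist = 1e6, binWidth = 1e4) {
  d <- dosageMatrix(genotypes)
  if (is.null(chrom)) {
    mk <- .markerFrame(genotypes)
    if (is.null(mk)) stop("marker coordinates required")
    chrom <- mk$chrom; pos <- mk$pos
  }
  res <- list()
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    ix <- ix[order(pos[ix])]
    p <- pos[ix]
    for (a in seq_along(ix)) {
      b <- a + 1
      while (b <= length(ix) && p[b] - p[a] <= maxDist) {
        x <- d[ix[a], ]; y <- d[ix[b], ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) >= 2 && stats::var(x[ok]) > 0 && stats::var(y[ok]) > 0) {
          res[[length(res) + 1L]] <- data.frame(
            chrom = ch, dist = p[b] - p[a],
            r2 = stats::cor(x[ok], y[ok])^2,
            dPrime = dPrime(x, y))
        }
        b <- b + 1
      }
    }
  }
  pairs <- if (length(res)) do.call(rbind, res)
           else data.frame(chrom = character(), dist = numeric(),
                           r2 = numeric(), dPrime = numeric())
  decay <- .ldDecayCurve(pairs, maxDist, binWidth)
  structure(list(pairs = pairs, decay = decay,
                 decayDistance = .ldDecayDistance(decay)),
            class = "LdResult")
}

.ldDecayCurve <- function(pairs, maxDist, binWidth) {
  edges <- seq(0, maxDist, by = binWidth)
  if (edges[length(edges)] < maxDist) edges <- c(edges, maxDist)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- cut(pairs$dist, breaks = edges, include.lowest = TRUE,
             labels = FALSE)
  meanR2 <- vapply(seq_along(mids), function(i) {
    v <- pairs$r2[which(bin == i)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  data.frame(mid = mids, meanR2 = meanR2)
}

## Half-maximum crossing of the (lightly smoothed) binned decay curve.
.ldDecayDistance <- function(decay) {
  ok <- !is.na(decay$meanR2)
  if (sum(ok) < 2) return(NA_real_)
  x <- decay$mid[ok]; y <- decay$meanR2[ok]
  if (length(y) >= 3) {
    sm <- stats::filter(y, rep(1 / 3, 3), sides = 2)
    sm[1] <- mean(y[1:2]); sm[length(y)] <- mean(y[(length(y) - 1):length(y)])
    y <- as.numeric(sm)
  }
  half <- max(y) / 2
  hit <- which(y <= half)
  if (!length(hit)) return(NA_real_)
  x[hit[1]]
}

#' @export
print.LdResult <- function(x, ...) {
  cat("LdResult:", nrow(x$pairs), "marker pairs; decay distance",
      if (is.na(x$decayDistance)) "NA" else
        sprintf("%.0f bp", x$decayDistance), "\n")
  invisible(x)
}
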