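## Q+K mixed-linear-model association scan with peak-region merging and
## candidate-gene extraction.
##
## Model: y = mu + Q v + x beta + u + e, u ~ N(0, sg2 K), e ~ N(0, se2 I).
## Variance components are estimated by REML through the spectral
## decomposition of K; by default the null-model ratio lambda = sg2/se2 is
## reused for every marker (P3D), with exact per-marker REML behind a flag.

#' @importFrom GenomicRanges GRanges seqnames start end reduce findOverlaps
#' @importFrom IRanges IRanges
NULL

#' VanRaden kinship matrix
#'
#' Centered-dosage cross-product scaled by the total expected heterozygosity
#' `sum(2 p (1 - p))` over polymorphic markers. Missing dosages are imputed
#' with the marker mean, which leaves centered values of zero and so does
#' not bias relatedness.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix
#'   (>= 2 samples).
#' @return Symmetric positive-semidefinite samples x samples matrix.
#' @export
kinshipMatrix <- function(genotypes) {
  d <- dosageMatrix(genotypes)
  stopifnot(ncol(d) >= 2)
  mns <- rowMeans(d, na.rm = TRUE)
  for (i in which(rowSums(is.na(d)) > 0)) d[i, is.na(d[i, ])] <- mns[i]
  p <- rowMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers: kinship undefined")
  M <- d[poly, , drop = FALSE] - 2 * p[poly]
  crossprod(M) / sum(2 * p[poly] * (1 - p[poly]))
}

#' Population-structure covariates
#'
#' Top `k - 1` principal components of the dosage matrix plus an intercept.
#' Admixture proportions for `k` source populations sum to one and hence
#' span `k - 1` dimensions, so `k - 1` components are the PCA substitute
#' for a `k`-population structure matrix. An externally computed Q matrix
#' can be supplied to downstream functions instead.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix.
#' @param k Assumed number of source populations. `k < 2` yields the
#'   intercept only.
#' @return Numeric matrix with an `intercept` column and `k - 1` `PC`
#'   columns, rows aligned with samples.
#' @export
structureCovariates <- function(genotypes, k = 3) {
  cl <- .asCallMatrix(genotypes)
  n <- ncol(cl)
  sn <- colnames(cl)
  if (k < 2)
    return(matrix(1, n, 1, dimnames = list(sn, "intercept")))
  pc <- pcaCoordinates(genotypes, nComponents = k - 1)
  out <- cbind(intercept = 1, pc$coords)
  colnames(out) <- c("intercept", paste0("PC", seq_len(ncol(out) - 1)))
  rownames(out) <- sn
  out
}

## REML profile criterion for lambda = sg2/se2 on the rotated model.
## yt, Wt: data rotated by the eigenvectors of K; d: eigenvalues.
.remlNegLogLik <- function(logLambda, yt, Wt, d) {
  v <- exp(logLambda) * d + 1
  w <- 1 / v
  A <- crossprod(Wt, Wt * w)
  b <- crossprod(Wt, yt * w)
  coef <- solve(A, b)
  r <- yt - Wt %*% coef
  rss <- sum(w * r^2)
  np <- length(yt) - ncol(Wt)
  0.5 * (np * log(rss) + sum(log(v)) + determinant(A)$modulus[1])
}

.wls <- function(yt, Xt, w) {
  A <- crossprod(Xt, Xt * w)
  b <- crossprod(Xt, yt * w)
  coef <- solve(A, b)
  r <- yt - Xt %*% coef
  rss <- sum(w * r^2)
  list(coef = drop(coef), rss = rss, Ainv = solve(A))
}

#' Mixed-linear-model association scan
#'
#' Single-marker Q+K association tests. The null model (intercept + Q +
#' polygenic effect) is fit by REML on the spectral decomposition of K;
#' each marker is then tested by a Wald t-test on its dosage effect under
#' generalized least squares. By default the null variance-component ratio
#' is reused for every marker (P3D); `exact = TRUE` re-estimates it per
#' marker.
#'
#' @param phenotype Named numeric vector of trait values; names must match
#'   sample names. Missing values drop the sample.
#' @param genotypes A [GenotypeExperiment-class] or call matrix.
#' @param Q Optional covariate matrix including an intercept column (e.g.
#'   from [structureCovariates()]). Default: intercept only.
#' @param K Optional kinship matrix; default [kinshipMatrix()] of
#'   `genotypes`.
#' @param mafMin Markers below this MAF are excluded from the scan.
#'   Default 0.05.
#' @param exact Per-marker REML instead of P3D? Default `FALSE`.
#' @return `data.frame` of class `AssociationResult`: `marker`, `chrom`,
#'   `pos`, `maf`, `effect`, `se`, `p`, `logP` (-log10 p). Markers
#'   monomorphic after imputation get `NA`.
#' @export
mlmAssociation <- function(phenotype, genotypes, Q = NULL, K = NULL,
                           mafMin = 0.05, exact = FALSE) {
  cl <- .asCallMatrix(genotypes)
  sn <- colnames(cl)
  if (is.null(sn)) sn <- as.character(seq_len(ncol(cl)))
  if (!is.null(names(phenotype))) {
    keep <- sn[sn %in% names(phenotype)]
    phenotype <- phenotype[keep]
  } else {
    stopifnot(length(phenotype) == ncol(cl))
    names(phenotype) <- sn
    keep <- sn
  }
  keep <- keep[!is.na(phenotype[keep])]
  keepIdx <- match(keep, sn)
  y <- as.numeric(phenotype[keep])
  n <- length(y)
  cl <- cl[, keepIdx, drop = FALSE]

  maf <- .maf(cl)
  mk <- .markerFrame(genotypes)
  sel <- which(!is.na(maf) & maf > mafMin)
  d <- dosageMatrix(cl[sel, , drop = FALSE])
  mns <- rowMeans(d, na.rm = TRUE)
  for (i in which(rowSums(is.na(d)) > 0)) d[i, is.na(d[i, ])] <- mns[i]

  if (is.null(K)) {
    K <- kinshipMatrix(cl)
  } else {
    K <- if (!is.null(rownames(K))) K[keep, keep, drop = FALSE]
         else K[keepIdx, keepIdx, drop = FALSE]
  }
  if (is.null(Q)) {
    W <- matrix(1, n, 1, dimnames = list(keep, "intercept"))
  } else {
    W <- as.matrix(Q)
    W <- if (!is.null(rownames(W))) W[keep, , drop = FALSE]
         else W[keepIdx, , drop = FALSE]
  }
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    dropCols <- colnames(W)[qrW$pivot[(qrW$rank + 1):ncol(W)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(dropCols, collapse = ", "))
  }

  eig <- eigen(K, symmetric = TRUE)
  U <- eig$vectors
  ev <- pmax(eig$values, 0)
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)

  opt <- stats::optimize(.remlNegLogLik, c(-12, 12), yt = yt, Wt = Wt,
                         d = ev, tol = 1e-9)
  lambda0 <- exp(opt$minimum)

  m <- nrow(d)
  effect <- se <- p <- rep(NA_real_, m)
  Dt <- crossprod(U, t(d))   # rotated dosages, samples x markers
  for (j in seq_len(m)) {
    xt <- Dt[, j]
    if (stats::var(d[j, ]) == 0) next
    lam <- lambda0
    if (exact) {
      oj <- stats::optimize(.remlNegLogLik, c(-12, 12), yt = yt,
                            Wt = cbind(Wt, xt), d = ev, tol = 1e-9)
      lam <- exp(oj$minimum)
    }
    w <- 1 / (lam * ev + 1)
    fit <- .wls(yt, cbind(Wt, xt), w)
    df <- n - ncol(Wt) - 1
    sigma2 <- fit$rss / df
    b <- fit$coef[length(fit$coef)]
    sb <- sqrt(sigma2 * fit$Ainv[length(fit$coef), length(fit$coef)])
    effect[j] <- b
    se[j] <- sb
    p[j] <- 2 * stats::pt(-abs(b / sb), df)
  }

  out <- data.frame(
    marker = if (is.null(rownames(cl))) sel else rownames(cl)[sel],
    chrom = if (is.null(mk)) NA_character_ else mk$chrom[sel],
    pos = if (is.null(mk)) NA_real_ else mk$pos[sel],
    maf = maf[sel],
    effect = effect, se = se, p = p, logP = -log10(p),
    row.names = NULL)
  attr(out, "lambda") <- lambda0
  class(out) <- c("AssociationResult", "data.frame")
  out
}

#' Significance thresholds for a scan
#'
#' The Bonferroni family-wise threshold `1/n` (reported at two significant
#' figures, the conventional presentation) alongside a fixed reporting
#' threshold used to declare significant trait-associated SNPs.
#'
#' @param nMarkers Number of markers tested (>= 1).
#' @param fixedThreshold Reporting threshold. Default `1e-5`.
#' @return `list(bonferroni, reporting)`.
#' @examples
#' significanceThresholds(54588)$bonferroni  # 1.8e-05
#' @export
significanceThresholds <- function(nMarkers, fixedThreshold = 1e-5) {
  if (length(nMarkers) != 1 || is.na(nMarkers) || nMarkers < 1)
    stop("nMarkers must be a positive count")
  list(bonferroni = signif(1 / nMarkers, 2), reporting = fixedThreshold)
}

#' Merge significant SNPs into peak regions and attach genes
#'
#' Every SNP below `threshold` is expanded by `windowBp` on each side;
#' overlapping same-chromosome windows are merged, and genes whose spans
#' intersect a merged region are listed with it. Region bounds are also
#' reported in Mb at two decimals.
#'
#' @param results An `AssociationResult` (or data.frame with `marker`,
#'   `chrom`, `pos`, `p`).
#' @param threshold Significance threshold (strict `<`). Default `1e-5`.
#' @param windowBp Half-window in bp. Default `5e5`.
#' @param annotation Optional gene annotation ([readGeneAnnotation()]
#'   `GRanges` or `data.frame(chrom, start, end, type, id)`); only `gene`
#'   rows are used. Chromosomes absent from the annotation raise a warning
#'   and keep their regions without genes.
#' @param genomeLayout Optional `data.frame(chrom, length_bp)` used to clip
#'   regions to chromosome bounds (the lower bound is always clipped at 1).
#' @return `data.frame` of class `RegionSet`: `chrom`, `start`, `end`,
#'   `startMb`, `endMb`, `nSNP`, `snps` (comma-separated ids), `genes`.
#' @examples
#' res <- data.frame(marker = "snp1", chrom = "D05", pos = 8908622, p = 1e-6)
#' peakRegionsAndGenes(res)[, c("startMb", "endMb")]  # 8.41  9.41
#' @export
peakRegionsAndGenes <- function(results, threshold = 1e-5, windowBp = 5e5,
                                annotation = NULL, genomeLayout = NULL) {
  sig <- results[!is.na(results$p) & results$p < threshold, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), startMb = numeric(),
                      endMb = numeric(), nSNP = integer(),
                      snps = character(), genes = character())
  class(empty) <- c("RegionSet", "data.frame")
  if (nrow(sig) == 0) return(empty)

  start <- pmax(sig$pos - windowBp, 1)
  end <- sig$pos + windowBp
  if (!is.null(genomeLayout)) {
    lim <- stats::setNames(genomeLayout$length_bp, genomeLayout$chrom)
    has <- sig$chrom %in% names(lim)
    end[has] <- pmin(end[has], lim[sig$chrom[has]])
  }
  gr <- GRanges(sig$chrom, IRanges(start, end))
  merged <- reduce(gr)
  snpGr <- GRanges(sig$chrom, IRanges(sig$pos, sig$pos))
  hits <- findOverlaps(snpGr, merged)

  genes <- NULL
  if (!is.null(annotation)) {
    ann <- .asAnnotationFrame(annotation)
    ann <- ann[ann$type == "gene", , drop = FALSE]
    missing <- setdiff(unique(as.character(seqnames(merged))),
                       unique(ann$chrom))
    if (length(missing))
      warning("no gene annotation for chromosome(s): ",
              paste(missing, collapse = ", "))
    if (nrow(ann)) {
      gid <- if (!is.null(ann$id)) ann$id else
        paste0(ann$chrom, ":", ann$start, "-", ann$end)
      geneGr <- GRanges(ann$chrom, IRanges(ann$start, ann$end))
      gh <- findOverlaps(geneGr, merged)
      genes <- vapply(seq_along(merged), function(i)
        paste(gid[S4Vectors::queryHits(gh)[S4Vectors::subjectHits(gh) == i]],
              collapse = ","), character(1))
    }
  }

  out <- data.frame(
    chrom = as.character(seqnames(merged)),
    start = start(merged), end = end(merged),
    startMb = round(start(merged) / 1e6, 2),
    endMb = round(end(merged) / 1e6, 2),
    nSNP = as.integer(table(factor(S4Vectors::subjectHits(hits),
                                   levels = seq_along(merged)))),
    snps = vapply(seq_along(merged), function(i)
      paste(sig$marker[S4Vectors::queryHits(hits)[
        S4Vectors::subjectHits(hits) == i]], collapse = ","), character(1)),
    genes = if (is.null(genes)) NA_character_ else genes,
    row.names = NULL)
  class(out) <- c("RegionSet", "data.frame")
  out
}
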