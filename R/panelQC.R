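## Panel evaluation statistics: per-locus QC, replicate concordance,
## pairwise polymorphic rates, parent/F1 heterozygosity verification and
## subpopulation polymorphism summaries.
##
## Throughout, only definite genotypes (AA/AB/BB) enter denominators; NG
## and "--" are treated as non-called.

.asCallMatrix <- function(x) {
  if (is(x, "GenotypeExperiment")) assay(x, "calls") else as.matrix(x)
}

.markerFrame <- function(x) {
  if (is(x, "GenotypeExperiment")) {
    rd <- rowData(x)
    if (all(c("chrom", "pos") %in% names(rd)))
      return(data.frame(chrom = rd$chrom, pos = rd$pos,
                        row.names = rownames(x)))
  }
  NULL
}

#' Per-marker locus statistics
#'
#' Call rate, minor allele frequency, observed heterozygosity and a
#' polymorphism flag per marker. MAF comes from allele counts of the called
#' genotypes (AA contributes two reference alleles, AB one of each, BB two
#' alternate). A marker is polymorphic when its MAF is positive. Markers
#' with zero calls are flagged `undefined` with `NA` statistics rather than
#' propagating NaN.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix.
#' @return `data.frame(marker, nCalled, callRate, maf, het, polymorphic,
#'   undefined)`.
#' @examples
#' m <- matrix(c("AA","AA","AA","AA","AA","AA","AB","AB","BB","BB"), 1, 10)
#' locusStats(m)$maf  # 0.3
#' @export
locusStats <- function(genotypes) {
  cl <- .asCallMatrix(genotypes)
  nAA <- rowSums(cl == "AA"); nAB <- rowSums(cl == "AB")
  nBB <- rowSums(cl == "BB")
  n <- nAA + nAB + nBB
  p <- ifelse(n > 0, (2 * nAA + nAB) / (2 * n), NA_real_)
  maf <- pmin(p, 1 - p)
  data.frame(marker = if (is.null(rownames(cl))) seq_len(nrow(cl))
                      else rownames(cl),
             nCalled = n,
             callRate = n / ncol(cl),
             maf = maf,
             het = ifelse(n > 0, nAB / n, NA_real_),
             polymorphic = ifelse(n > 0, maf > 0, NA),
             undefined = n == 0,
             row.names = NULL)
}

.coCalled <- function(cl, a, b) {
  ca <- cl[, a]; cb <- cl[, b]
  ok <- ca %in% c("AA", "AB", "BB") & cb %in% c("AA", "AB", "BB")
  list(a = ca, b = cb, ok = ok)
}

#' Concordance between two samples
#'
#' Similarity is the percentage of identical calls over loci where both
#' samples have a definite genotype; the differing percentage (the pairwise
#' polymorphic rate) is its complement. A per-chromosome breakdown is
#' included when marker coordinates are available.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix.
#' @param sampleA,sampleB Column names or indices.
#' @return A list of class `ConcordanceResult`: `pair`, `nCoCalled`,
#'   `nIdentical`, `similarityPct`, `differingPct`, `undefined`, and
#'   optionally `byChrom`.
#' @export
sampleConcordance <- function(genotypes, sampleA, sampleB) {
  cl <- .asCallMatrix(genotypes)
  cc <- .coCalled(cl, sampleA, sampleB)
  nCo <- sum(cc$ok)
  res <- list(pair = c(as.character(sampleA), as.character(sampleB)),
              nCoCalled = nCo)
  if (nCo == 0) {
    res <- c(res, list(nIdentical = NA_integer_, similarityPct = NA_real_,
                       differingPct = NA_real_, undefined = TRUE))
  } else {
    nId <- sum(cc$a[cc$ok] == cc$b[cc$ok])
    res <- c(res, list(nIdentical = nId,
                       similarityPct = 100 * nId / nCo,
                       differingPct = 100 * (nCo - nId) / nCo,
                       undefined = FALSE))
    mk <- .markerFrame(genotypes)
    if (!is.null(mk)) {
      same <- cc$a == cc$b
      res$byChrom <- do.call(rbind, lapply(split(seq_len(nrow(cl)),
                                                 mk$chrom), function(ix) {
        ok <- cc$ok[ix]
        data.frame(chrom = mk$chrom[ix[1]], nCoCalled = sum(ok),
                   similarityPct = if (sum(ok)) 100 * mean(same[ix][ok])
                                   else NA_real_)
      }))
      rownames(res$byChrom) <- NULL
    }
  }
  class(res) <- "ConcordanceResult"
  res
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("Concordance %s vs %s: ", x$pair[1], x$pair[2]))
  if (isTRUE(x$undefined)) cat("undefined (no co-called loci)\n")
  else cat(sprintf("%.2f%% identical over %d co-called loci\n",
                   x$similarityPct, x$nCoCalled))
  invisible(x)
}

#' Pairwise polymorphic rate between two samples
#'
#' The percentage of co-called loci at which two samples differ — the
#' complement of [sampleConcordance()] similarity.
#'
#' @inheritParams sampleConcordance
#' @return Percentage in \[0, 100\], or `NA` when no loci are co-called.
#' @export
pairwisePolymorphicRate <- function(genotypes, sampleA, sampleB) {
  sampleConcordance(genotypes, sampleA, sampleB)$differingPct
}

#' Verify F1 heterozygosity in a parent/F1 trio
#'
#' Expected heterozygous loci are those where the two parents carry opposite
#' homozygous genotypes (AA vs BB) and all three samples are called; the
#' verification percentage is the share of those loci at which the F1 is
#' heterozygous (AB).
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix.
#' @param parent1,parent2,f1 Column names or indices of the trio.
#' @return A list of class `TrioResult`: `nExpected`, `nObserved`,
#'   `verificationPct`, `undefined`, `perLocus` (data.frame with locus ids
#'   and pass/fail), and `byChrom` when coordinates are available.
#' @export
verifyF1Heterozygosity <- function(genotypes, parent1, parent2, f1) {
  cl <- .asCallMatrix(genotypes)
  p1 <- cl[, parent1]; p2 <- cl[, parent2]; ch <- cl[, f1]
  called <- function(v) v %in% c("AA", "AB", "BB")
  opposite <- ((p1 == "AA" & p2 == "BB") | (p1 == "BB" & p2 == "AA"))
  expected <- opposite & called(ch)
  nExp <- sum(expected)
  if (nExp == 0) {
    res <- list(nExpected = 0L, nObserved = NA_integer_,
                verificationPct = NA_real_, undefined = TRUE,
                perLocus = NULL)
  } else {
    pass <- expected & ch == "AB"
    perLocus <- data.frame(
      marker = if (is.null(rownames(cl))) which(expected)
               else rownames(cl)[expected],
      f1Call = ch[expected],
      pass = pass[expected], row.names = NULL)
    res <- list(nExpected = nExp, nObserved = sum(pass),
                verificationPct = 100 * sum(pass) / nExp,
                undefined = FALSE, perLocus = perLocus)
    mk <- .markerFrame(genotypes)
    if (!is.null(mk)) {
      res$byChrom <- do.call(rbind, lapply(
        split(which(expected), mk$chrom[expected]), function(ix)
          data.frame(chrom = mk$chrom[ix[1]], nExpected = length(ix),
                     nObserved = sum(pass[ix]))))
      rownames(res$byChrom) <- NULL
    }
  }
  class(res) <- "TrioResult"
  res
}

#' @export
print.TrioResult <- function(x, ...) {
  if (isTRUE(x$undefined))
    cat("Trio verification: undefined (no expected heterozygous loci)\n")
  else
    cat(sprintf("Trio verification: %d/%d expected loci heterozygous (%.2f%%)\n",
                x$nObserved, x$nExpected, x$verificationPct))
  invisible(x)
}

#' Polymorphism summary by subpopulation
#'
#' For each sample group (and the union of all samples), counts the markers
#' that are polymorphic within the group, and those with within-group
#' MAF > 0.05 and MAF > 0.1. By construction the counts nest:
#' MAF>0.1 <= MAF>0.05 <= polymorphic <= total.
#'
#' @param genotypes A [GenotypeExperiment-class] or call matrix.
#' @param metadata `data.frame` with `sample` and `group` columns covering
#'   every sample, or a named group vector.
#' @return `data.frame(group, nAccessions, polymorphic, mafGt05, mafGt10)`
#'   with an `Overall` row appended. Groups with fewer than two samples
#'   raise a warning but are still summarized.
#' @export
subpopulationSummary <- function(genotypes, metadata) {
  cl <- .asCallMatrix(genotypes)
  if (is.data.frame(metadata)) {
    stopifnot(all(c("sample", "group") %in% names(metadata)))
    groups <- stats::setNames(as.character(metadata$group),
                              as.character(metadata$sample))
  } else groups <- metadata
  sn <- colnames(cl)
  if (is.null(sn)) sn <- as.character(seq_len(ncol(cl)))
  if (!all(sn %in% names(groups)))
    stop("every sample needs a group label")
  groups <- groups[sn]
  small <- names(table(groups))[table(groups) < 2]
  if (length(small))
    warning("group(s) with < 2 samples: ", paste(small, collapse = ", "))
  row1 <- function(label, idx) {
    maf <- .maf(cl[, idx, drop = FALSE])
    data.frame(group = label, nAccessions = length(idx),
               polymorphic = sum(maf > 0, na.rm = TRUE),
               mafGt05 = sum(maf > 0.05, na.rm = TRUE),
               mafGt10 = sum(maf > 0.1, na.rm = TRUE))
  }
  out <- do.call(rbind, lapply(unique(groups), function(g)
    row1(g, which(groups == g))))
  rbind(out, row1("Overall", seq_len(ncol(cl))))
}
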