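## Candidate-filter cascade and spacing selection for array panel design.

#' Filter configuration for array panel design
#'
#' Thresholds of the candidate-filter cascade. Defaults reflect common
#' Infinium design practice for an intraspecific polyploid array: candidates
#' must have minor allele frequency of at least `mafMin`, a re-sequencing
#' genotype accuracy above `accuracyMin`, no other variant within `flankBp`
#' of the site, a heterozygosity rate below `hetMax`, probe design scores
#' above 0.7 (genic) / 0.9 (intergenic), and selected markers must be more
#' than `minGapBp` apart.
#'
#' @param mafMin Minimum minor allele frequency (inclusive). Default 0.1.
#' @param accuracyMin Genotype-accuracy threshold (exclusive). Default 0.9912.
#' @param flankBp Exclusion window for neighboring variants, bp each side.
#' @param hetMax Maximum heterozygosity rate (exclusive). Default 0.15.
#' @param scoreGenicMin,scoreIntergenicMin Design-score thresholds
#'   (exclusive) for genic and intergenic candidates.
#' @param minGapBp Minimum distance between adjacent selected markers
#'   (exclusive). Default 2100.
#' @param dropMultiMapped Drop candidates whose flanking sequence maps to
#'   multiple (e.g. homeologous) locations? Default `TRUE`.
#' @return A list of class `FilterConfig`.
#' @export
filterConfig <- function(mafMin = 0.1, accuracyMin = 0.9912, flankBp = 50,
                         hetMax = 0.15, scoreGenicMin = 0.7,
                         scoreIntergenicMin = 0.9, minGapBp = 2100,
                         dropMultiMapped = TRUE) {
  stopifnot(mafMin >= 0, mafMin <= 0.5, accuracyMin >= 0, accuracyMin <= 1,
            flankBp >= 0, hetMax >= 0, hetMax <= 1,
            scoreGenicMin >= 0, scoreGenicMin <= 1,
            scoreIntergenicMin >= 0, scoreIntergenicMin <= 1,
            minGapBp > 0)
  structure(list(mafMin = mafMin, accuracyMin = accuracyMin,
                 flankBp = flankBp, hetMax = hetMax,
                 scoreGenicMin = scoreGenicMin,
                 scoreIntergenicMin = scoreIntergenicMin,
                 minGapBp = minGapBp, dropMultiMapped = dropMultiMapped),
            class = "FilterConfig")
}

.checkIntervals <- function(iv, chroms, what) {
  if (is.null(iv) || nrow(iv) == 0) return(invisible(NULL))
  if (any(iv$end < iv$start))
    stop("malformed interval (end < start) in ", what)
  bad <- setdiff(unique(iv$chrom), chroms)
  if (length(bad))
    stop("unknown chromosome in ", what, ": ", paste(bad, collapse = ", "))
  invisible(NULL)
}

#' Apply the hard candidate filters
#'
#' Runs the filter cascade in a fixed order — MAF, accuracy, repeat regions,
#' flanking variants, heterozygosity, uniqueness — and records stage-by-stage
#' attrition. The fixed order makes the per-stage report reproducible; the
#' surviving set itself is order-independent because each rule is a
#' per-candidate predicate.
#'
#' @param candidates `data.frame` with columns `id`, `chrom`, `pos`, `maf`,
#'   `het_rate`, `accuracy` and (if `dropMultiMapped`) `multi_mapped`.
#' @param config A [filterConfig()].
#' @param repeatMask Optional `data.frame(chrom, start, end)` of repeat
#'   intervals, 1-based inclusive (BED files are converted on read, see
#'   [readBedMask()]).
#' @param neighborVariants Optional `data.frame(chrom, pos)` of other
#'   variants (SNPs/In-Dels). A candidate is removed when any of these lies
#'   within `flankBp` of its site. The candidates themselves must not be
#'   included in this set.
#' @return `list(candidates = survivors, report = FilterReport)`, the report
#'   being a `data.frame(stage, input, removed, surviving)`.
#' @examples
#' cand <- data.frame(id = c("s1", "s2"), chrom = "A01", pos = c(100, 200),
#'                    maf = c(0.3, 0.05), het_rate = 0, accuracy = 1,
#'                    multi_mapped = FALSE)
#' applyHardFilters(cand, filterConfig())$report
#' @export
applyHardFilters <- function(candidates, config = filterConfig(),
                             repeatMask = NULL, neighborVariants = NULL) {
  stopifnot(inherits(config, "FilterConfig"))
  if (nrow(candidates)) {
    chroms <- unique(candidates$chrom)
    .checkIntervals(repeatMask, chroms, "repeat mask")
    if (!is.null(neighborVariants) && nrow(neighborVariants)) {
      bad <- setdiff(unique(neighborVariants$chrom), chroms)
      if (length(bad))
        stop("unknown chromosome in neighbor variants: ",
             paste(bad, collapse = ", "))
    }
  }

  inRepeat <- function(df) {
    if (is.null(repeatMask) || nrow(repeatMask) == 0 || nrow(df) == 0)
      return(rep(FALSE, nrow(df)))
    hit <- rep(FALSE, nrow(df))
    for (ch in unique(repeatMask$chrom)) {
      iv <- repeatMask[repeatMask$chrom == ch, , drop = FALSE]
      sel <- which(df$chrom == ch)
      if (!length(sel)) next
      hit[sel] <- vapply(df$pos[sel], function(p)
        any(p >= iv$start & p <= iv$end), logical(1))
    }
    hit
  }
  nearNeighbor <- function(df) {
    if (is.null(neighborVariants) || nrow(neighborVariants) == 0 ||
        nrow(df) == 0)
      return(rep(FALSE, nrow(df)))
    hit <- rep(FALSE, nrow(df))
    for (ch in unique(neighborVariants$chrom)) {
      np <- sort(neighborVariants$pos[neighborVariants$chrom == ch])
      sel <- which(df$chrom == ch)
      if (!length(sel)) next
      hit[sel] <- vapply(df$pos[sel], function(p)
        any(abs(np - p) <= config$flankBp), logical(1))
    }
    hit
  }

  stages <- list(
    maf = function(df) df$maf >= config$mafMin,
    accuracy = function(df) df$accuracy > config$accuracyMin,
    repeat_region = function(df) !inRepeat(df),
    flanking_variant = function(df) !nearNeighbor(df),
    heterozygosity = function(df) df$het_rate < config$hetMax,
    uniqueness = function(df)
      if (config$dropMultiMapped) !df$multi_mapped else rep(TRUE, nrow(df))
  )

  cur <- candidates
  rep_rows <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    keep <- stages[[i]](cur)
    if (nrow(cur) == 0) keep <- logical(0)
    rep_rows[[i]] <- data.frame(stage = names(stages)[i],
                                input = nrow(cur),
                                removed = sum(!keep),
                                surviving = sum(keep))
    cur <- cur[keep, , drop = FALSE]
  }
  list(candidates = cur, report = do.call(rbind, rep_rows))
}

#' Apply the probe design-score rule
#'
#' Genic candidates must exceed `scoreGenicMin`, intergenic candidates the
#' stricter `scoreIntergenicMin` (their flanking sequence lacks the
#' conservation that makes genic probes easier to design against a single
#' locus).
#'
#' @inheritParams applyHardFilters
#' @return The surviving candidates.
#' @export
applyDesignScoreRule <- function(candidates, config = filterConfig()) {
  if (nrow(candidates) == 0) return(candidates)
  if (!all(c("design_score", "region_class") %in% names(candidates)))
    stop("candidates need 'design_score' and 'region_class' columns")
  missing <- is.na(candidates$design_score)
  if (any(missing))
    stop("missing design_score for: ",
         paste(candidates$id[missing], collapse = ", "))
  thr <- ifelse(candidates$region_class == "genic",
                config$scoreGenicMin, config$scoreIntergenicMin)
  candidates[candidates$design_score > thr, , drop = FALSE]
}

#' Select spacing-constrained markers
#'
#' Enforces the panel spacing rule: adjacent selected markers on a
#' chromosome must be more than `minGapBp` apart.
#'
#' In `max_count` mode a left-to-right greedy sweep retains the maximum
#' achievable number of markers per chromosome (greedy is optimal for this
#' 1-D selection problem). In `score_priority` mode candidates are admitted
#' in descending `design_score` (ties broken by position then id) subject to
#' the gap constraint.
#'
#' @param candidates `data.frame` with `id`, `chrom`, `pos` (and
#'   `design_score` for `score_priority` mode).
#' @param minGapBp Exclusive minimum gap, bp.
#' @param mode `"max_count"` or `"score_priority"`.
#' @return A [MarkerPanel-class].
#' @examples
#' cand <- data.frame(id = paste0("s", 1:4), chrom = "A01",
#'                    pos = c(100, 1500, 2700, 5000))
#' panelTable(selectSpacedMarkers(cand, 2100))$pos  # 100, 2700, 5000
#' @export
selectSpacedMarkers <- function(candidates, minGapBp = 2100,
                                mode = c("max_count", "score_priority")) {
  mode <- match.arg(mode)
  if (anyDuplicated(candidates[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) pairs in candidates")
  if (nrow(candidates) == 0)
    return(new("MarkerPanel", table = candidates, minGapBp = minGapBp))

  if (mode == "max_count") {
    keep <- unlist(lapply(split(seq_len(nrow(candidates)), candidates$chrom),
                          function(ix) {
      ix <- ix[order(candidates$pos[ix])]
      last <- -Inf
      sel <- logical(length(ix))
      for (i in seq_along(ix)) {
        p <- candidates$pos[ix[i]]
        if (p - last > minGapBp) { sel[i] <- TRUE; last <- p }
      }
      ix[sel]
    }), use.names = FALSE)
  } else {
    if (is.null(candidates$design_score))
      stop("score_priority mode needs a 'design_score' column")
    ord <- order(-candidates$design_score, candidates$pos, candidates$id)
    admitted <- list()
    keep <- integer(0)
    for (i in ord) {
      ch <- candidates$chrom[i]
      p <- candidates$pos[i]
      ps <- admitted[[ch]]
      if (is.null(ps) || all(abs(ps - p) > minGapBp)) {
        admitted[[ch]] <- c(ps, p)
        keep <- c(keep, i)
      }
    }
  }
  tb <- candidates[keep, , drop = FALSE]
  tb <- tb[order(tb$chrom, tb$pos), , drop = FALSE]
  rownames(tb) <- NULL
  new("MarkerPanel", table = tb, minGapBp = minGapBp)
}

#' Annotate candidates with genic context
#'
#' Classifies each candidate as genic or intergenic from gene spans, and
#' genic candidates into UTR, exon or intron with precedence
#' UTR > exon > intron (intron = inside a gene but in no exon/UTR interval).
#'
#' @param candidates `data.frame` with `chrom`, `pos`.
#' @param annotation Either a `GRanges` as returned by
#'   [readGeneAnnotation()] (GFF3 `type` column with `gene`, `exon` and UTR
#'   features) or a `data.frame(chrom, start, end, type)` with 1-based
#'   inclusive coordinates.
#' @return `candidates` with `region_class` (`genic`/`intergenic`) and
#'   `feature` (`UTR`/`exon`/`intron`/`none`) columns filled.
#' @details Exon/UTR intervals not contained in any gene span raise a
#'   warning and are ignored.
#' @export
annotateSnpContext <- function(candidates, annotation) {
  ann <- .asAnnotationFrame(annotation)
  ann$type[ann$type %in% c("five_prime_UTR", "three_prime_UTR", "UTR")] <- "UTR"
  genes <- ann[ann$type == "gene", , drop = FALSE]
  feats <- ann[ann$type %in% c("exon", "UTR"), , drop = FALSE]

  if (nrow(feats)) {
    contained <- vapply(seq_len(nrow(feats)), function(i) {
      g <- genes[genes$chrom == feats$chrom[i], , drop = FALSE]
      any(g$start <= feats$start[i] & g$end >= feats$end[i])
    }, logical(1))
    if (any(!contained)) {
      warning(sum(!contained),
              " feature interval(s) outside any gene span; ignored")
      feats <- feats[contained, , drop = FALSE]
    }
  }

  overlaps <- function(iv, chrom, pos) {
    if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
    vapply(seq_along(pos), function(i) {
      any(iv$chrom == chrom[i] & iv$start <= pos[i] & iv$end >= pos[i])
    }, logical(1))
  }
  inGene <- overlaps(genes, candidates$chrom, candidates$pos)
  inUTR <- overlaps(feats[feats$type == "UTR", , drop = FALSE],
                    candidates$chrom, candidates$pos)
  inExon <- overlaps(feats[feats$type == "exon", , drop = FALSE],
                     candidates$chrom, candidates$pos)

  candidates$region_class <- ifelse(inGene, "genic", "intergenic")
  candidates$feature <- ifelse(!inGene, "none",
                        ifelse(inUTR, "UTR",
                        ifelse(inExon, "exon", "intron")))
  candidates
}

.asAnnotationFrame <- function(annotation) {
  if (is(annotation, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(annotation)),
               start = GenomicRanges::start(annotation),
               end = GenomicRanges::end(annotation),
               type = as.character(annotation$type))
  } else {
    stopifnot(all(c("chrom", "start", "end", "type") %in% names(annotation)))
    annotation
  }
}

#' Average marker spacing on a chromosome
#'
#' Defined as chromosome length divided by marker count and reported at one
#' decimal in Kb — the simple convention that treats markers as partitioning
#' the chromosome into `count` stretches.
#'
#' @param count Marker count (vectorized).
#' @param lengthKb Chromosome length in Kb.
#' @return Average spacing in Kb, one decimal; `NA` where `count` is zero.
#' @export
averageSpacingKb <- function(count, lengthKb) {
  ifelse(count > 0, round(lengthKb / count, 1), NA_real_)
}

#' Percentage share, reported at two decimals
#'
#' @param n Numerator count(s).
#' @param d Denominator count.
#' @return `100 * n / d` rounded to two decimals.
#' @export
percentShare <- function(n, d) round(100 * n / d, 2)

#' Per-chromosome panel summary from counts
#'
#' The count-level arithmetic behind [summarizePanel()], usable directly on
#' externally tabulated counts (e.g. a published panel table).
#'
#' @param counts Named integer vector of SNP counts per chromosome.
#' @param lengthsKb Chromosome lengths in Kb, aligned with `counts`.
#' @param subgenome Optional subgenome tag per chromosome; adds per-subgenome
#'   aggregate rows and percentage shares.
#' @return `data.frame(chrom, nSNP, lengthKb, avgSpacingKb [, subgenome])`
#'   with aggregate rows (per subgenome and `Total`) appended, plus a
#'   `sharePct` column on aggregate rows.
#' @examples
#' panelSummaryFromCounts(c(A01 = 3500), c(A01 = 99884.70))
#' @export
panelSummaryFromCounts <- function(counts, lengthsKb, subgenome = NULL) {
  stopifnot(length(counts) == length(lengthsKb))
  chrom <- names(counts)
  if (is.null(chrom)) chrom <- paste0("chr", seq_along(counts))
  df <- data.frame(chrom = chrom, nSNP = as.numeric(counts),
                   lengthKb = as.numeric(lengthsKb),
                   avgSpacingKb = averageSpacingKb(counts, lengthsKb),
                   sharePct = NA_real_)
  total <- sum(counts)
  agg <- list()
  if (!is.null(subgenome)) {
    df$subgenome <- subgenome
    for (sg in unique(subgenome)) {
      sel <- subgenome == sg
      agg[[sg]] <- data.frame(chrom = sg, nSNP = sum(counts[sel]),
                              lengthKb = sum(lengthsKb[sel]),
                              avgSpacingKb = averageSpacingKb(
                                sum(counts[sel]), sum(lengthsKb[sel])),
                              sharePct = percentShare(sum(counts[sel]), total),
                              subgenome = sg)
    }
  }
  tot <- data.frame(chrom = "Total", nSNP = total,
                    lengthKb = sum(lengthsKb),
                    avgSpacingKb = averageSpacingKb(total, sum(lengthsKb)),
                    sharePct = 100)
  if (!is.null(subgenome)) tot$subgenome <- NA
  rbind(df, do.call(rbind, agg), tot)
}

#' Summarize a marker panel
#'
#' Panel statistics for reporting: per-chromosome counts and average
#' spacing, subgenome counts/shares, a gap-distance histogram over
#' consecutive same-chromosome distances, the largest gap per chromosome,
#' and genic/intergenic and feature breakdowns when the panel carries that
#' annotation.
#'
#' @param panel A [MarkerPanel-class] or a `data.frame` with `chrom`, `pos`
#'   (optionally `region_class`, `feature`).
#' @param genomeLayout `data.frame(chrom, length_bp, subgenome)`; every
#'   panel chromosome must appear here.
#' @param gapBreaksKb Gap-histogram bin edges in Kb. The default bins are
#'   <10, 10–20, 20–30, 30–40, 40–50 and >50 Kb.
#' @return A list of class `PanelSummary` with elements `chromTable`,
#'   `gapHist`, `largestGapKb`, `regionTable`, `featureTable`.
#' @export
summarizePanel <- function(panel, genomeLayout,
                           gapBreaksKb = c(0, 10, 20, 30, 40, 50, Inf)) {
  tb <- if (is(panel, "MarkerPanel")) panelTable(panel) else panel
  stopifnot(all(c("chrom", "length_bp") %in% names(genomeLayout)))
  missingChrom <- setdiff(unique(tb$chrom), genomeLayout$chrom)
  if (length(missingChrom))
    stop("panel chromosome(s) not in genome layout: ",
         paste(missingChrom, collapse = ", "))

  counts <- table(factor(tb$chrom, levels = genomeLayout$chrom))
  counts <- stats::setNames(as.numeric(counts), genomeLayout$chrom)
  lengthsKb <- stats::setNames(genomeLayout$length_bp / 1000,
                               genomeLayout$chrom)
  chromTable <- panelSummaryFromCounts(counts, lengthsKb,
                                       subgenome = genomeLayout$subgenome)

  gapsBp <- unlist(tapply(tb$pos, tb$chrom,
                          function(p) diff(sort(p)), simplify = FALSE),
                   use.names = FALSE)
  gapsKb <- gapsBp / 1000
  gapHist <- if (length(gapsKb)) {
    cutg <- cut(gapsKb, breaks = gapBreaksKb, right = FALSE,
                include.lowest = TRUE)
    data.frame(bin = levels(cutg), count = as.numeric(table(cutg)),
               sharePct = percentShare(as.numeric(table(cutg)),
                                       length(gapsKb)))
  } else data.frame(bin = character(), count = numeric(),
                    sharePct = numeric())
  largestGapKb <- vapply(genomeLayout$chrom, function(ch) {
    p <- sort(tb$pos[tb$chrom == ch])
    if (length(p) > 1) max(diff(p)) / 1000 else NA_real_
  }, numeric(1))

  regionTable <- featureTable <- NULL
  if (!is.null(tb$region_class)) {
    rc <- table(factor(tb$region_class, levels = c("genic", "intergenic")))
    regionTable <- data.frame(region = names(rc), count = as.numeric(rc),
                              sharePct = percentShare(as.numeric(rc),
                                                      nrow(tb)))
    if (!is.null(tb$feature)) {
      fe <- tb$feature[tb$region_class == "genic"]
      ft <- table(factor(fe, levels = c("UTR", "exon", "intron")))
      featureTable <- data.frame(feature = names(ft),
                                 count = as.numeric(ft),
                                 sharePct = percentShare(as.numeric(ft),
                                                         max(length(fe), 1)))
    }
  }
  structure(list(chromTable = chromTable, gapHist = gapHist,
                 largestGapKb = largestGapKb, regionTable = regionTable,
                 featureTable = featureTable, nMarkers = nrow(tb)),
            class = "PanelSummary")
}

#' @export
print.PanelSummary <- function(x, ...) {
  cat("Panel summary:", x$nMarkers, "markers\n\nPer chromosome:\n")
  print(x$chromTable, row.names = FALSE)
  if (nrow(x$gapHist)) {
    cat("\nGap histogram (Kb bins):\n")
    print(x$gapHist, row.names = FALSE)
  }
  if (!is.null(x$regionTable)) {
    cat("\nGenic/intergenic:\n")
    print(x$regionTable, row.names = FALSE)
  }
  invisible(x)
}

#' Run the full design cascade
#'
#' Convenience wrapper: hard filters, design-score rule, then spacing
#' selection.
#'
#' @inheritParams applyHardFilters
#' @inheritParams selectSpacedMarkers
#' @return `list(panel = MarkerPanel, report = FilterReport)`; the report
#'   gains `design_score` and `spacing` stages.
#' @export
designPanel <- function(candidates, config = filterConfig(),
                        repeatMask = NULL, neighborVariants = NULL,
                        mode = "max_count") {
  hf <- applyHardFilters(candidates, config, repeatMask, neighborVariants)
  ds <- applyDesignScoreRule(hf$candidates, config)
  rep2 <- rbind(hf$report,
                data.frame(stage = "design_score",
                           input = nrow(hf$candidates),
                           removed = nrow(hf$candidates) - nrow(ds),
                           surviving = nrow(ds)))
  panel <- selectSpacedMarkers(ds, config$minGapBp, mode)
  rep2 <- rbind(rep2,
                data.frame(stage = "spacing", input = nrow(ds),
                           removed = nrow(ds) - length(panel),
                           surviving = length(panel)))
  list(panel = panel, report = rep2)
}
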