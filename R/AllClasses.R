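#' @importFrom methods new validObject is as callNextMethod show
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

## Valid genotype-call states. "NG" = no genotype (absent signal, putative
## structural variation / In-Del); "--" = failed or off-cluster call.
.GT_LEVELS <- c("AA", "AB", "BB", "NG", "--")

## ---------------------------------------------------------------------------
## IntensityExperiment
## ---------------------------------------------------------------------------

#' Two-channel array intensities (theta, normalized R)
#'
#' A \linkS4class{SummarizedExperiment} holding, per (marker, sample), the
#' normalized allele-contrast angle `theta` (0 = one homozygote, 1 = the
#' other) and the normalized total signal `normR`. Signal normalization is
#' assumed to have happened upstream in the scanner software; this container
#' starts where that leaves off.
#'
#' @slot .  Inherits all SummarizedExperiment slots; assays must be named
#'   `theta` and `normR`.
#' @seealso [IntensityExperiment()], [callGenotypeMatrix()]
#' @export
setClass("IntensityExperiment", contains = "SummarizedExperiment")

setValidity("IntensityExperiment", function(object) {
  msg <- character()
  if (!all(c("theta", "normR") %in% assayNames(object)))
    msg <- c(msg, "assays 'theta' and 'normR' are required")
  else {
    th <- assay(object, "theta")
    nr <- assay(object, "normR")
    if (any(th < 0 | th > 1, na.rm = TRUE))
      msg <- c(msg, "theta values must lie in [0, 1]")
    if (any(nr < 0, na.rm = TRUE))
      msg <- c(msg, "normR values must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityExperiment
#'
#' @param theta Numeric matrix of allele-contrast values in \[0, 1\],
#'   markers in rows, samples in columns.
#' @param normR Numeric matrix of normalized intensities (>= 0), same
#'   dimensions as `theta`.
#' @param rowData,colData Optional marker / sample annotation.
#' @return An [IntensityExperiment-class] object.
#' @examples
#' ie <- IntensityExperiment(
#'   theta = matrix(c(0.05, 0.95), 1, 2, dimnames = list("m1", c("s1", "s2"))),
#'   normR = matrix(1, 1, 2, dimnames = list("m1", c("s1", "s2"))))
#' thetaMatrix(ie)
#' @export
IntensityExperiment <- function(theta, normR, rowData = NULL, colData = NULL) {
  theta <- as.matrix(theta)
  normR <- as.matrix(normR)
  stopifnot(identical(dim(theta), dim(normR)))
  args <- list(assays = list(theta = theta, normR = normR))
  if (!is.null(rowData)) args$rowData <- rowData
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment, args)
  new("IntensityExperiment", se)
}

#' @rdname thetaMatrix
#' @export
setMethod("thetaMatrix", "IntensityExperiment",
          function(x) assay(x, "theta"))

#' @rdname normRMatrix
#' @export
setMethod("normRMatrix", "IntensityExperiment",
          function(x) assay(x, "normR"))

setMethod("show", "IntensityExperiment", function(object) {
  cat("IntensityExperiment:", nrow(object), "markers x",
      ncol(object), "samples\n")
  callNextMethod()
})

## ---------------------------------------------------------------------------
## GenotypeExperiment
## ---------------------------------------------------------------------------

#' Genotype calls for markers x samples
#'
#' A \linkS4class{SummarizedExperiment} whose `calls` assay is a character
#' matrix over the states `AA`, `AB`, `BB`, `NG`, `--`. Marker coordinates
#' (`chrom`, `pos`) live in `rowData`, sample metadata in `colData`.
#' Tetraploid genotype classes observed during calling are kept as marker
#' annotation; the calls themselves are diploidized.
#'
#' @seealso [GenotypeExperiment()], [callRate()], [minorAlleleFreq()]
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  msg <- character()
  if (!"calls" %in% assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    cl <- assay(object, "calls")
    if (!is.character(cl))
      msg <- c(msg, "'calls' must be a character matrix")
    else if (!all(cl %in% .GT_LEVELS))
      msg <- c(msg, sprintf("calls must be one of %s",
                            paste(.GT_LEVELS, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param calls Character matrix of genotype calls (`AA`, `AB`, `BB`, `NG`,
#'   `--`), markers in rows, samples in columns.
#' @param chrom,pos Optional marker coordinates (recycled into `rowData`).
#' @param rowData,colData Optional further annotation.
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' gt <- GenotypeExperiment(
#'   matrix(c("AA", "AB", "BB", "AA"), 2, 2,
#'          dimnames = list(c("m1", "m2"), c("s1", "s2"))))
#' minorAlleleFreq(gt)
#' @export
GenotypeExperiment <- function(calls, chrom = NULL, pos = NULL,
                               rowData = NULL, colData = NULL) {
  calls <- as.matrix(calls)
  rd <- if (is.null(rowData)) DataFrame(row.names = rownames(calls))
        else DataFrame(rowData)
  if (!is.null(chrom)) rd$chrom <- chrom
  if (!is.null(pos)) rd$pos <- as.numeric(pos)
  args <- list(assays = list(calls = calls), rowData = rd)
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment, args)
  new("GenotypeExperiment", se)
}

#' @rdname calls
#' @export
setMethod("calls", "GenotypeExperiment", function(x) assay(x, "calls"))

setMethod("show", "GenotypeExperiment", function(object) {
  cl <- assay(object, "calls")
  called <- mean(cl %in% c("AA", "AB", "BB"))
  cat("GenotypeExperiment:", nrow(object), "markers x", ncol(object),
      sprintf("samples (%.1f%% called)\n", 100 * called))
  callNextMethod()
})

#' @rdname callRate
#' @export
setMethod("callRate", "GenotypeExperiment", function(x, by = "marker") {
  .callRate(assay(x, "calls"), by)
})

#' @rdname callRate
#' @export
setMethod("callRate", "matrix", function(x, by = "marker") .callRate(x, by))

.callRate <- function(cl, by = c("marker", "sample")) {
  by <- match.arg(by)
  called <- cl %in% c("AA", "AB", "BB")
  dim(called) <- dim(cl)
  dimnames(called) <- dimnames(cl)
  if (by == "marker") rowMeans(called) else colMeans(called)
}

#' @rdname minorAlleleFreq
#' @export
setMethod("minorAlleleFreq", "GenotypeExperiment",
          function(x) .maf(assay(x, "calls")))

#' @rdname minorAlleleFreq
#' @export
setMethod("minorAlleleFreq", "matrix", function(x) .maf(x))

.maf <- function(cl) {
  nAA <- rowSums(cl == "AA")
  nAB <- rowSums(cl == "AB")
  nBB <- rowSums(cl == "BB")
  n <- nAA + nAB + nBB
  p <- ifelse(n > 0, (2 * nAA + nAB) / (2 * n), NA_real_)
  maf <- pmin(p, 1 - p)
  names(maf) <- rownames(cl)
  maf
}

## ---------------------------------------------------------------------------
## ClusterModelSet
## ---------------------------------------------------------------------------

#' Fitted theta-cluster models for a set of markers
#'
#' One model per marker, as produced by [fitThetaClusters()] /
#' [adjustClusters()]: cluster means, standard deviations, weights,
#' tetraploid and diploidized labels, merge/complex/failed flags and the
#' BIC of the selected mixture.
#'
#' @slot models List of per-marker model lists.
#' @slot config The [callingConfig()] used for the fit.
#' @export
setClass("ClusterModelSet",
         representation(models = "list", config = "list"))

setValidity("ClusterModelSet", function(object) {
  ok <- vapply(object@models, function(m) {
    is.list(m) && !is.null(m$failed) &&
      (isTRUE(m$failed) || (length(m$mean) == m$k && !is.unsorted(m$mean)))
  }, logical(1))
  if (all(ok)) TRUE else "malformed per-marker model(s)"
})

#' @rdname clusterModels
#' @export
setMethod("clusterModels", "ClusterModelSet", function(x) x@models)

#' @export
setMethod("length", "ClusterModelSet", function(x) length(x@models))

setMethod("show", "ClusterModelSet", function(object) {
  ks <- vapply(object@models,
               function(m) if (isTRUE(m$failed)) NA_integer_ else m$k,
               integer(1))
  cat("ClusterModelSet:", length(object@models), "markers\n")
  cat("  k distribution:",
      paste(sprintf("k=%s:%d", names(table(ks, useNA = "ifany")),
                    as.integer(table(ks, useNA = "ifany"))),
            collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## MarkerPanel
## ---------------------------------------------------------------------------

#' A spacing-constrained selected marker panel
#'
#' The ordered set of SNPs retained for an array: sorted by (chromosome,
#' position) with every adjacent same-chromosome pair separated by more
#' than `minGapBp` base pairs.
#'
#' @slot table `data.frame` of retained candidates (at least `id`, `chrom`,
#'   `pos`).
#' @slot minGapBp Minimum allowed adjacent gap in bp (exclusive bound).
#' @seealso [selectSpacedMarkers()], [summarizePanel()]
#' @export
setClass("MarkerPanel",
         representation(table = "data.frame", minGapBp = "numeric"))

setValidity("MarkerPanel", function(object) {
  tb <- object@table
  msg <- character()
  if (nrow(tb)) {
    if (!all(c("chrom", "pos") %in% names(tb)))
      return("panel table needs 'chrom' and 'pos' columns")
    o <- order(tb$chrom, tb$pos)
    if (!identical(o, seq_len(nrow(tb))))
      msg <- c(msg, "panel must be sorted by (chrom, pos)")
    gaps <- unlist(tapply(tb$pos, tb$chrom, function(p) diff(sort(p)),
                          simplify = FALSE), use.names = FALSE)
    if (length(gaps) && any(gaps <= object@minGapBp))
      msg <- c(msg, sprintf("adjacent markers closer than minGapBp (%g)",
                            object@minGapBp))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname panelTable
#' @export
setMethod("panelTable", "MarkerPanel", function(x) x@table)

#' @export
setMethod("length", "MarkerPanel", function(x) nrow(x@table))

setMethod("show", "MarkerPanel", function(object) {
  tb <- object@table
  cat("MarkerPanel:", nrow(tb), "markers on",
      length(unique(tb$chrom)), "chromosome(s),",
      "min gap >", object@minGapBp, "bp\n")
})
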