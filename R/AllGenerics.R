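#' @importFrom methods setGeneric setMethod
NULL

#' Extract the theta (allele-contrast) matrix
#'
#' @param x An [IntensityExperiment-class] object.
#' @return Numeric matrix, markers in rows, samples in columns.
#' @export
setGeneric("thetaMatrix", function(x) standardGeneric("thetaMatrix"))

#' Extract the normalized total-intensity (R) matrix
#'
#' @param x An [IntensityExperiment-class] object.
#' @return Numeric matrix, markers in rows, samples in columns.
#' @export
setGeneric("normRMatrix", function(x) standardGeneric("normRMatrix"))

#' Extract the genotype-call matrix
#'
#' @param x A [GenotypeExperiment-class] object.
#' @return Character matrix of calls (`AA`, `AB`, `BB`, `NG`, `--`),
#'   markers in rows, samples in columns.
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' Call rates per marker or per sample
#'
#' A call is a definite genotype (`AA`, `AB` or `BB`); `NG` ("no genotype",
#' absent signal) and `--` (failed/off-cluster) both reduce the rate.
#'
#' @param x A [GenotypeExperiment-class] object or call matrix.
#' @param by `"marker"` (default) or `"sample"`.
#' @return Named numeric vector of rates in \[0, 1\].
#' @export
setGeneric("callRate", function(x, by = "marker") standardGeneric("callRate"))

#' Minor allele frequency per marker
#'
#' Computed from allele counts of called genotypes (`AA` contributes two
#' reference alleles, `AB` one of each, `BB` two alternate alleles).
#' Markers with no calls get `NA`.
#'
#' @param x A [GenotypeExperiment-class] object or call matrix.
#' @return Named numeric vector in \[0, 0.5\] (or `NA`).
#' @export
setGeneric("minorAlleleFreq", function(x) standardGeneric("minorAlleleFreq"))

#' Per-marker cluster models from a calling run
#'
#' @param x A [ClusterModelSet-class] object.
#' @return List of per-marker model lists.
#' @export
setGeneric("clusterModels", function(x) standardGeneric("clusterModels"))

#' Selected-marker table of a panel
#'
#' @param x A [MarkerPanel-class] object.
#' @return `data.frame` of the retained markers, sorted by (chromosome,
#'   position).
#' @export
setGeneric("panelTable", function(x) standardGeneric("panelTable"))
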