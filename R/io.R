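## Readers and writers for the plain-text formats the toolkit exchanges.
## Coordinates are 1-based inclusive internally (VCF/GFF convention); BED
## input is converted from 0-based half-open at this boundary.

#' Read a candidate-SNP manifest
#'
#' Tab-separated with columns `id`, `chrom`, `pos`, `ref`, `alt`, `maf`,
#' `het_rate`, `accuracy`, `design_score`, `multi_mapped` (and optionally
#' `region_class`, `feature`).
#'
#' @param path File path.
#' @return `data.frame` of candidates.
#' @export
readCandidateManifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "maf", "het_rate", "accuracy")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (!is.null(df$multi_mapped)) df$multi_mapped <- as.logical(df$multi_mapped)
  df
}

#' Write a candidate/panel manifest
#'
#' @param candidates `data.frame` (or [MarkerPanel-class]).
#' @param path File path.
#' @export
writeCandidateManifest <- function(candidates, path) {
  if (is(candidates, "MarkerPanel")) candidates <- panelTable(candidates)
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a genome layout table
#'
#' Tab-separated `chrom`, `length_bp` and optional `subgenome`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
readGenomeLayout <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length_bp") %in% names(df)))
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome names in layout")
  if (any(df$length_bp <= 0)) stop("chromosome lengths must be positive")
  df
}

#' Read a BED repeat mask
#'
#' Converts from BED's 0-based half-open intervals to the 1-based inclusive
#' convention used internally.
#'
#' @param path File path.
#' @return `data.frame(chrom, start, end)`.
#' @export
readBedMask <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr))
}

#' Write intervals as BED
#'
#' @param intervals `data.frame(chrom, start, end)`, 1-based inclusive.
#' @param path File path.
#' @export
writeBedMask <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start,
                                                intervals$end))
  rtracklayer::export(gr, path, format = "BED")
}

#' Read gene annotation from GFF3
#'
#' @param path File path.
#' @param types Feature types to keep. Default gene, exon and UTR records.
#' @return A `GRanges` with a `type` column, as consumed by
#'   [annotateSnpContext()] and [peakRegionsAndGenes()].
#' @export
readGeneAnnotation <- function(path,
                               types = c("gene", "exon", "UTR",
                                         "five_prime_UTR",
                                         "three_prime_UTR")) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr[as.character(gr$type) %in% types]
}

#' Write gene annotation as GFF3
#'
#' @param annotation `data.frame(chrom, start, end, type)` with optional
#'   `id`.
#' @param path File path.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  id <- if (!is.null(annotation$id)) annotation$id else NA
  attrs <- ifelse(is.na(id), "ID=NA", paste0("ID=", id))
  lines <- c("##gff-version 3",
             paste(annotation$chrom, "polyArray", annotation$type,
                   annotation$start, annotation$end, ".", "+", ".",
                   attrs, sep = "\t"))
  writeLines(lines, path)
}

#' Read a long-format intensity table
#'
#' Tab-separated `marker_id`, `sample_id`, `theta`, `norm_r`.
#'
#' @param path File path.
#' @return An [IntensityExperiment-class].
#' @export
readIntensities <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "sample_id", "theta", "norm_r") %in%
                  names(df)))
  mk <- unique(df$marker_id)
  sp <- unique(df$sample_id)
  theta <- matrix(NA_real_, length(mk), length(sp),
                  dimnames = list(mk, sp))
  normR <- theta
  ij <- cbind(match(df$marker_id, mk), match(df$sample_id, sp))
  theta[ij] <- df$theta
  normR[ij] <- df$norm_r
  IntensityExperiment(theta, normR)
}

#' Write intensities in long format
#'
#' @param intensities An [IntensityExperiment-class].
#' @param path File path.
#' @export
writeIntensities <- function(intensities, path) {
  th <- thetaMatrix(intensities)
  nr <- normRMatrix(intensities)
  df <- data.frame(marker_id = rep(rownames(th), ncol(th)),
                   sample_id = rep(colnames(th), each = nrow(th)),
                   theta = as.vector(th), norm_r = as.vector(nr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write genotype calls as VCF
#'
#' Diploidized calls become the GT field (`AA` = 0/0, `AB` = 0/1,
#' `BB` = 1/1); both `NG` and `--` are `./.`, distinguished by an `NG`
#' FORMAT flag (1 = absent signal, 0 otherwise).
#'
#' @param genotypes A [GenotypeExperiment-class] with `chrom`/`pos` rowData
#'   (and optionally `ref`/`alt`).
#' @param path Output path (plain text).
#' @export
writeGenotypeVCF <- function(genotypes, path) {
  cl <- calls(genotypes)
  rd <- rowData(genotypes)
  stopifnot(all(c("chrom", "pos") %in% names(rd)))
  ref <- if (!is.null(rd$ref)) rd$ref else rep("A", nrow(cl))
  alt <- if (!is.null(rd$alt)) rd$alt else rep("G", nrow(cl))
  gtCode <- c(AA = "0/0", AB = "0/1", BB = "1/1", NG = "./.", "--" = "./.")
  body <- vapply(seq_len(nrow(cl)), function(i) {
    fmt <- paste0(gtCode[cl[i, ]], ":", as.integer(cl[i, ] == "NG"))
    paste(c(rd$chrom[i], rd$pos[i], rownames(cl)[i], ref[i], alt[i], ".",
            "PASS", ".", "GT:NG", fmt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=polyArray",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=NG,Number=1,Type=Integer,Description=",
           "\"No-genotype flag: absent signal at a working locus\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(cl)), collapse = "\t"))
  writeLines(c(header, body), path)
}

#' Read genotype calls from VCF
#'
#' Inverse of [writeGenotypeVCF()]: GT 0/0, 0/1 (or 1/0), 1/1 map to `AA`,
#' `AB`, `BB`; `./.` becomes `NG` where the NG FORMAT flag is 1, `--`
#' otherwise.
#'
#' @param path File path.
#' @return A [GenotypeExperiment-class].
#' @export
readGenotypeVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  cl <- matrix("--", nrow(gtRaw), ncol(gtRaw), dimnames = dimnames(gtRaw))
  cl[gtRaw %in% "0/0"] <- "AA"
  cl[gtRaw %in% c("0/1", "1/0")] <- "AB"
  cl[gtRaw %in% "1/1"] <- "BB"
  ngRaw <- tryCatch(vcfR::extract.gt(v, element = "NG"),
                    error = function(e) NULL)
  if (!is.null(ngRaw)) cl[!is.na(ngRaw) & ngRaw == "1" & cl == "--"] <- "NG"
  fix <- vcfR::getFIX(v)
  GenotypeExperiment(cl, chrom = fix[, "CHROM"],
                     pos = as.numeric(fix[, "POS"]),
                     rowData = S4Vectors::DataFrame(
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       row.names = rownames(cl)))
}

#' Read a sample metadata table
#'
#' Tab-separated `sample`, `group` and optional `replicate_of`, `parent1`,
#' `parent2`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(df)))
  for (col in c("replicate_of", "parent1", "parent2")) {
    if (!is.null(df[[col]])) {
      bad <- stats::na.omit(setdiff(df[[col]], c(df$sample, "")))
      if (length(bad))
        stop("metadata references unknown sample(s): ",
             paste(bad, collapse = ", "))
    }
  }
  if (!is.null(df$parent1) &&
      any(df$parent1 == df$sample | df$parent2 == df$sample, na.rm = TRUE))
    stop("self-pedigree in metadata")
  df
}

#' Read a phenotype table
#'
#' Tab-separated `sample` column plus one numeric column per trait.
#'
#' @param path File path.
#' @param trait Optional trait name; if given, returns a named numeric
#'   vector for that trait, otherwise the full data.frame.
#' @return Named numeric vector or `data.frame`.
#' @export
readPhenotypes <- function(path, trait = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("sample" %in% names(df))
  if (is.null(trait)) return(df)
  if (!trait %in% names(df)) stop("unknown trait: ", trait)
  stats::setNames(as.numeric(df[[trait]]), df$sample)
}
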