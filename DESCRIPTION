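Package: polyArray
Title: SNP Array Design, Polyploid Genotype Calling, and Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for designing intraspecific SNP genotyping arrays on
    polyploid genomes and analysing the resulting data. Implements the
    candidate-filter cascade and spacing selection used to assemble array
    panels, genotype calling from normalized two-channel intensities (theta
    and normalized R) with cluster-merging adjustments for allotetraploid
    loci, panel quality control (call rates, replicate concordance,
    parent/F1 heterozygosity verification), identity-by-state phylogenetics,
    linkage-disequilibrium decay, and Q+K mixed-linear-model genome-wide
    association scans. Includes seeded synthetic-data generators (Balding-
    Nichols structured populations, intensity clusters, trios, phenotypes
    with planted effects) so every step can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'snpSelection.R'
    'genotypeCalling.R'
    'panelQC.R'
    'popgen.R'
    'gwas.R'
    'simulate.R'
    'io.R'
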