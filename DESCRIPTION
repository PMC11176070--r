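Package: mosaicscan
Title: Statistical Characterization of Mosaic Structural Variants in Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing mosaic structural variants (mSVs) in
    single hematopoietic stem and progenitor cells from strand-resolved
    single-cell sequencing and companion single-cell assays. Provides
    strand-state segmentation and sister-chromatid-exchange (SCE) calling from
    binned Watson/Crick read counts, diagnostic-footprint genotyping of mSV
    classes, negative-binomial SCE hotspot statistics with permutation-based
    breakpoint overlap enrichment, nucleosome-occupancy-based cell-type
    classification via two-stage PLS-DA VIP feature selection, subclone
    cell-type enrichment testing, haplotype-resolved sliding-window tests for
    cis-regulatory effects, and targeted copy-number re-calling from
    single-cell expression via Gaussian mixture models. A synthetic-data
    module generates all pipeline inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fitdistrplus,
    mixOmics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
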