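Package: cnvburden
Title: Consensus CNV Calling, Tier Classification and Burden Analysis for
    Pediatric Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort-scale copy number variant (CNV) analysis:
    merging per-caller CNV calls into multi-algorithm consensus events by
    reciprocal overlap, annotating cohort frequency and rarity strata,
    tiered clinical classification (aneuploidy, recurrent genomic-disorder
    loci, non-recurrent gene-disrupting, susceptibility) against a
    user-supplied catalog, carrier-phenotype association (odds ratios,
    chi-square enrichment, per-disorder logistic and trait regressions),
    and global, gene-set and locus-level CNV burden regression with
    global-burden correction, Benjamini-Hochberg FDR and max-T permutation
    family-wise error control. A fully specified synthetic cohort
    generator with planted effects supports calibration and testing
    without access to restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    igraph,
    lmtest,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
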