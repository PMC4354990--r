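Package: methtrio
Title: Matched-Trio Methylome Analysis for Precursor-Lesion Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-methylation analysis of matched tissue trios
    (normal kidney, nephrogenic rest, Wilms tumour) profiled on Illumina
    450k-style beta-value matrices. Provides empirical-Bayes moderated
    paired and three-way differential methylation, density-adaptive
    probe-lasso DMR detection, reference-free cell-mixture-adjusted
    ("pheno-MVP") calling with bootstrap p-values, consensus-clustering
    subtype discovery, probe-wise variance comparisons, resampling-based
    genomic-feature enrichment, a mean-plus-one-SD DMR hypermethylation
    classifier, and a synthetic trio-cohort generator with ground-truth
    manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
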