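Package: eqtmMapper
Title: Scalable Expression Quantitative Trait Methylation (eQTM) Mapping
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps expression quantitative trait methylation loci (eQTMs, also
    called eCpGs) by fitting a covariate-adjusted linear model, or computing a
    Pearson correlation, for every selected (CpG methylation locus, gene
    expression locus) pair. Pairs are selected by genomic mapping modality
    (cis, distal, trans, or all-by-all) from BED annotations anchored at the
    transcript start site. Association statistics are computed in batched
    block form via covariate residualization (Frisch-Waugh-Lovell), with
    two-sided p-values from the standard normal tail approximation, chunked
    execution under a memory budget, p-value threshold filtering, and
    column-selected CSV output. A seed-reproducible synthetic data generator
    produces unstructured dummy inputs and effect-planted datasets for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, GeneExpression, DNAMethylation, Regression,
    Software
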