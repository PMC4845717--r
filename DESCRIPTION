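Package: irdx
Title: Diagnostic Comparison Toolkit for Inherited Retinal Disease Genomic
    Testing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to compare targeted gene-panel sequencing against whole
    genome sequencing in the molecular diagnosis of inherited retinal
    dystrophies. Implements genotype-concordance benchmarking of a
    sequencing pipeline against array-derived truth genotypes (with
    Sanger-style adjudication of discordant sites), a rule-based
    Mendelian outcome classifier that assigns patients to diagnostic and
    carrier categories from annotated variant calls and gene models,
    normalisation and cross-platform differencing of clinically relevant
    variant sets with structural/noncoding categorisation, and a
    stratified weighted estimator of diagnostic-yield uplift with
    binomial-simulation confidence intervals. A synthetic-cohort
    generator and a deterministic worked-example fixture provide inputs
    with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: VariantDetection, Genetics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
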