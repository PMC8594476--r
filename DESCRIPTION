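Package: scredit
Title: RNA Editing Analysis for Full-Length Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and analysis of A-to-I RNA editing in unstranded
    full-length single-nucleus RNA-seq. Implements candidate editing-site
    selection and filtering from per-cell variant calls (coverage,
    prevalence, common-SNP removal, cognate-strand and overlap rules,
    repeat-context and gene-feature annotation, novelty classification),
    per-cell global and Alu editing indices, pseudobulk paired-count
    negative-binomial differential editing between cell groups with a
    directional rotation test for gene-level enrichment, and linear
    modelling of gene-abundance associations with editing activity.
    A synthetic-data generator reproduces the statistical structure the
    analysis assumes (bimodal per-cell edited-allele fractions, skewed
    cross-cell means, Alu-clustered sites, negative-binomial coverage,
    planted SNPs and abundance-editing correlations) so that every stage
    is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    MASS,
    stats,
    utils,
    methods,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
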