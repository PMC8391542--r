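Package: famcnv
Title: Family-Based Exon Read-Depth CNV Calling and Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates family-structured whole-exome read-count cohorts with
    implanted copy number variants (CNVs), calls CNVs per sample from exon
    read depth against an aggregated reference set using a beta-binomial
    emission model with hidden-state segmentation, and prioritizes calls the
    way congenital scoliosis cohort studies do: log10 Bayes factor and size
    filters, gene-based population-frequency filtering against DGV/gnomAD-SV
    style tables, trio-based inheritance classification, detection of
    patient-unique homozygous (recessive) CNVs by the observed/expected reads
    ratio, recurrence-based enrichment of novel CNVs in patients versus
    family controls, and a 2^-ddCt qPCR copy-number validation calculator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
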