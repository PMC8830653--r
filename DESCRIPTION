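Package: rohet
Title: Runs of Heterozygosity: Detection, Islands, and Trait Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to detect runs of heterozygosity (ROHet) in diploid SNP
    array genotypes with a consecutive scanning strategy, summarise their
    genomic distribution, map heterozygosity-rich islands from per-SNP run
    incidence with a top-1-percent occurrence threshold, and test the
    presence or absence of shared heterozygous regions for association with
    quantitative traits under a fixed-effects linear model with an
    FDR-derived significance threshold. Includes PLINK-style PED/MAP text
    input and output, SNP quality control (call rate, minor allele
    frequency, exact Hardy-Weinberg test), and a synthetic-data generator
    with planted heterozygosity-rich segments and region-linked trait
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
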