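Package: genepip
Title: Functional Fine-Mapping and Gene-Level Posterior Inclusion
    Probabilities for GWAS Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-GWAS analysis toolkit for cell-type-aware interpretation of
    association signals. Performs single-effect Bayesian fine-mapping of LD
    blocks from z-scores with annotation-informed priors, estimates functional
    enrichment of causal variants by an EM logistic-prior model, aggregates
    SNP posterior inclusion probabilities (PIPs) into gene-level PIPs through
    weighted SNP-to-gene links (exons, active promoters, enhancer loops, and
    exponential distance decay), partitions PIPs into disjoint functional
    annotation categories, classifies open chromatin regions by cell-type
    sharing, and decomposes eQTL tissue sharing by functional category. A
    synthetic-data generator reproduces the statistical structure of every
    input for testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
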