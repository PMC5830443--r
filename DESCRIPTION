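Package: sweepscape
Title: Selection Sweep Scans and Regulatory Feature Enrichment for
    Two-Population Genome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for detecting domestication selection sweeps from
    diploid genotypes of a domestic and a wild population, and for
    quantifying enrichment of regulatory genome features inside sweeps and
    among allele-frequency-divergent sites. Implements a post-calling SNP
    quality-control cascade, per-site Weir-Cockerham FST, sliding-window
    nucleotide diversity and log diversity-ratio statistics with joint
    Z-score outlier calling, region merging and closest-gene assignment,
    chain-based reciprocal interval projection with a minimum match
    criterion, shuffle-based empirical overlap p-values, Fisher-exact locus
    overlap enrichment, and delta-allele-frequency M-value analysis. A
    synthetic-data module generates genotypes, annotation features, peaks
    and alignment chains with the statistical structure the analysis
    assumes, so the whole pipeline can be exercised end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
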