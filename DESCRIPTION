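Package: poolscan
Title: Pooled-DNA Genome-Wide Association Analysis with Relative Allele Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pool-based genome-wide association
    studies. Computes Relative Allele Scores (RAS) from SNP-array probe
    quartets with mismatch correction and cross-array quantile
    normalization, prioritizes markers by absolute RAS difference, by an
    LD-weighted cluster method and by a combined Z-test accounting for
    both sampling and experimental error, and carries prioritized SNPs
    through individual-genotyping stages: Hardy-Weinberg and call-rate
    quality control, log-additive logistic association with odds ratios
    and confidence intervals, dataset combination and Bonferroni
    correction. A synthetic-data generator emulates case-control
    genotypes under a logistic disease model, equimolar DNA pooling with
    mass noise, and replicate array hybridization, so the whole pipeline
    is testable end to end without raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    limma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
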