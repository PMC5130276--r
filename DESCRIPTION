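Package: sexage
Title: Discovery-Validation Analysis of Sex- and Age-Associated Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying and replicating sex- and
    age-associated transcripts in bulk expression studies. Covers
    probe-level preprocessing (detection-rate filtering, probe-to-gene
    collapse, quantile normalization, empirical-Bayes batch adjustment),
    per-gene linear-model association with Benjamini-Hochberg false
    discovery rate control, a label-permutation null for discovery
    counts, multi-cohort validation requiring concordant direction of
    effect, Kolmogorov-Smirnov gene set enrichment with an
    enrichment-map graph, and a synthetic multi-cohort data generator
    with known planted effects so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    sva,
    igraph
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
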