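Package: srnapipe
Title: Small RNA Sequencing Analysis of Cambium Dormancy Libraries
Version: 0.9.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing workflow for three-library
    dormancy-release designs (endodormancy, ecodormancy, active growth):
    adapter and quality cleaning with full read accounting, exact-match
    genome mapping and hierarchical annotation of sRNA classes, known miRNA
    quantification against a mature reference, novel miRNA discovery by
    precursor hairpin folding with a built-in nearest-neighbor energy model,
    digital differential expression via the Audic-Claverie statistic with
    reads-per-million normalization, plant-style miRNA target scoring, and
    RACE cleavage-site prediction. Includes a deterministic synthetic data
    generator with a planted ground-truth manifest so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    Rcpp,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
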