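Package: plasmaconcord
Title: Tissue-Plasma Concordance and Fragmentomics for ctDNA Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Plasma", "Concord", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating circulating tumor DNA (ctDNA) detection in
    plasma liquid biopsies against matched tumor tissue: a post-annotation
    somatic-variant filter cascade with per-criterion accounting, tumor-mutation
    detection rates with Wilson score confidence intervals, patient-level
    per-gene positive-detection rates, reference-material VAF-panel evaluation,
    and allele-aware cell-free DNA fragment-size (insert-size) analysis using
    positional CIGAR-based read classification at variant loci. A seeded
    synthetic-data generator emits aligned read pairs (SAM), annotated variant
    tables, and paired tissue/plasma cohorts so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    GenomicAlignments,
    GenomicRanges,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
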