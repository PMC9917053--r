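Package: difcir
Title: Differential Analysis of Purified Extrachromosomal Circular DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of short-read sequenced, purified
    extrachromosomal circular DNA (eccDNA). Reads per-sample circle calls
    with split-read junction counts, filters and merges them, quantifies
    Produced-per-Gene Circles (PpGCs) with gene-length scaling and
    log-equalization, calls Differentially Produced per Gene Circles
    (DPpGCs) between two groups with a pooled-variance t-test, finds
    Common PpGCs within a group by democratic voting against a
    data-derived threshold, and detects eccDNA carrying whole genes.
    Includes a seeded synthetic circle-call generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
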