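Package: polpause
Title: RNA Polymerase II Promoter-Proximal Pausing Analysis from ChIP-seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the RNA polymerase II traveling ratio (pausing index) from
    per-base ChIP-seq pileup tracks: strand-aware promoter (-30..+300 bp) and
    gene-body (+300 bp..end) windows over transcript annotations, a genome-wide
    background pseudocount, peak-overlap and minimum-length isoform filters, and
    gene-level aggregation. Includes cross-condition fold-change classification
    of pausing, gene-group traveling-ratio distributions with seeded random
    control sets, expression-response grouping, single-gene metagene coverage
    profiles with proportional flanking margins, and a seeded synthetic
    coverage generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    withr,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
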